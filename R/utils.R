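#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "minigeneACMG_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @importFrom utils head tail read.delim read.csv write.table
#' @importFrom stats sd runif rnorm rlnorm setNames
NULL
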