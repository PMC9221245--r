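# HGVS c. variant descriptions: the substitution / deletion / delins subset
# used for splice-site variants. Positions carry optional signed intronic
# offsets (c.404+2, c.146-3).

parse_c_position <- function(txt) {
  m <- regmatches(txt, regexec("^([0-9]+)([+-][0-9]+)?$", txt))[[1]]
  if (length(m) == 0L)
    abort(sprintf("cannot parse HGVS position \"%s\"", txt), "parse_error")
  list(c_pos = as.integer(m[2]),
       intron_offset = if (m[3] == "") 0L else as.integer(m[3]))
}

#' Parse an HGVS c. variant description
#'
#' Supports the subset used for splice-site variants: substitutions
#' (`c.904G>A`, `c.404+2T>C`), deletions with optional range
#' (`c.571+1del`, `c.146-4_146-2del`, `c.905-3_906del`) and
#' deletion-insertions (`c.100_102delinsAT`).
#'
#' @param hgvs_c Character scalar such as `"c.146-3C>G"`.
#' @return An object of class `variant_spec` with fields `hgvs_c`, `type`
#'   (`"substitution"`, `"deletion"` or `"delins"`), `start`/`end` (each a
#'   list with `c_pos`, `intron_offset`), and for substitutions `ref`/`alt`;
#'   for delins, `alt`.
#' @export
parse_variant <- function(hgvs_c) {
  stopifnot(is_string(hgvs_c))
  x <- sub("^c\\.", "", gsub("\\s+", "", hgvs_c))
  pos_re <- "[0-9]+(?:[+-][0-9]+)?"
  m <- regmatches(x, regexec(
    sprintf("^(%s)([ACGT])>([ACGT])$", pos_re), x))[[1]]
  if (length(m) == 4L) {
    p <- parse_c_position(m[2])
    return(structure(list(hgvs_c = hgvs_c, type = "substitution",
                          start = p, end = p, ref = m[3], alt = m[4]),
                     class = "variant_spec"))
  }
  m <- regmatches(x, regexec(
    sprintf("^(%s)(?:_(%s))?del(?:ins([ACGT]+))?([ACGT]*)$", pos_re, pos_re), x))[[1]]
  if (length(m) == 5L) {
    p1 <- parse_c_position(m[2])
    p2 <- if (m[3] == "") p1 else parse_c_position(m[3])
    type <- if (m[4] == "") "deletion" else "delins"
    return(structure(list(hgvs_c = hgvs_c, type = type, start = p1, end = p2,
                          alt = if (m[4] == "") NULL else m[4]),
                     class = "variant_spec"))
  }
  abort(sprintf("unsupported or malformed HGVS description \"%s\"", hgvs_c),
        "parse_error")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s (%s)\n", x$hgvs_c, x$type))
  invisible(x)
}

# locus of the variant start against a model (used by the candidate filter)
variant_locus <- function(model, variant) {
  c_to_exon(model, variant$start$c_pos, variant$start$intron_offset)
}
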