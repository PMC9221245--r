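# Semi-quantitative fluorescent RT-PCR: convert capillary-electrophoresis
# peak tables into per-variant transcript fractions. Peaks below the RFU
# height threshold are discarded (from numerator and denominator alike);
# surviving peaks are matched to expected amplicon sizes within a tolerance,
# the rest reported as uncharacterized by their rounded size. Percentages
# are computed per replicate from peak areas, then averaged.

#' Expected amplicon sizes of a set of isoforms
#'
#' Full-length size = vector flank + sum of the minigene exon lengths; each
#' splice event adds or removes its nucleotide delta.
#'
#' @param model A [transcript_model()].
#' @param layout A [minigene_layout()].
#' @param isoforms List of [isoform_label()]s or label strings.
#' @return `data.frame` with columns `label`, `size_nt`.
#' @export
expected_sizes <- function(model, layout, isoforms) {
  rows <- lapply(isoforms, function(iso) {
    if (is.character(iso)) iso <- parse_label(iso)
    mt <- apply_isoform(model, iso, context = "minigene", layout = layout)
    data.frame(label = format_label(iso), size_nt = mt$amplicon_size_nt)
  })
  do.call(rbind, rows)
}

#' Construct a readout (per-variant transcript fractions)
#'
#' @param variant_id Variant identifier.
#' @param entries `data.frame` with columns `label`, `mean_percent`,
#'   `sd_percent`, `characterized` (logical).
#' @param n_replicates Number of replicates the statistics summarize.
#' @return An object of class `readout`.
#' @export
readout <- function(variant_id, entries, n_replicates) {
  req <- c("label", "mean_percent", "sd_percent", "characterized")
  if (!is.data.frame(entries) || !all(req %in% names(entries)))
    abort("readout entries need label, mean_percent, sd_percent, characterized",
          "quantification_error")
  tot <- sum(entries$mean_percent)
  if (abs(tot - 100) > 0.2)
    abort(sprintf("readout percentages sum to %.2f, not 100", tot),
          "quantification_error")
  if (any(entries$sd_percent < 0))
    abort("negative sd_percent", "quantification_error")
  structure(list(variant_id = variant_id,
                 entries = entries[, req, drop = FALSE],
                 n_replicates = as.integer(n_replicates)),
            class = "readout")
}

#' @export
print.readout <- function(x, ...) {
  cat(sprintf("<readout> %s (%d replicate%s)\n", x$variant_id, x$n_replicates,
              if (x$n_replicates == 1L) "" else "s"))
  for (i in seq_len(nrow(x$entries)))
    cat(sprintf("  %-14s %5.1f%% ± %.1f%%\n", x$entries$label[i],
                x$entries$mean_percent[i], x$entries$sd_percent[i]))
  invisible(x)
}

match_peak <- function(size, expected, tol) {
  # nearest expected size within tolerance; ties resolved toward the larger
  # expected product
  d <- abs(expected$size_nt - size)
  ok <- which(d <= tol)
  if (length(ok) == 0L) return(NA_integer_)
  best <- ok[d[ok] == min(d[ok])]
  best[which.max(expected$size_nt[best])]
}

#' Quantify a peak table into transcript readouts
#'
#' @param peaks `data.frame` with columns `variant_id`, `replicate`,
#'   `size_nt`, `height_rfu`, `area`.
#' @param expected `data.frame` from [expected_sizes()] (`label`, `size_nt`).
#' @param rfu_min Minimum peak height; smaller peaks are dropped from both
#'   the numerator and the denominator.
#' @param size_tol_nt Size tolerance for matching a peak to an expected
#'   amplicon.
#' @return A named list of [readout()] objects, one per `variant_id`.
#' @export
quantify <- function(peaks, expected, rfu_min = 200, size_tol_nt = 2) {
  req <- c("variant_id", "replicate", "size_nt", "height_rfu", "area")
  if (!is.data.frame(peaks) || !all(req %in% names(peaks)))
    abort("peak table needs variant_id, replicate, size_nt, height_rfu, area",
          "quantification_error")
  if (any(peaks$size_nt <= 0) || any(peaks$height_rfu < 0) || any(peaks$area < 0))
    abort("invalid peak table values", "quantification_error")
  if (nrow(peaks) == 0L)
    abort("empty peak table", "quantification_error")
  out <- list()
  for (vid in unique(peaks$variant_id)) {
    pv <- peaks[peaks$variant_id == vid & peaks$height_rfu >= rfu_min, , drop = FALSE]
    if (nrow(pv) == 0L)
      abort(sprintf("no peaks above %g RFU for %s", rfu_min, vid),
            "quantification_error")
    pv$assigned <- vapply(pv$size_nt, function(s) {
      i <- match_peak(s, expected, size_tol_nt)
      if (is.na(i)) sprintf("%dnt", round(s)) else expected$label[i]
    }, "")
    reps <- sort(unique(pv$replicate))
    labels <- unique(pv$assigned)
    pct <- matrix(0, nrow = length(reps), ncol = length(labels),
                  dimnames = list(NULL, labels))
    for (r in seq_along(reps)) {
      pr <- pv[pv$replicate == reps[r], , drop = FALSE]
      tot <- sum(pr$area)
      if (tot <= 0)
        abort(sprintf("replicate %s of %s has zero total area", reps[r], vid),
              "quantification_error")
      for (lab in unique(pr$assigned))
        pct[r, lab] <- sum(pr$area[pr$assigned == lab]) / tot * 100
    }
    means <- colMeans(pct)
    sds <- if (length(reps) > 1L) apply(pct, 2L, sd) else {
      warning(sprintf("%s: single replicate, reporting sd = 0", vid))
      rep(0, length(labels))
    }
    entries <- data.frame(label = labels, mean_percent = as.numeric(means),
                          sd_percent = as.numeric(sds),
                          characterized = labels %in% expected$label)
    entries <- entries[order(-entries$mean_percent), , drop = FALSE]
    rownames(entries) <- NULL
    out[[as.character(vid)]] <- readout(vid, entries, length(reps))
  }
  out
}
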