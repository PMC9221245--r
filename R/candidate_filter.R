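# Candidate pre-selection: position windows around splice sites, the
# MaxEntScan score-reduction threshold, per-site deduplication, ClinVar
# record-count and prior-report filters. MES scores are consumed as inputs;
# the maximum-entropy models themselves are out of scope.

#' Is a locus inside the screened splice-site window?
#'
#' True for intronic positions within +/-10 of a splice site and for the
#' first two and last three nucleotides of an exon.
#'
#' @param locus A [c_to_exon()] result.
#' @return Logical scalar.
#' @export
in_window <- function(locus) {
  if (locus$kind == "intron") return(locus$distance <= 10L)
  locus$offset_in_exon <= 2L || locus$from_exon_end <= 2L
}

#' Percent reduction of a MaxEntScan score
#'
#' `(ref - alt) / ref * 100`. Negative alt scores are allowed (reductions
#' then exceed 100%). Non-positive reference scores cannot be expressed as a
#' percent reduction and return `NA` with the `undefined` attribute set.
#'
#' @param ref,alt MES score of the site before and after the variant.
#' @return Numeric percent reduction (possibly > 100), or `NA`.
#' @export
mes_reduction <- function(ref, alt) {
  if (ref <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (ref - alt) / ref * 100
}

#' Default selection policy
#'
#' @param min_reduction_percent MES reduction threshold (at least 40%).
#' @param min_records Minimum ClinVar record count.
#' @return A policy list for [select_candidates()].
#' @export
default_policy <- function(min_reduction_percent = 40, min_records = 2L) {
  list(min_reduction_percent = min_reduction_percent, min_records = min_records)
}

site_key <- function(variant) {
  sprintf("%d%+d", variant$start$c_pos, variant$start$intron_offset)
}

#' Apply the candidate-selection policy
#'
#' Criteria, applied in order (the audit names the first failed one per
#' rejected variant): (1) inside the splice-site window; (2) MES reduction
#' of at least 40%; (3) one variant per splice-site position, keeping the
#' one with most ClinVar records (ties: strongest reduction, then
#' lexicographic HGVS; invented tie-break, logged here), exempting variants
#' predicted to create de novo sites or activate cryptic ones; (4) at least
#' two ClinVar records; (5) no published splicing assay.
#'
#' @param variants `data.frame` with columns `hgvs_c`, `mes_ref`, `mes_alt`,
#'   `clinvar_records`, `prior_report` (logical), and optionally
#'   `new_site_score` (non-`NA` marks a predicted de novo/cryptic site).
#' @param model A [transcript_model()] for locus resolution.
#' @param policy Policy list from [default_policy()].
#' @return A list with `selected` (data.frame subset) and `audit`
#'   (data.frame `hgvs_c`, `selected`, `reason`).
#' @export
select_candidates <- function(variants, model, policy = default_policy()) {
  req <- c("hgvs_c", "mes_ref", "mes_alt", "clinvar_records", "prior_report")
  if (!is.data.frame(variants) || !all(req %in% names(variants)))
    abort("variant table needs hgvs_c, mes_ref, mes_alt, clinvar_records, prior_report",
          "input_error")
  n <- nrow(variants)
  specs <- lapply(variants$hgvs_c, parse_variant)
  reason <- rep(NA_character_, n)
  red <- numeric(n)
  for (i in seq_len(n)) {
    loc <- variant_locus(model, specs[[i]])
    if (!in_window(loc)) { reason[i] <- "outside_window"; next }
    r <- mes_reduction(variants$mes_ref[i], variants$mes_alt[i])
    red[i] <- if (is.na(r)) Inf else r   # undefined ref treated as flagged, kept
    if (!is.na(r) && r < policy$min_reduction_percent) {
      reason[i] <- "MES<40%"; next
    }
  }
  # per-site dedup among still-alive variants
  alive <- which(is.na(reason))
  keys <- vapply(specs, site_key, "")
  has_new_site <- if ("new_site_score" %in% names(variants))
    !is.na(variants$new_site_score) else rep(FALSE, n)
  for (key in unique(keys[alive])) {
    grp <- alive[keys[alive] == key]
    contenders <- grp[!has_new_site[grp]]   # de novo/cryptic predictions exempt
    if (length(contenders) > 1L) {
      ord <- order(-variants$clinvar_records[contenders], -red[contenders],
                   variants$hgvs_c[contenders])
      reason[contenders[ord[-1L]]] <- "duplicate_site"
    }
  }
  for (i in which(is.na(reason))) {
    if (variants$clinvar_records[i] < policy$min_records) {
      reason[i] <- "records<2"
    } else if (isTRUE(variants$prior_report[i])) {
      reason[i] <- "prior_splicing_report"
    }
  }
  audit <- data.frame(hgvs_c = variants$hgvs_c, selected = is.na(reason),
                      reason = ifelse(is.na(reason), "selected", reason))
  list(selected = variants[is.na(reason), , drop = FALSE], audit = audit)
}
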