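# ACMG/AMP point-based engine.
#
# Evidence strengths map to points (supporting 1, moderate 2, strong 4,
# very strong 8; benign evidence negative), point sums map to categories
# (P >= +10, LP +6..+9, VUS 0..+5, LB -6..-1, B <= -7). Splicing-assay
# readouts enter as PVS1_O (pathogenic) or BP7_O (benign) codes whose
# strength is derived by deconvoluting the readout: per-transcript evidence
# first, then the >=90% expression-share rule with the weakest strength
# contributing >10% selected.

STRENGTHS <- c(supporting = 1L, moderate = 2L, strong = 4L, very_strong = 8L)
STRENGTH_ABBREV <- c(supporting = "P", moderate = "M", strong = "S",
                     very_strong = "VS")

#' Default rule configuration
#'
#' All thresholds of the engine in one versioned list: per-category evidence
#' mapping, the readout-aggregation thresholds (expression share >= 90%,
#' contributor > 10%), the PM2 allele-frequency ceiling (1e-4, supporting
#' strength) and the point/category scales. `critical_domain_upgrade`
#' upgrades PTC transcripts that escape NMD from strong to very strong when
#' they truncate a critical domain, and rates in-frame deletions of a
#' critical domain as very strong.
#'
#' @return A list; pass to the evidence functions or serialize with
#'   [write_rules()].
#' @export
default_rules <- function() {
  list(
    version = "1.0",
    evidence = list(
      ptc_nmd = "very_strong",
      ptc_escape = "strong",
      critical_domain_upgrade = TRUE,
      in_frame_critical = "very_strong",
      in_frame_insilico = "supporting",
      fl_wildtype = "strong",            # benign side
      fl_missense_insilico = "supporting"
    ),
    insilico = list(provean_deleterious_max = -2.5, revel_supporting_min = 0.7),
    aggregation = list(share_min_percent = 90, contributor_min_percent = 10,
                       sum_tolerance = 0.5),
    pm2 = list(af_max = 1e-4, strength = "supporting"),
    points = as.list(STRENGTHS),
    categories = list(P_min = 10L, LP_min = 6L, VUS_min = 0L, LB_min = -6L)
  )
}

#' Serialize / load a rule configuration
#' @param rules A rule list as from [default_rules()].
#' @param path File path (JSON).
#' @return `read_rules()` returns the rule list.
#' @export
write_rules <- function(rules, path) {
  jsonlite::write_json(rules, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Construct an evidence item
#'
#' @param code Evidence code (e.g. `"PVS1_O"`, `"BP7_O"`, `"PM2_P"`).
#' @param direction `"pathogenic"`, `"benign"` or `"none"`.
#' @param strength `"supporting"`, `"moderate"`, `"strong"`, `"very_strong"`
#'   or `"not_applicable"`.
#' @return An object of class `evidence_strength` with signed `points`.
#' @export
evidence_strength <- function(code, direction, strength) {
  direction <- match.arg(direction, c("pathogenic", "benign", "none"))
  strength <- match.arg(strength, c(names(STRENGTHS), "not_applicable"))
  points <- if (strength == "not_applicable" || direction == "none") 0L
    else STRENGTHS[[strength]] * if (direction == "benign") -1L else 1L
  structure(list(code = code, direction = direction, strength = strength,
                 points = points), class = "evidence_strength")
}

#' @export
print.evidence_strength <- function(x, ...) {
  cat(sprintf("<evidence> %s %s (%+d)\n", x$code, x$strength, x$points))
  invisible(x)
}

#' Format an evidence item the way the verdict tables print it
#'
#' E.g. `"PVS1_O_VS (+8)"`, `"PVS1_O_N/A"`.
#' @param ev An [evidence_strength()].
#' @return Character scalar.
#' @export
format_evidence <- function(ev) {
  if (ev$strength == "not_applicable") return(sprintf("%s_N/A", ev$code))
  sprintf("%s_%s (%+d)", ev$code, STRENGTH_ABBREV[[ev$strength]], ev$points)
}

insilico_deleterious <- function(insilico, rules) {
  if (is.null(insilico)) return(FALSE)
  if (isTRUE(insilico$deleterious_flag)) return(TRUE)
  if (!is.null(insilico$provean_score) && !is.na(insilico$provean_score) &&
      insilico$provean_score <= rules$insilico$provean_deleterious_max)
    return(TRUE)
  if (!is.null(insilico$revel_score) && !is.na(insilico$revel_score) &&
      insilico$revel_score >= rules$insilico$revel_supporting_min)
    return(TRUE)
  FALSE
}

#' Per-transcript ACMG evidence
#'
#' Maps one transcript's consequence to an evidence call following the PVS1
#' decision-tree rationale: PTC-NMD transcripts are very strong pathogenic
#' evidence; PTC transcripts escaping NMD are strong, upgraded to very
#' strong when they truncate a critical domain; in-frame transcripts are
#' very strong when they delete a critical domain, supporting when an in
#' silico score supports deleteriousness, otherwise no evidence; a
#' full-length transcript identical to wild type is strong benign evidence,
#' while a full-length transcript carrying a missense change is judged by
#' its in silico score (supporting pathogenic or no evidence).
#'
#' @param consequence A [analyze_consequence()] result (category and
#'   `domains_lost` used; for category `"FL"`, `protein_annotation` decides
#'   wild-type identity).
#' @param fraction_percent This transcript's share of overall expression.
#' @param insilico Optional list with `provean_score`, `revel_score`,
#'   `deleterious_flag`.
#' @param rules Rule configuration, see [default_rules()].
#' @param critical_domains Character vector of critical domain names (from a
#'   [domain_table()]); defaults to treating every entry of
#'   `consequence$domains_lost` as non-critical when empty.
#' @return A list of class `transcript_evidence` with fields `label`,
#'   `fraction_percent`, `evidence` (`"P_VS"`, `"P_S"`, `"P_M"`, `"P_P"`,
#'   `"B_S"`, `"B_P"` or `"N/A"`), `direction`, `strength`.
#' @export
transcript_evidence <- function(consequence, fraction_percent,
                                insilico = NULL, rules = default_rules(),
                                critical_domains = NULL) {
  cat_ <- consequence$category
  if (is.na(cat_) || cat_ == "uncharacterized") {
    if (!is.null(consequence$isoform) && !is_full_length(consequence$isoform) &&
        is.na(consequence$ptc_present) && !isTRUE(consequence$frame_preserved))
      abort("consequence category undetermined (sequence required?)",
            "evidence_undetermined")
  }
  lost_critical <- if (is.null(critical_domains)) character(0)
    else intersect(consequence$domains_lost, critical_domains)
  res <- switch(cat_,
    PTC_NMD = list(direction = "pathogenic", strength = rules$evidence$ptc_nmd),
    PTC_escape = {
      s <- rules$evidence$ptc_escape
      if (isTRUE(rules$evidence$critical_domain_upgrade) && length(lost_critical))
        s <- "very_strong"
      list(direction = "pathogenic", strength = s)
    },
    in_frame = {
      if (length(lost_critical))
        list(direction = "pathogenic", strength = rules$evidence$in_frame_critical)
      else if (insilico_deleterious(insilico, rules))
        list(direction = "pathogenic", strength = rules$evidence$in_frame_insilico)
      else list(direction = "none", strength = "not_applicable")
    },
    FL = {
      wildtype <- is.na(consequence$protein_annotation) ||
        consequence$protein_annotation == "p.(=)"
      if (wildtype)
        list(direction = "benign", strength = rules$evidence$fl_wildtype)
      else if (insilico_deleterious(insilico, rules))
        list(direction = "pathogenic", strength = rules$evidence$fl_missense_insilico)
      else list(direction = "none", strength = "not_applicable")
    },
    list(direction = "none", strength = "not_applicable")  # uncharacterized
  )
  structure(list(
    label = if (!is.null(consequence$isoform)) format_label(consequence$isoform)
            else NA_character_,
    fraction_percent = fraction_percent,
    direction = res$direction, strength = res$strength,
    evidence = if (res$strength == "not_applicable") "N/A"
      else paste0(if (res$direction == "pathogenic") "P_" else "B_",
                  STRENGTH_ABBREV[[res$strength]])
  ), class = "transcript_evidence")
}

#' Aggregate a deconvoluted readout into a PVS1_O / BP7_O code
#'
#' Implements the readout-aggregation algorithm: if transcripts carrying
#' pathogenic evidence contribute at least 90% of the overall expression the
#' PVS1_O code applies, with strength equal to the weakest strength among
#' pathogenic transcripts individually contributing more than 10%; the
#' BP7_O code is derived symmetrically from benign-evidence transcripts.
#' Otherwise the assay provides no evidence either way (0 points).
#' Uncharacterized and no-evidence transcripts count toward the expression
#' denominator but carry no evidence.
#'
#' When the share test passes but no single qualifying transcript exceeds
#' 10%, the weakest strength present is used and the result is flagged
#' `extrapolated` (a case the published algorithm leaves open).
#'
#' @param items List of [transcript_evidence()] objects.
#' @param rules Rule configuration.
#' @return An [evidence_strength()] with code `"PVS1_O"`, `"BP7_O"`, and
#'   attribute `extrapolated`.
#' @export
aggregate_readout <- function(items, rules = default_rules()) {
  if (length(items) == 0L) abort("empty readout", "input_error")
  frac <- vapply(items, function(x) x$fraction_percent, 0)
  if (any(frac < 0) || sum(frac) > 100 + rules$aggregation$sum_tolerance)
    abort(sprintf("transcript fractions sum to %.1f%%", sum(frac)),
          "input_error")
  dir <- vapply(items, function(x) x$direction, "")
  strength <- vapply(items, function(x) x$strength, "")
  share_min <- rules$aggregation$share_min_percent
  contrib_min <- rules$aggregation$contributor_min_percent
  pick <- function(direction, code) {
    sel <- dir == direction
    if (sum(frac[sel]) < share_min) return(NULL)
    big <- sel & frac > contrib_min
    extrapolated <- !any(big)
    use <- if (extrapolated) sel else big
    weakest <- names(STRENGTHS)[min(match(strength[use], names(STRENGTHS)))]
    ev <- evidence_strength(code, direction, weakest)
    attr(ev, "extrapolated") <- extrapolated
    ev
  }
  res <- pick("pathogenic", "PVS1_O") %||% pick("benign", "BP7_O")
  if (is.null(res)) {
    res <- evidence_strength("PVS1_O/BP7_O", "none", "not_applicable")
    attr(res, "extrapolated") <- FALSE
  }
  res
}

#' PM2 rarity evidence
#'
#' Supporting-strength PM2 when the allele frequency is at or below the
#' configured ceiling (default 0.01%).
#'
#' @param allele_count,allele_number gnomAD global allele count and number.
#' @param rules Rule configuration.
#' @return An [evidence_strength()] (code `"PM2"` at supporting strength,
#'   printed `"PM2_P (+1)"`, or no evidence).
#' @export
pm2_evidence <- function(allele_count, allele_number, rules = default_rules()) {
  if (!is_count(allele_count) || !is_count(allele_number) || allele_number <= 0)
    abort("allele_count/allele_number must be non-negative, allele_number > 0",
          "input_error")
  if (allele_count / allele_number <= rules$pm2$af_max)
    evidence_strength("PM2", "pathogenic", rules$pm2$strength)
  else
    evidence_strength("PM2", "none", "not_applicable")
}

#' Sum evidence into a clinical category
#'
#' Predictive splicing codes (PVS1, PP3, BP4) are excluded whenever an
#' assay-derived code (PVS1_O/BP7_O) is present: functional codes replace
#' rather than combine with predictive ones.
#'
#' @param variant_id Variant identifier.
#' @param evidence_items List of [evidence_strength()] objects.
#' @param rules Rule configuration.
#' @return An object of class `verdict` with `total_points` and `category`
#'   (`"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`).
#' @export
classify_variant <- function(variant_id, evidence_items, rules = default_rules()) {
  predictive <- c("PVS1", "PP3", "BP4")
  has_assay <- any(vapply(evidence_items, function(e)
    grepl("_O", e$code, fixed = TRUE), NA))
  kept <- Filter(function(e) !(has_assay && e$code %in% predictive),
                 evidence_items)
  total <- sum(vapply(kept, function(e) e$points, 0L))
  cat_ <- rules$categories
  category <- if (total >= cat_$P_min) "P"
    else if (total >= cat_$LP_min) "LP"
    else if (total >= cat_$VUS_min) "VUS"
    else if (total >= cat_$LB_min) "LB"
    else "B"
  structure(list(variant_id = variant_id, evidence_items = kept,
                 total_points = as.integer(total), category = category),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  ev <- paste(vapply(x$evidence_items, format_evidence, ""), collapse = " + ")
  cat(sprintf("<verdict> %s: %s (%+d) [%s]\n", x$variant_id, x$category,
              x$total_points, ev))
  invisible(x)
}
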