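# Tabular readers/writers and the end-to-end classification pipeline.
# All tables are UTF-8 with a header line; readout/verdict tables are
# tab-separated, peak tables comma-separated.

UNCHAR_RE <- "^[0-9]+ ?nt$"

#' Read / write readout tables
#'
#' Readout TSV columns: `variant_id`, `transcript_label`, `mean_percent`,
#' `sd_percent`. Uncharacterized transcripts are labelled by their rounded
#' size with an `nt` suffix (e.g. `"657nt"`).
#'
#' @param path File path.
#' @return `read_readout_table()` returns a `data.frame`.
#' @export
read_readout_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("variant_id", "transcript_label", "mean_percent", "sd_percent")
  if (!all(req %in% names(df)))
    abort(sprintf("%s: readout table needs columns %s", path,
                  paste(req, collapse = ", ")), "io_error")
  for (i in seq_len(nrow(df))) {
    # row numbers reported as file lines (header is line 1)
    if (!grepl(UNCHAR_RE, df$transcript_label[i]))
      tryCatch(parse_label(df$transcript_label[i]), error = function(e)
        abort(sprintf("%s row %d: %s", path, i + 1L, conditionMessage(e)), "io_error"))
    if (is.na(df$mean_percent[i]))
      abort(sprintf("%s row %d: missing mean_percent", path, i + 1L), "io_error")
  }
  df
}

#' @rdname read_readout_table
#' @param readouts List of [readout()] objects or a readout `data.frame`.
#' @param ascii Write ASCII event glyphs instead of Unicode.
#' @export
write_readout_table <- function(readouts, path, ascii = FALSE) {
  if (is.data.frame(readouts)) {
    df <- readouts
  } else {
    df <- do.call(rbind, lapply(readouts, function(r)
      data.frame(variant_id = r$variant_id, transcript_label = r$entries$label,
                 mean_percent = r$entries$mean_percent,
                 sd_percent = r$entries$sd_percent)))
  }
  if (ascii)
    df$transcript_label <- vapply(df$transcript_label, function(lab)
      if (grepl(UNCHAR_RE, lab)) lab else format_label(parse_label(lab), ascii = TRUE),
      "")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a peak table (CSV)
#'
#' Columns: `variant_id`, `replicate`, `size_nt`, `height_rfu`, `area`.
#' @param path File path.
#' @return `data.frame` suitable for [quantify()].
#' @export
read_peak_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("variant_id", "replicate", "size_nt", "height_rfu", "area")
  if (!all(req %in% names(df)))
    abort(sprintf("%s: peak table needs columns %s", path,
                  paste(req, collapse = ", ")), "io_error")
  df
}

lookup_insilico <- function(insilico_df, variant_id, label) {
  if (is.null(insilico_df)) return(NULL)
  hit <- insilico_df$variant_id == variant_id &
    insilico_df$transcript_label == label
  if (!any(hit)) return(NULL)
  row <- insilico_df[which(hit)[1], ]
  list(provean_score = row$provean %||% NA_real_,
       revel_score = row$revel %||% NA_real_)
}

#' Classify a cohort of variants from readouts
#'
#' The end-to-end engine: for each variant of `variant_df`, deconvolutes its
#' readout into transcripts, derives each transcript's consequence on the
#' gene model (the variant is applied to the pre-mRNA, so full-length
#' transcripts of exonic variants carry the missense change), assigns
#' per-transcript evidence, aggregates the readout into a PVS1_O/BP7_O code,
#' adds PM2 rarity evidence from the allele counts, and sums points into a
#' clinical category. Predictive codes present in the table (PVS1/PP3/BP4
#' columns) are carried along but excluded from the sum because assay
#' evidence is present.
#'
#' @param model A [transcript_model()] with sequences.
#' @param readout_df Readout table ([read_readout_table()] format).
#' @param variant_df Variant table with columns `hgvs_c`, `gnomad_ac`,
#'   `gnomad_an`, and optionally `pvs1`, `pp3`.
#' @param insilico_df Optional table `variant_id`, `transcript_label`,
#'   `provean`, `revel`.
#' @param domains Optional [domain_table()].
#' @param rules Rule configuration.
#' @return `data.frame` with one row per variant: `variant_id`,
#'   `assay_code`, `assay_breakdown`, `pm2`, `total_points`, `category`.
#' @export
classify_readouts <- function(model, readout_df, variant_df,
                              insilico_df = NULL, domains = NULL,
                              rules = default_rules()) {
  critical <- if (!is.null(domains))
    domains$entries$domain_name[domains$entries$critical] else NULL
  rows <- lapply(seq_len(nrow(variant_df)), function(i) {
    vid <- variant_df$hgvs_c[i]
    rd <- readout_df[readout_df$variant_id == vid, , drop = FALSE]
    if (nrow(rd) == 0L)
      abort(sprintf("no readout rows for %s", vid), "input_error")
    items <- lapply(seq_len(nrow(rd)), function(j) {
      lab <- rd$transcript_label[j]
      if (grepl(UNCHAR_RE, lab)) {
        cons <- structure(list(isoform = NULL, category = "uncharacterized",
                               domains_lost = character(0),
                               protein_annotation = NA_character_),
                          class = "consequence")
        te <- transcript_evidence(cons, rd$mean_percent[j], rules = rules)
        te$label <- lab
        return(te)
      }
      iso <- parse_label(lab)
      cons <- analyze_consequence(model, iso, variant = vid, domains = domains)
      transcript_evidence(cons, rd$mean_percent[j],
                          insilico = lookup_insilico(insilico_df, vid, lab),
                          rules = rules, critical_domains = critical)
    })
    agg <- aggregate_readout(items, rules)
    pm2 <- pm2_evidence(variant_df$gnomad_ac[i], variant_df$gnomad_an[i], rules)
    extra <- list()
    if (!is.null(variant_df$pvs1) && identical(variant_df$pvs1[i], "PVS1"))
      extra <- c(extra, list(evidence_strength("PVS1", "pathogenic", "very_strong")))
    if (!is.null(variant_df$pp3) && identical(variant_df$pp3[i], "PP3"))
      extra <- c(extra, list(evidence_strength("PP3", "pathogenic", "supporting")))
    verdict <- classify_variant(vid, c(list(agg, pm2), extra), rules)
    breakdown <- paste(vapply(items, function(x)
      sprintf("%s: %.0f%%, %s", x$label, x$fraction_percent, x$evidence), ""),
      collapse = " + ")
    data.frame(variant_id = vid,
               assay_code = format_evidence(agg),
               assay_breakdown = sprintf("[%s]", breakdown),
               pm2 = format_evidence(pm2),
               total_points = verdict$total_points,
               category = verdict$category,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the classification pipeline from files
#'
#' Reads the gene model (JSON), readout table (TSV), variant table (TSV) and
#' optional in-silico / domain / rule files, classifies every variant and
#' writes `verdicts.tsv`, `verdicts.json` and a `provenance.json` block
#' (package version, rule digest, input paths) into `out_dir`. Outputs are
#' written atomically: nothing is left behind on error.
#'
#' @param model_path,readouts_path,variants_path,out_dir Required paths.
#' @param insilico_path,domains_path,rules_path Optional paths.
#' @param ascii Write ASCII event glyphs in the verdict table.
#' @return The verdict `data.frame`, invisibly.
#' @export
run_classify <- function(model_path, readouts_path, variants_path, out_dir,
                         insilico_path = NULL, domains_path = NULL,
                         rules_path = NULL, ascii = FALSE) {
  model <- read_gene_model(model_path)
  readout_df <- read_readout_table(readouts_path)
  variant_df <- read.delim(variants_path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (!all(c("hgvs_c", "gnomad_ac", "gnomad_an") %in% names(variant_df)))
    abort("variant table needs hgvs_c, gnomad_ac, gnomad_an", "io_error")
  insilico_df <- if (!is.null(insilico_path))
    read.delim(insilico_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  domains <- if (!is.null(domains_path)) read_domain_table(domains_path)
  rules <- if (!is.null(rules_path)) read_rules(rules_path) else default_rules()
  if (nrow(variant_df) == 0L) {
    warning("empty variant table: writing empty report")
    verdicts <- data.frame(variant_id = character(0), assay_code = character(0),
                           assay_breakdown = character(0), pm2 = character(0),
                           total_points = integer(0), category = character(0))
  } else {
    verdicts <- classify_readouts(model, readout_df, variant_df, insilico_df,
                                  domains, rules)
  }
  tmp <- tempfile("verdicts_")
  dir.create(tmp)
  out_v <- verdicts
  if (ascii) out_v$assay_breakdown <- gsub(DELTA, "D",
                                           gsub(NABLA, "v", out_v$assay_breakdown))
  write.table(out_v, file.path(tmp, "verdicts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(out_v, file.path(tmp, "verdicts.json"), dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  prov <- list(
    package = "minigeneACMG",
    version = as.character(utils::packageVersion("minigeneACMG")),
    rules_digest = jsonlite::toJSON(rules, auto_unbox = TRUE, digits = NA),
    inputs = list(model = model_path, readouts = readouts_path,
                  variants = variants_path))
  jsonlite::write_json(prov, file.path(tmp, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(tmp))
    file.copy(file.path(tmp, f), file.path(out_dir, f), overwrite = TRUE)
  unlink(tmp, recursive = TRUE)
  invisible(verdicts)
}

#' Classify the shipped RAD51C cohort
#'
#' Convenience wrapper: builds the RAD51C fixture with the synthetic
#' reference, loads the shipped readout/variant/in-silico fixtures and runs
#' [classify_readouts()].
#'
#' @param rules Rule configuration.
#' @return Verdict `data.frame` (20 rows, assayed variants only).
#' @export
rad51c_verdicts <- function(rules = default_rules()) {
  model <- build_rad51c_fixture(sequences = "synthetic")
  readout_df <- rad51c_readouts()
  variant_df <- rad51c_variant_table()
  classify_readouts(model, readout_df, variant_df,
                    insilico_df = rad51c_insilico(),
                    domains = rad51c_domains(), rules = rules)
}
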