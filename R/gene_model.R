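# Transcript gene model: exon architecture in HGVS c. coordinates plus
# optional sequences. Internally all splicing arithmetic works on the virtual
# spliced transcript (0-based half-open); HGVS 1-based positions with signed
# intronic offsets exist only at the I/O boundary.

#' Construct a transcript gene model
#'
#' Represents a single transcript in transcript orientation: ordered,
#' non-overlapping exons in spliced (HGVS c.) coordinates, the CDS extent,
#' and optionally per-exon sequences and intron-flank sequences used for
#' PTC/NMD prediction and intronic-inclusion events.
#'
#' @param gene_symbol Gene symbol, e.g. `"RAD51C"`.
#' @param transcript_id Reference transcript identifier.
#' @param exons `data.frame` with columns `index` (1-based exon number),
#'   `c_start`, `c_end` (inclusive HGVS c. coordinates of the exon).
#' @param cds_end_c Last coding position (the final base of the stop codon).
#'   The CDS starts at c.1 by HGVS convention.
#' @param exon_sequences Optional named list mapping exon index to its
#'   nucleotide sequence (uppercase ACGT, length `c_end - c_start + 1`).
#' @param intron_flanks Optional named list mapping intron index (intron *i*
#'   follows exon *i*) to `list(donor = <5' intron sequence>,
#'   acceptor = <3' intron sequence>)`.
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_symbol, transcript_id, exons, cds_end_c,
                             exon_sequences = NULL, intron_flanks = NULL) {
  stopifnot(is_string(gene_symbol), is_string(transcript_id),
            is.data.frame(exons))
  required <- c("index", "c_start", "c_end")
  if (!all(required %in% names(exons)))
    abort("exons must have columns index, c_start, c_end", "model_error")
  exons <- exons[order(exons$index), required, drop = FALSE]
  if (any(exons$c_end < exons$c_start))
    abort("exon with c_end < c_start", "model_error")
  if (any(diff(exons$c_start) <= 0) ||
      any(exons$c_start[-1] != exons$c_end[-nrow(exons)] + 1L))
    abort("exons must be strictly ordered and contiguous in c. coordinates",
          "model_error")
  if (!is_count(cds_end_c) || cds_end_c > max(exons$c_end))
    abort("cds_end_c outside the transcript", "model_error")
  if (!is.null(exon_sequences)) {
    for (nm in names(exon_sequences)) {
      i <- match(as.integer(nm), exons$index)
      if (is.na(i)) abort(paste0("sequence for unknown exon ", nm), "model_error")
      len <- exons$c_end[i] - exons$c_start[i] + 1L
      if (nchar(exon_sequences[[nm]]) != len)
        abort(sprintf("exon %s sequence length %d != %d", nm,
                      nchar(exon_sequences[[nm]]), len), "model_error")
    }
  }
  structure(list(
    gene_symbol = gene_symbol,
    transcript_id = transcript_id,
    exons = exons,
    cds_start_c = 1L,
    cds_end_c = as.integer(cds_end_c),
    exon_sequences = exon_sequences,
    intron_flanks = intron_flanks
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s): %d exons, CDS c.1-%d%s\n",
              x$gene_symbol, x$transcript_id, nrow(x$exons), x$cds_end_c,
              if (is.null(x$exon_sequences)) ", no sequences" else ", with sequences"))
  print(x$exons, row.names = FALSE)
  invisible(x)
}

exon_length <- function(model, index) {
  i <- match(index, model$exons$index)
  if (any(is.na(i))) abort("unknown exon index", "coordinate_error")
  model$exons$c_end[i] - model$exons$c_start[i] + 1L
}

has_sequences <- function(model) !is.null(model$exon_sequences)

#' Resolve an HGVS c. position against the gene model
#'
#' Maps a position (with optional signed intronic offset) to the exon that
#' contains it, or to the intron and splice-site side it lies in.
#'
#' @param model A [transcript_model()].
#' @param c_pos HGVS c. coordinate (positive integer).
#' @param intron_offset Signed intronic offset; `0` for exonic positions,
#'   positive for donor-side (`c.404+2`), negative for acceptor-side
#'   (`c.146-3`) intronic positions.
#'
#' @return A list with `kind` (`"exon"` or `"intron"`); for exonic loci,
#'   `exon`, `offset_in_exon` (1-based), `from_exon_end` (0 for the last
#'   nucleotide); for intronic loci, `intron`, `side` (`"donor"`/`"acceptor"`)
#'   and `distance` (nucleotides from the splice site).
#' @export
c_to_exon <- function(model, c_pos, intron_offset = 0L) {
  stopifnot(is_count(c_pos))
  ex <- model$exons
  i <- which(ex$c_start <= c_pos & c_pos <= ex$c_end)
  if (length(i) != 1L)
    abort(sprintf("position c.%d outside the transcript model", c_pos),
          "coordinate_error")
  if (intron_offset == 0L) {
    return(list(kind = "exon", exon = ex$index[i],
                offset_in_exon = c_pos - ex$c_start[i] + 1L,
                from_exon_end = ex$c_end[i] - c_pos))
  }
  if (intron_offset > 0L) {
    if (c_pos != ex$c_end[i])
      abort(sprintf("c.%d+%d: donor offsets must be anchored at an exon end",
                    c_pos, intron_offset), "coordinate_error")
    if (i == nrow(ex))
      abort("no intron after the last exon", "coordinate_error")
    list(kind = "intron", intron = ex$index[i], side = "donor",
         distance = as.integer(intron_offset))
  } else {
    if (c_pos != ex$c_start[i])
      abort(sprintf("c.%d%d: acceptor offsets must be anchored at an exon start",
                    c_pos, intron_offset), "coordinate_error")
    if (i == 1L)
      abort("no intron before the first exon", "coordinate_error")
    list(kind = "intron", intron = ex$index[i] - 1L, side = "acceptor",
         distance = as.integer(-intron_offset))
  }
}

#' Map an exonic locus back to its HGVS c. position
#'
#' Inverse of [c_to_exon()] for exonic loci.
#'
#' @param model A [transcript_model()].
#' @param exon Exon index.
#' @param offset_in_exon 1-based offset within the exon.
#' @return The HGVS c. coordinate (integer).
#' @export
exon_to_c <- function(model, exon, offset_in_exon) {
  i <- match(exon, model$exons$index)
  if (is.na(i)) abort("unknown exon index", "coordinate_error")
  pos <- model$exons$c_start[i] + offset_in_exon - 1L
  if (offset_in_exon < 1L || pos > model$exons$c_end[i])
    abort("offset outside exon", "coordinate_error")
  as.integer(pos)
}

#' Functional domain table
#'
#' @param entries `data.frame` with columns `domain_name`, `aa_start`,
#'   `aa_end`, `critical` (logical: is the domain essential so that its loss
#'   is deleterious by itself).
#' @return An object of class `domain_table`.
#' @export
domain_table <- function(entries) {
  req <- c("domain_name", "aa_start", "aa_end", "critical")
  if (!is.data.frame(entries) || !all(req %in% names(entries)))
    abort("domain table needs domain_name, aa_start, aa_end, critical",
          "model_error")
  if (any(entries$aa_end < entries$aa_start))
    abort("domain with aa_end < aa_start", "model_error")
  structure(list(entries = entries[, req, drop = FALSE]), class = "domain_table")
}

#' Read a domain table from TSV
#'
#' Expects columns `domain_name`, `aa_start`, `aa_end`, `critical`.
#' @param path Path to a tab-separated file.
#' @return A [domain_table()].
#' @export
read_domain_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$critical <- as.logical(df$critical)
  domain_table(df)
}

#' Minigene layout
#'
#' Describes which exons of the gene are cloned between the vector exons and
#' how many nucleotides the vector exons plus primers contribute to the
#' RT-PCR amplicon.
#'
#' @param included_exons Integer vector of exon indices present in the
#'   minigene (e.g. `2:8`).
#' @param vector_flank_nt Combined vector/primer contribution to the amplicon
#'   size, in nucleotides.
#' @return An object of class `minigene_layout`.
#' @export
minigene_layout <- function(included_exons, vector_flank_nt) {
  if (!is.numeric(included_exons) || length(included_exons) < 1L)
    abort("included_exons must be a non-empty integer vector", "model_error")
  if (!is_count(vector_flank_nt))
    abort("vector_flank_nt must be a non-negative integer", "model_error")
  structure(list(included_exons = as.integer(included_exons),
                 vector_flank_nt = as.integer(vector_flank_nt)),
            class = "minigene_layout")
}

#' Write / read a gene model as JSON
#'
#' @param model A [transcript_model()].
#' @param path Output (input) file path.
#' @return `write_gene_model()` returns `path` invisibly; `read_gene_model()`
#'   returns a [transcript_model()].
#' @export
write_gene_model <- function(model, path) {
  obj <- list(
    gene_symbol = model$gene_symbol,
    transcript_id = model$transcript_id,
    exons = model$exons,
    cds_end_c = model$cds_end_c,
    exon_sequences = model$exon_sequences,
    intron_flanks = model$intron_flanks
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  flanks <- obj$intron_flanks
  if (!is.null(flanks)) flanks <- lapply(flanks, function(f) list(donor = f$donor, acceptor = f$acceptor))
  transcript_model(obj$gene_symbol, obj$transcript_id, as.data.frame(obj$exons),
                   obj$cds_end_c,
                   exon_sequences = as.list(obj$exon_sequences),
                   intron_flanks = flanks)
}
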