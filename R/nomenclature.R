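# The compact transcript annotation grammar:
#   Delta (exonic deletion), down-triangle (intronic inclusion), E (exon),
#   p (acceptor shift), q (donor shift), with p/q always followed by the
#   number of nucleotides gained or lost at that splice site.
# "FL" denotes the full-length transcript. A "-a"/"-b" suffix distinguishes
# transcripts with the same splice event but different underlying variant
# bases; it is carried verbatim as an opaque allele tag.

DELTA <- "Δ"      # greek capital delta
NABLA <- "▼"      # black down-pointing triangle

EVENT_KINDS <- c("exon_skip",
                 "exonic_deletion_acceptor", "exonic_deletion_donor",
                 "intronic_inclusion_acceptor", "intronic_inclusion_donor")

#' Construct a splice event
#'
#' @param kind One of `"exon_skip"`, `"exonic_deletion_acceptor"` (Delta..p),
#'   `"exonic_deletion_donor"` (Delta..q), `"intronic_inclusion_acceptor"`
#'   (inclusion ..p), `"intronic_inclusion_donor"` (inclusion ..q).
#' @param exon_from,exon_to Exon range; `exon_to > exon_from` only for
#'   multi-exon skips.
#' @param shift_nt Shift size in (spliced) nucleotides; `0` iff whole-exon
#'   skip.
#' @return An object of class `splice_event`.
#' @export
splice_event <- function(kind, exon_from, exon_to = exon_from, shift_nt = 0L) {
  kind <- match.arg(kind, EVENT_KINDS)
  stopifnot(is_count(exon_from), is_count(exon_to), is_count(shift_nt))
  if ((shift_nt == 0L) != (kind == "exon_skip"))
    abort("shift_nt must be 0 exactly for whole-exon skips", "parse_error")
  if (exon_to < exon_from)
    abort("exon_to < exon_from", "parse_error")
  if (exon_to > exon_from && kind != "exon_skip")
    abort("multi-exon ranges only for exon skips", "parse_error")
  structure(list(kind = kind, exon_from = as.integer(exon_from),
                 exon_to = as.integer(exon_to), shift_nt = as.integer(shift_nt)),
            class = "splice_event")
}

#' Construct an isoform label
#'
#' @param events List of [splice_event()]s; empty list = full-length.
#' @param allele_tag Optional allele tag (`"a"`, `"b"`, ...), without the dash.
#' @param raw_label Original text, if the label was parsed.
#' @return An object of class `isoform_label`.
#' @export
isoform_label <- function(events = list(), allele_tag = NULL, raw_label = NULL) {
  stopifnot(is.list(events))
  for (e in events) if (!inherits(e, "splice_event"))
    abort("events must be splice_event objects", "parse_error")
  structure(list(events = events, allele_tag = allele_tag,
                 raw_label = raw_label), class = "isoform_label")
}

is_full_length <- function(iso) length(iso$events) == 0L

#' Parse a transcript label
#'
#' Accepts the canonical Unicode glyphs as well as ASCII aliases on input
#' (`"D"`/`"d"` for the deletion glyph, `"v"`/`"V"` for the inclusion glyph);
#' [format_label()] always emits the canonical Unicode form. Several
#' concatenated event groups are allowed, e.g. `"D(E2p3)D(E5)"`.
#'
#' @param label Text such as `"FL"`, `"Δ(E2p3)"`, `"▼(E6q4)-a"`,
#'   `"Δ(E4_5)"`.
#' @return An [isoform_label()].
#' @export
parse_label <- function(label) {
  stopifnot(is_string(label))
  raw <- label
  x <- gsub("\\s+", "", label)
  if (toupper(x) == "FL") return(isoform_label(raw_label = raw))
  tag <- NULL
  tag_m <- regmatches(x, regexec("-([A-Za-z][A-Za-z0-9]*)$", x))[[1]]
  if (length(tag_m) == 2L) {
    tag <- tag_m[2]
    x <- sub("-[A-Za-z][A-Za-z0-9]*$", "", x)
  }
  group_re <- paste0("^([", DELTA, NABLA, "DdVv])?\\(E([0-9]+)(_([0-9]+))?([pq])?([0-9]+)?\\)")
  events <- list()
  while (nchar(x) > 0L) {
    m <- regmatches(x, regexec(group_re, x))[[1]]
    if (length(m) == 0L)
      abort(sprintf("malformed transcript label near \"%s\" in \"%s\"", x, raw),
            "parse_error")
    glyph <- m[2]; e_from <- as.integer(m[3])
    e_to <- if (m[5] == "") e_from else as.integer(m[5])
    side <- m[6]; nt <- if (m[7] == "") NA_integer_ else as.integer(m[7])
    if (glyph == "") glyph <- "D"  # tolerated: bare "(E2q175)" style deletions
    is_del <- glyph %in% c(DELTA, "D", "d")
    is_inc <- glyph %in% c(NABLA, "V", "v")
    if (!is_del && !is_inc)
      abort(sprintf("unknown event glyph \"%s\" in \"%s\"", glyph, raw), "parse_error")
    if (side == "") {
      if (!is.na(nt))
        abort(sprintf("shift size without p/q in \"%s\"", raw), "parse_error")
      if (is_inc)
        abort(sprintf("intronic inclusion needs a p or q shift in \"%s\"", raw),
              "parse_error")
      ev <- splice_event("exon_skip", e_from, e_to)
    } else {
      if (is.na(nt) || nt < 1L)
        abort(sprintf("p/q must be followed by a positive size in \"%s\"", raw),
              "parse_error")
      if (e_to != e_from)
        abort(sprintf("p/q shifts apply to a single exon in \"%s\"", raw),
              "parse_error")
      kind <- if (is_del) {
        if (side == "p") "exonic_deletion_acceptor" else "exonic_deletion_donor"
      } else {
        if (side == "p") "intronic_inclusion_acceptor" else "intronic_inclusion_donor"
      }
      ev <- splice_event(kind, e_from, e_from, nt)
    }
    events[[length(events) + 1L]] <- ev
    x <- substr(x, nchar(m[1]) + 1L, nchar(x))
  }
  isoform_label(events, allele_tag = tag, raw_label = raw)
}

#' Serialize an isoform label to canonical text
#'
#' Inverse of [parse_label()]: `parse_label(format_label(x))` recovers `x`.
#'
#' @param isoform An [isoform_label()].
#' @param ascii Use ASCII aliases (`D`/`v`) instead of the Unicode glyphs.
#' @return Character scalar.
#' @export
format_label <- function(isoform, ascii = FALSE) {
  stopifnot(inherits(isoform, "isoform_label"))
  if (is_full_length(isoform)) return("FL")
  del <- if (ascii) "D" else DELTA
  inc <- if (ascii) "v" else NABLA
  fmt1 <- function(e) {
    rng <- if (e$exon_to > e$exon_from)
      sprintf("E%d_%d", e$exon_from, e$exon_to) else sprintf("E%d", e$exon_from)
    switch(e$kind,
      exon_skip = sprintf("%s(%s)", del, rng),
      exonic_deletion_acceptor = sprintf("%s(%sp%d)", del, rng, e$shift_nt),
      exonic_deletion_donor = sprintf("%s(%sq%d)", del, rng, e$shift_nt),
      intronic_inclusion_acceptor = sprintf("%s(%sp%d)", inc, rng, e$shift_nt),
      intronic_inclusion_donor = sprintf("%s(%sq%d)", inc, rng, e$shift_nt))
  }
  out <- paste(vapply(isoform$events, fmt1, ""), collapse = "")
  if (!is.null(isoform$allele_tag)) out <- paste0(out, "-", isoform$allele_tag)
  out
}

#' @export
print.isoform_label <- function(x, ...) {
  cat("<isoform_label>", format_label(x), "\n")
  invisible(x)
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<splice_event> %s E%d%s shift %d nt\n", x$kind, x$exon_from,
              if (x$exon_to > x$exon_from) paste0("_", x$exon_to) else "",
              x$shift_nt))
  invisible(x)
}

#' Classify the splice-site side of an event
#'
#' Returns `"skip"`, `"acceptor"` or `"donor"` for each event of a label;
#' used for event-taxonomy summaries.
#' @param isoform An [isoform_label()].
#' @return Character vector, one element per event.
#' @export
event_side <- function(isoform) {
  vapply(isoform$events, function(e) switch(e$kind,
    exon_skip = "skip",
    exonic_deletion_acceptor = , intronic_inclusion_acceptor = "acceptor",
    exonic_deletion_donor = , intronic_inclusion_donor = "donor"), "")
}
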