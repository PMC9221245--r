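# Apply a DNA variant plus a splice-event set to the gene model and derive
# the mature mRNA, reading frame, PTC position, NMD susceptibility and a
# best-effort HGVS p. annotation.
#
# Conventions:
#  * The variant is applied to the pre-mRNA before splicing, so variant
#    bases inside retained exonic sequence or inside an included intronic
#    segment appear in the mature transcript; bases in excised regions
#    vanish.
#  * Consequences are evaluated in native full-transcript context; amplicon
#    sizes are evaluated in minigene context with the vector flank added.
#  * NMD: a PTC ending more than 50 nt upstream of the transcript's last
#    exon-exon junction is predicted to trigger decay (50-nt boundary rule).

NMD_BOUNDARY_NT <- 50L

# per-nucleotide representation of a mature transcript: data.frame with the
# pre-mRNA ordering key, block id (junctions fall between blocks) and base.
mature_positions <- function(model, isoform, exon_set) {
  ex <- model$exons
  keep <- ex$index %in% exon_set
  starts <- setNames(ex$c_start, ex$index)
  ends <- setNames(ex$c_end, ex$index)
  incl <- list()  # per exon: data.frame rows to prepend/append
  for (e in isoform$events) {
    if (!all(seq(e$exon_from, e$exon_to) %in% exon_set))
      abort(sprintf("event references exon %d absent from context", e$exon_from),
            "coordinate_error")
    k <- as.character(e$exon_from)
    switch(e$kind,
      exon_skip = { keep[ex$index %in% seq(e$exon_from, e$exon_to)] <- FALSE },
      exonic_deletion_acceptor = { starts[k] <- starts[k] + e$shift_nt },
      exonic_deletion_donor = { ends[k] <- ends[k] - e$shift_nt },
      intronic_inclusion_acceptor = {
        incl[[k]] <- c(incl[[k]], list(list(where = "before",
          intron = e$exon_from - 1L, side = "acceptor", n = e$shift_nt)))
      },
      intronic_inclusion_donor = {
        incl[[k]] <- c(incl[[k]], list(list(where = "after",
          intron = e$exon_from, side = "donor", n = e$shift_nt)))
      })
    if (e$kind %in% c("exonic_deletion_acceptor", "exonic_deletion_donor") &&
        starts[k] > ends[k] + 1L)
      abort(sprintf("shift of %d nt exceeds exon %d", e$shift_nt, e$exon_from),
            "coordinate_error")
  }
  rows <- list()
  for (i in which(keep)) {
    k <- as.character(ex$index[i])
    blk <- ex$index[i]
    pre <- Filter(function(x) x$where == "before", incl[[k]] %||% list())
    post <- Filter(function(x) x$where == "after", incl[[k]] %||% list())
    for (p in pre) {
      # last n nucleotides of the upstream intron, offsets -n..-1 anchored
      # at the natural exon start
      rows[[length(rows) + 1L]] <- data.frame(
        block = blk, kind = "intron", intron = p$intron,
        anchor_c = ex$c_start[i], offset = seq(-p$n, -1L), c_pos = NA_integer_)
    }
    if (starts[k] <= ends[k]) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = blk, kind = "exon", intron = NA_integer_,
        anchor_c = NA_integer_, offset = 0L, c_pos = seq(starts[k], ends[k]))
    }
    for (p in post) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = blk, kind = "intron", intron = p$intron,
        anchor_c = ex$c_end[i], offset = seq_len(p$n), c_pos = NA_integer_)
    }
  }
  if (length(rows) == 0L) abort("empty mature transcript", "coordinate_error")
  do.call(rbind, rows)
}

position_base <- function(model, pos) {
  # reference base at one mature position row
  if (pos$kind == "exon") {
    loc <- c_to_exon(model, pos$c_pos)
    seqs <- model$exon_sequences
    if (is.null(seqs)) return(NA_character_)
    substr(seqs[[as.character(loc$exon)]], loc$offset_in_exon, loc$offset_in_exon)
  } else {
    fl <- model$intron_flanks[[as.character(pos$intron)]]
    if (is.null(fl)) abort(sprintf("no flank sequence for intron %d", pos$intron),
                           "sequence_required")
    if (pos$offset > 0L) {
      if (pos$offset > nchar(fl$donor))
        abort(sprintf("inclusion exceeds stored donor flank of intron %d",
                      pos$intron), "sequence_required")
      substr(fl$donor, pos$offset, pos$offset)
    } else {
      j <- nchar(fl$acceptor) + pos$offset + 1L
      if (j < 1L)
        abort(sprintf("inclusion exceeds stored acceptor flank of intron %d",
                      pos$intron), "sequence_required")
      substr(fl$acceptor, j, j)
    }
  }
}

# total order over pre-mRNA coordinates: exonic position p has key p;
# intronic offsets interleave just after (donor) / before (acceptor) their
# anchor exon boundary
premrna_key <- function(c_pos, offset) c_pos + offset / 1000

#' Apply a splice isoform (and optionally a variant) to the gene model
#'
#' Reconstructs the mature transcript that a given isoform label describes,
#' with the variant applied to the pre-mRNA first. Returns sequence when the
#' model carries sequences, and length accounting always.
#'
#' @param model A [transcript_model()].
#' @param isoform An [isoform_label()] (or label text).
#' @param variant Optional [parse_variant()] result or HGVS string.
#' @param context `"native"` (all exons of the model) or `"minigene"`
#'   (exons of `layout`, with the vector flank added to the amplicon size).
#' @param layout A [minigene_layout()]; required for minigene context.
#' @return A list of class `mature_transcript` with `length_nt`,
#'   `net_length_change_nt`, `sequence` (or `NA`), `junctions` (mature
#'   positions after which a splice junction lies), `cds_start` (mature
#'   position of c.1, native context only), `native_stop_end` (mature
#'   position of the last base of the reference stop codon, if retained) and
#'   `amplicon_size_nt` (minigene context).
#' @export
apply_isoform <- function(model, isoform, variant = NULL,
                          context = c("native", "minigene"), layout = NULL) {
  context <- match.arg(context)
  if (is.character(isoform)) isoform <- parse_label(isoform)
  if (is.character(variant)) variant <- parse_variant(variant)
  exon_set <- if (context == "minigene") {
    if (is.null(layout)) abort("minigene context needs a layout", "model_error")
    layout$included_exons
  } else model$exons$index

  pos <- mature_positions(model, isoform, exon_set)
  ref_len <- {
    i <- model$exons$index %in% exon_set
    sum(model$exons$c_end[i] - model$exons$c_start[i] + 1L)
  }

  with_seq <- has_sequences(model)
  if (with_seq) {
    # exon coordinates are contiguous in c., so one concatenated character
    # vector serves as a direct lookup; intron flanks handled per segment
    spliced <- strsplit(paste(vapply(as.character(model$exons$index), function(k)
      model$exon_sequences[[k]], ""), collapse = ""), "")[[1]]
    pos$base <- NA_character_
    ex_rows <- pos$kind == "exon"
    pos$base[ex_rows] <- spliced[pos$c_pos[ex_rows]]
    for (i in which(!ex_rows)) pos$base[i] <- position_base(model, pos[i, ])
  } else {
    # inclusions still need flanks when present in the model; length-only
    # models simply account for lengths
    pos$base <- NA_character_
  }

  # apply the variant to the pre-mRNA representation
  if (!is.null(variant)) {
    key <- premrna_key(ifelse(pos$kind == "exon", pos$c_pos, pos$anchor_c),
                       pos$offset)
    k1 <- premrna_key(variant$start$c_pos, variant$start$intron_offset)
    k2 <- premrna_key(variant$end$c_pos, variant$end$intron_offset)
    hit <- key >= min(k1, k2) & key <= max(k1, k2)
    if (variant$type == "substitution") {
      if (any(hit)) {
        if (with_seq && !is.na(pos$base[hit][1]) &&
            pos$base[hit][1] != variant$ref)
          warning(sprintf("%s: reference base is %s in the model",
                          variant$hgvs_c, pos$base[hit][1]))
        pos$base[hit] <- variant$alt
      }
    } else {
      ins <- NULL
      if (variant$type == "delins" && any(hit)) {
        at <- which(hit)[1]
        ins <- data.frame(block = pos$block[at], kind = pos$kind[at],
                          intron = pos$intron[at], anchor_c = pos$anchor_c[at],
                          offset = pos$offset[at],
                          c_pos = pos$c_pos[at],
                          base = strsplit(variant$alt, "")[[1]])
        pre <- pos[seq_len(at - 1L), , drop = FALSE]
        post <- pos[setdiff(which(!hit), seq_len(at - 1L)), , drop = FALSE]
        pos <- rbind(pre, ins, post)
      } else {
        pos <- pos[!hit, , drop = FALSE]
      }
    }
  }

  n <- nrow(pos)
  blocks <- rle(pos$block)$lengths
  junctions <- cumsum(blocks)
  junctions <- junctions[-length(junctions)]
  seqchr <- if (with_seq) paste(pos$base, collapse = "") else NA_character_
  cds_start <- NA_integer_
  native_stop_end <- NA_integer_
  if (context == "native") {
    i <- which(pos$kind == "exon" & pos$c_pos == model$cds_start_c)
    if (length(i) == 1L) cds_start <- i
    j <- which(pos$kind == "exon" & pos$c_pos == model$cds_end_c)
    if (length(j) == 1L) native_stop_end <- j
  }
  structure(list(
    isoform = isoform, variant = variant, context = context,
    length_nt = n, net_length_change_nt = n - ref_len,
    sequence = seqchr, junctions = junctions,
    cds_start = cds_start, native_stop_end = native_stop_end,
    amplicon_size_nt = if (context == "minigene")
      n + layout$vector_flank_nt else NA_integer_
  ), class = "mature_transcript")
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "*")

translate_nt <- function(seqchr) {
  # translate from the first base; trailing partial codon dropped
  n <- nchar(seqchr) - nchar(seqchr) %% 3L
  if (n < 3L) return(character(0))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seqchr, 1L, n)),
    if.fuzzy.codon = "solve"))
  strsplit(aa, "")[[1]]
}

first_stop_scan <- function(aa) {
  i <- which(aa == "*")
  if (length(i) == 0L) NA_integer_ else i[1]
}

# HGVS p.-style annotation from native vs edited protein (1-letter vectors,
# stop excluded), with `fs` handling driven by the ptc flag
protein_annotation <- function(native, edited, frameshift_ptc = FALSE) {
  if (identical(native, edited)) return("p.(=)")
  n_n <- length(native); n_e <- length(edited)
  i <- 0L
  while (i < min(n_n, n_e) && native[i + 1L] == edited[i + 1L]) i <- i + 1L
  if (frameshift_ptc) {
    r <- i + 1L
    if (r > n_e)  # stop codon right at the first changed position
      return(sprintf("p.%s%d*", AA3[[native[r]]], r))
    return(sprintf("p.%s%d%sFs*%d", AA3[[native[r]]], r, AA3[[edited[r]]],
                   n_e - i + 1L))
  }
  s <- 0L
  while (s < min(n_n, n_e) - i && native[n_n - s] == edited[n_e - s]) s <- s + 1L
  nat_mid <- if (i + 1L <= n_n - s) native[(i + 1L):(n_n - s)] else character(0)
  ed_mid <- if (i + 1L <= n_e - s) edited[(i + 1L):(n_e - s)] else character(0)
  r1 <- i + 1L; r2 <- n_n - s
  if (length(ed_mid) == 0L) {          # pure deletion
    if (length(nat_mid) == 1L)
      return(sprintf("p.%s%ddel", AA3[[nat_mid]], r1))
    return(sprintf("p.%s%d_%s%ddel", AA3[[nat_mid[1]]], r1,
                   AA3[[nat_mid[length(nat_mid)]]], r2))
  }
  ins <- paste(AA3[ed_mid], collapse = "")
  if (length(nat_mid) == 0L)           # pure insertion between r1-1 and r1
    return(sprintf("p.%s%d_%s%dins%s", AA3[[native[i]]], i,
                   AA3[[native[i + 1L]]], i + 1L, ins))
  if (length(nat_mid) == 1L && length(ed_mid) == 1L)
    return(sprintf("p.%s%d%s", AA3[[nat_mid]], r1, AA3[[ed_mid]]))
  if (length(nat_mid) == 1L)
    return(sprintf("p.%s%ddelins%s", AA3[[nat_mid]], r1, ins))
  sprintf("p.%s%d_%s%ddelins%s", AA3[[nat_mid[1]]], r1,
          AA3[[nat_mid[length(nat_mid)]]], r2, ins)
}

#' Derive the transcript-level consequence of a variant + isoform
#'
#' Reconstructs the mature mRNA in native context, scans for the first
#' in-frame stop codon, applies the 50-nt NMD boundary rule against the
#' transcript's own last exon-exon junction, annotates the protein product
#' and lists functional domains lost.
#'
#' Domain-loss logic: an in-frame deletion loses the domains fully contained
#' in the deleted residue range; a truncating change (frameshift or PTC)
#' loses every domain whose end lies at or after the first altered residue.
#'
#' Without sequences the function degrades to frame arithmetic:
#' `ptc_present`/`nmd_predicted` are `NA` and the category is
#' `"uncharacterized"` for aberrant isoforms.
#'
#' @param model A [transcript_model()] (sequences required for PTC/NMD).
#' @param isoform [isoform_label()] or label text.
#' @param variant Optional [parse_variant()] result or HGVS string.
#' @param domains Optional [domain_table()].
#' @return An object of class `consequence` with fields `isoform`,
#'   `net_length_change_nt`, `frame_preserved`, `ptc_present`, `ptc_c_index`
#'   (mature-transcript position of the PTC's last base), `nmd_predicted`,
#'   `protein_annotation`, `domains_lost`, `category` (one of `"FL"`,
#'   `"PTC_NMD"`, `"PTC_escape"`, `"in_frame"`, `"uncharacterized"`).
#' @export
analyze_consequence <- function(model, isoform, variant = NULL, domains = NULL) {
  if (is.character(isoform)) isoform <- parse_label(isoform)
  mt <- apply_isoform(model, isoform, variant, context = "native")
  frame_preserved <- mt$net_length_change_nt %% 3L == 0L
  out <- list(isoform = isoform, variant = mt$variant,
              net_length_change_nt = mt$net_length_change_nt,
              frame_preserved = frame_preserved,
              ptc_present = NA, ptc_c_index = NA_integer_,
              nmd_predicted = NA, protein_annotation = NA_character_,
              domains_lost = character(0),
              category = if (is_full_length(isoform)) "FL" else "uncharacterized")
  if (!has_sequences(model)) {
    if (!frame_preserved) out$protein_annotation <- "p.fs?"
    return(structure(out, class = "consequence"))
  }
  if (is.na(mt$cds_start))
    abort("CDS start absent from the mature transcript", "sequence_required")
  edited_aa_full <- translate_nt(substr(mt$sequence, mt$cds_start, mt$length_nt))
  stop_i <- first_stop_scan(edited_aa_full)
  native_mt <- apply_isoform(model, isoform_label(), context = "native")
  native_aa_full <- translate_nt(substr(native_mt$sequence, native_mt$cds_start,
                                        native_mt$length_nt))
  native_stop <- first_stop_scan(native_aa_full)
  native_aa <- native_aa_full[seq_len(native_stop - 1L)]

  if (is.na(stop_i)) {
    out$ptc_present <- NA
    out$protein_annotation <- "p.?"
    return(structure(out, class = "consequence"))
  }
  stop_end <- mt$cds_start - 1L + stop_i * 3L   # mature position of stop's last base
  out$ptc_present <- if (!is.na(mt$native_stop_end)) stop_end < mt$native_stop_end
                     else TRUE
  out$ptc_c_index <- stop_end
  edited_aa <- edited_aa_full[seq_len(stop_i - 1L)]

  if (isTRUE(out$ptc_present)) {
    last_junction <- if (length(mt$junctions)) max(mt$junctions) else 0L
    out$nmd_predicted <- (last_junction - stop_end) > NMD_BOUNDARY_NT
  }
  fs_ptc <- isTRUE(out$ptc_present) && !frame_preserved
  out$protein_annotation <- protein_annotation(native_aa, edited_aa,
                                               frameshift_ptc = fs_ptc)
  # in-frame PTC (e.g. a stop codon inside an included intronic segment) is
  # annotated as a truncation
  if (isTRUE(out$ptc_present) && frame_preserved && !fs_ptc &&
      !identical(native_aa, edited_aa)) {
    i <- 0L
    while (i < min(length(native_aa), length(edited_aa)) &&
           native_aa[i + 1L] == edited_aa[i + 1L]) i <- i + 1L
    out$protein_annotation <- if (i + 1L > length(edited_aa))
      sprintf("p.%s%d*", AA3[[native_aa[i + 1L]]], i + 1L)
    else sprintf("p.%s%d%sFs*%d", AA3[[native_aa[i + 1L]]], i + 1L,
                 AA3[[edited_aa[i + 1L]]], length(edited_aa) - i + 1L)
  }

  if (!is.null(domains)) {
    dt <- domains$entries
    if (isTRUE(out$ptc_present)) {
      i <- 0L
      while (i < min(length(native_aa), length(edited_aa)) &&
             native_aa[i + 1L] == edited_aa[i + 1L]) i <- i + 1L
      first_changed <- i + 1L
      out$domains_lost <- dt$domain_name[dt$aa_end >= first_changed]
    } else if (length(edited_aa) < length(native_aa)) {
      # in-frame deletion: recompute the deleted residue range
      i <- 0L
      while (i < length(edited_aa) && native_aa[i + 1L] == edited_aa[i + 1L]) i <- i + 1L
      k <- length(native_aa) - length(edited_aa)
      del_range <- seq(i + 1L, i + k)
      out$domains_lost <- dt$domain_name[dt$aa_start >= min(del_range) &
                                         dt$aa_end <= max(del_range)]
    }
  }

  out$category <- if (is_full_length(isoform)) "FL"
    else if (isTRUE(out$ptc_present) && isTRUE(out$nmd_predicted)) "PTC_NMD"
    else if (isTRUE(out$ptc_present)) "PTC_escape"
    else "in_frame"
  structure(out, class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("<consequence> %s: %+d nt, %s%s%s\n",
              format_label(x$isoform), x$net_length_change_nt, x$category,
              if (!is.na(x$protein_annotation)) paste0(", ", x$protein_annotation) else "",
              if (length(x$domains_lost))
                paste0(", loses ", paste(x$domains_lost, collapse = "+")) else ""))
  invisible(x)
}
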