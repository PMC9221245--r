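# Independent oracles and shared fixtures for the test suite. These
# re-derive expected behaviour through a different route than the package
# code they check.

# every transcript label printed with the assayed cohort (published readout
# tables), including the uncharacterized-by-size tags
published_readout_labels <- function() {
  rd <- rad51c_readouts()
  unique(rd$transcript_label)
}

# characterized aberrant labels of the assayed cohort
aberrant_labels <- function() {
  rd <- rad51c_readouts()
  labs <- unique(rd$transcript_label)
  labs[labs != "FL" & !grepl("^[0-9]+ ?nt$", labs)]
}

# labels from the 40-variant summary table (previous + current cohorts)
summary_table_labels <- c(
  "Δ(E2)", "Δ(E2p3)", "▼(E2q27)", "Δ(E2q175)", "Δ(E2q22)", "▼(E3p4)",
  "Δ(E3)", "Δ(E3q1)", "▼(E3q4)", "Δ(E3q114)", "Δ(E4)", "Δ(E4_5)",
  "Δ(E5p10)", "Δ(E5)", "Δ(E5p52)", "Δ(E6)", "▼(E6q4)", "Δ(E7)", "Δ(E7_8)",
  "Δ(E8)", "▼(E8p3)", "Δ(E8q18)", "▼(E8q41)", "▼(E8q44)", "FL"
)

# brute-force re-implementation of the readout-aggregation rules, written
# directly from the rule statement: pathogenic (benign) transcripts must
# reach >= 90% of overall expression; the code strength is the weakest
# strength among same-direction transcripts individually above 10%
oracle_aggregate <- function(fractions, directions, strengths) {
  rank <- c(supporting = 1, moderate = 2, strong = 3, very_strong = 4)
  for (side in c("pathogenic", "benign")) {
    tot <- sum(fractions[directions == side])
    if (tot >= 90) {
      over <- directions == side & fractions > 10
      pool <- if (any(over)) strengths[over] else strengths[directions == side]
      return(list(code = if (side == "pathogenic") "PVS1_O" else "BP7_O",
                  strength = names(rank)[min(rank[pool])]))
    }
  }
  list(code = NA_character_, strength = "not_applicable")
}

# independent NMD check: scan a mature transcript sequence codon by codon
# with a plain loop and compare the stop position against the last junction
oracle_nmd <- function(seqchr, cds_start, junctions) {
  i <- cds_start
  stops <- c("TAA", "TAG", "TGA")
  while (i + 2 <= nchar(seqchr)) {
    if (substr(seqchr, i, i + 2) %in% stops) {
      last_j <- if (length(junctions)) max(junctions) else 0
      return(list(stop_end = as.integer(i + 2), nmd = (last_j - (i + 2)) > 50))
    }
    i <- i + 3
  }
  list(stop_end = NA_integer_, nmd = NA)
}

random_splice_event <- function(n_exons) {
  kind <- sample(c("exon_skip", "exonic_deletion_acceptor",
                   "exonic_deletion_donor", "intronic_inclusion_acceptor",
                   "intronic_inclusion_donor"), 1)
  if (kind == "exon_skip") {
    from <- sample(2:(n_exons - 1), 1)
    to <- min(n_exons - 1, from + sample(0:1, 1))
    splice_event(kind, from, to)
  } else {
    splice_event(kind, sample(2:(n_exons - 1), 1), shift_nt = sample(1:30, 1))
  }
}
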