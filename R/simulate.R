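# Seeded synthetic-data generator: random gene models with canonical
# splice dinucleotides and an open reading frame, and simulated fragment
# readouts (peak tables) with multiplicative lognormal replicate noise and
# known ground truth, so every pipeline stage is testable without external
# data.

with_seed <- function(seed, code) {
  # all randomness flows through the supplied seed; global RNG state is
  # preserved
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA", "ATG"))
}

#' Simulation configuration
#'
#' Defaults emulate the structure of the published readouts: triplicate
#' fluorescent RT-PCR with per-replicate coefficients of variation around
#' 2% (published SDs are mostly below 2 percentage points), a major
#' aberrant transcript plus a minor one plus a trace transcript, and peak
#' heights scaled so a 100% transcript reads `rfu_baseline` RFU.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_exons Number of exons of the simulated gene (>= 3).
#' @param exon_length_range Min/max exon length in nt.
#' @param intron_flank_length Stored intron flank length, nt.
#' @param true_isoform_fractions Percentages summing to 100; the first is
#'   the full-length transcript, the rest are single-exon skips of exons
#'   2, 3, ...
#' @param replicate_noise_cv Coefficient of variation of peak areas.
#' @param n_replicates Number of replicates.
#' @param rfu_baseline Peak height of a 100% transcript, RFU.
#' @return A validated configuration list.
#' @export
simulation_config <- function(seed = 1L, n_exons = 9L,
                              exon_length_range = c(61L, 259L),
                              intron_flank_length = 40L,
                              true_isoform_fractions = c(73.8, 25.1, 1.1),
                              replicate_noise_cv = 0.02,
                              n_replicates = 3L,
                              rfu_baseline = 30000) {
  stopifnot(is_count(abs(seed)), n_exons >= 3L,
            length(exon_length_range) == 2L,
            exon_length_range[1] >= 10L,
            exon_length_range[2] >= exon_length_range[1],
            replicate_noise_cv >= 0, n_replicates >= 1L, rfu_baseline > 0)
  if (abs(sum(true_isoform_fractions) - 100) > 1e-6)
    abort("true_isoform_fractions must sum to 100", "input_error")
  if (length(true_isoform_fractions) > n_exons - 1L)
    abort("more isoforms than skippable exons", "input_error")
  list(seed = as.integer(seed), n_exons = as.integer(n_exons),
       exon_length_range = as.integer(exon_length_range),
       intron_flank_length = as.integer(intron_flank_length),
       true_isoform_fractions = true_isoform_fractions,
       replicate_noise_cv = replicate_noise_cv,
       n_replicates = as.integer(n_replicates),
       rfu_baseline = rfu_baseline)
}

#' Simulate a gene model with sequences
#'
#' Random exon lengths in the configured range (adjusted so the CDS length
#' is a multiple of three), a start codon at c.1, no premature stop codon in
#' the full-length frame, a terminal stop codon, and canonical GT..AG intron
#' flanks. Reproducible under the configuration seed.
#'
#' @param config A [simulation_config()].
#' @return A [transcript_model()] with sequences.
#' @export
simulate_gene <- function(config) {
  with_seed(config$seed, {
    n <- config$n_exons
    lens <- sample(seq(config$exon_length_range[1], config$exon_length_range[2]),
                   n, replace = TRUE)
    total <- sum(lens)
    lens[n] <- lens[n] + (3L - total %% 3L) %% 3L
    total <- sum(lens)
    codons <- c("ATG", sample(NONSTOP_CODONS, total %/% 3L - 2L, replace = TRUE),
                "TAA")
    seqchr <- paste(codons, collapse = "")
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    exon_seq <- lapply(seq_len(n), function(i) substr(seqchr, starts[i], ends[i]))
    names(exon_seq) <- as.character(seq_len(n))
    fl <- config$intron_flank_length
    rand_nt <- function(k) paste(sample(c("A", "C", "G"), k, replace = TRUE),
                                 collapse = "")
    flanks <- lapply(seq_len(n - 1L), function(i)
      list(donor = paste0("GT", rand_nt(fl - 2L)),
           acceptor = paste0(rand_nt(fl - 2L), "AG")))
    names(flanks) <- as.character(seq_len(n - 1L))
    transcript_model("SIMGENE", sprintf("SIM_%06d.1", config$seed),
                     data.frame(index = seq_len(n), c_start = starts, c_end = ends),
                     cds_end_c = total, exon_sequences = exon_seq,
                     intron_flanks = flanks)
  })
}

#' Simulate a fragment-analysis readout with ground truth
#'
#' Isoforms default to the full-length transcript plus single-exon skips of
#' exons 2, 3, ... matching the configured fraction vector. Per replicate,
#' each transcript's peak area is its true fraction times a multiplicative
#' lognormal noise factor (`cv`); peak heights scale with the noisy
#' fraction so that configuring a small `rfu_baseline` pushes trace peaks
#' below the 200 RFU cutoff. Peak sizes get a +/-0.3 nt calling jitter.
#'
#' @param model A [transcript_model()] (e.g. from [simulate_gene()]).
#' @param config A [simulation_config()].
#' @param layout Optional [minigene_layout()]; defaults to the internal
#'   exons of `model` with a 181-nt vector flank.
#' @param isoforms Optional list of labels overriding the defaults.
#' @return A list with `peaks` (data.frame for [quantify()]), `truth`
#'   (data.frame `label`, `true_percent`), `expected`
#'   (from [expected_sizes()]) and `layout`.
#' @export
simulate_readout <- function(model, config, layout = NULL, isoforms = NULL) {
  n_exons <- nrow(model$exons)
  if (is.null(layout))
    layout <- minigene_layout(2:(n_exons - 1L), 181L)
  fr <- config$true_isoform_fractions
  if (is.null(isoforms)) {
    skips <- lapply(seq_len(length(fr) - 1L) + 1L, function(k)
      isoform_label(list(splice_event("exon_skip", k))))
    isoforms <- c(list(isoform_label()), skips)
  }
  for (iso in isoforms) {
    ek <- unlist(lapply(iso$events, function(e) seq(e$exon_from, e$exon_to)))
    if (!all(ek %in% layout$included_exons))
      abort("isoform references an exon outside the minigene layout",
            "coordinate_error")
  }
  exp_sizes <- expected_sizes(model, layout, isoforms)
  with_seed(config$seed + 1L, {
    cv <- config$replicate_noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    rows <- list()
    for (r in seq_len(config$n_replicates)) {
      noise <- if (cv > 0) rlnorm(length(fr), -sdlog^2 / 2, sdlog) else rep(1, length(fr))
      area <- fr / 100 * 1e5 * noise
      height <- config$rfu_baseline * (fr / 100) * noise
      size <- exp_sizes$size_nt + runif(length(fr), -0.3, 0.3)
      rows[[r]] <- data.frame(variant_id = "sim", replicate = r,
                              size_nt = size, height_rfu = height, area = area)
    }
    list(peaks = do.call(rbind, rows),
         truth = data.frame(label = exp_sizes$label, true_percent = fr),
         expected = exp_sizes, layout = layout)
  })
}
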