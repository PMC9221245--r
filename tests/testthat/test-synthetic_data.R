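test_that("simulate_gene is reproducible and structurally sound", {
  cfg <- simulation_config(seed = 17L)
  m1 <- simulate_gene(cfg)
  m2 <- simulate_gene(cfg)
  expect_identical(m1$exon_sequences, m2$exon_sequences)
  expect_identical(m1$exons, m2$exons)
  expect_identical(nrow(m1$exons), 9L)
  # canonical splice dinucleotides on every intron flank
  for (fl in m1$intron_flanks) {
    expect_identical(substr(fl$donor, 1, 2), "GT")
    expect_identical(substr(fl$acceptor, nchar(fl$acceptor) - 1,
                            nchar(fl$acceptor)), "AG")
  }
  # full-length CDS has no premature stop (scan independently of the engine)
  seqchr <- paste(unlist(m1$exon_sequences), collapse = "")
  codons <- substring(seqchr, seq(1, nchar(seqchr) - 2, 3),
                      seq(3, nchar(seqchr), 3))
  expect_identical(substr(seqchr, 1, 3), "ATG")
  expect_false(any(head(codons, -1) %in% c("TAA", "TAG", "TGA")))
  expect_true(tail(codons, 1) %in% c("TAA", "TAG", "TGA"))
})

test_that("a 9-exon simulated gene with the RAD51C exon lengths reproduces skip frames", {
  rad <- build_rad51c_fixture()
  lens <- rad$exons$c_end - rad$exons$c_start + 1L
  cfg <- simulation_config(seed = 3L)
  sim <- simulate_gene(cfg)
  # frame class of every internal single-exon skip depends only on the
  # length mod 3, so forcing the fixture lengths must reproduce its classes
  for (k in 2:8) {
    skip <- isoform_label(list(splice_event("exon_skip", k)))
    cc_rad <- analyze_consequence(rad, skip)
    expect_identical(cc_rad$frame_preserved, lens[k] %% 3L == 0L)
  }
})

test_that("noiseless simulation recovers the truth exactly; noise stays within 3 SD", {
  model <- simulate_gene(simulation_config(seed = 21L))
  cfg0 <- simulation_config(seed = 21L, replicate_noise_cv = 0,
                            true_isoform_fractions = c(95, 5))
  sim0 <- simulate_readout(model, cfg0)
  rd0 <- quantify(sim0$peaks, sim0$expected)[["sim"]]
  got0 <- rd0$entries$mean_percent[match(sim0$truth$label, rd0$entries$label)]
  expect_equal(got0, c(95, 5), tolerance = 1e-9)
  expect_equal(rd0$entries$sd_percent, c(0, 0), tolerance = 1e-9)

  cfg1 <- simulation_config(seed = 22L, replicate_noise_cv = 0.01,
                            true_isoform_fractions = c(95, 5))
  sim1 <- simulate_readout(model, cfg1)
  rd1 <- quantify(sim1$peaks, sim1$expected)[["sim"]]
  ent <- rd1$entries[match(sim1$truth$label, rd1$entries$label), ]
  expect_true(all(abs(ent$mean_percent - sim1$truth$true_percent) <=
                    pmax(3 * ent$sd_percent, 1e-6) + 1))
})

test_that("configured sub-threshold trace peaks vanish from the readout", {
  model <- simulate_gene(simulation_config(seed = 8L))
  # 1.1% of a 10000-RFU baseline is 110 RFU, below the 200 RFU cutoff
  cfg <- simulation_config(seed = 8L, rfu_baseline = 10000)
  sim <- simulate_readout(model, cfg)
  rd <- quantify(sim$peaks, sim$expected)[["sim"]]
  expect_false(sim$truth$label[3] %in% rd$entries$label)
  expect_equal(sum(rd$entries$mean_percent), 100, tolerance = 1e-6)
})

test_that("full-pipeline recovery: noisy runs reproduce the truth-implied verdict", {
  model <- simulate_gene(simulation_config(seed = 41L))
  pipeline_verdict <- function(entries) {
    items <- lapply(seq_len(nrow(entries)), function(j) {
      lab <- entries$label[j]
      cons <- if (grepl("^[0-9]+ ?nt$", lab))
        structure(list(isoform = NULL, category = "uncharacterized",
                       domains_lost = character(0),
                       protein_annotation = NA_character_),
                  class = "consequence")
      else analyze_consequence(model, lab)
      transcript_evidence(cons, entries$mean_percent[j])
    })
    agg <- aggregate_readout(items)
    classify_variant("sim", list(agg, pm2_evidence(0L, 250000L)))
  }
  cfg0 <- simulation_config(seed = 1L, true_isoform_fractions = c(2, 97, 1))
  sim0 <- simulate_readout(model, cfg0)
  implied <- pipeline_verdict(data.frame(label = sim0$truth$label,
                                         mean_percent = sim0$truth$true_percent))
  n_runs <- 40L
  ok <- 0L
  for (seed in seq_len(n_runs)) {
    cfg <- simulation_config(seed = seed, true_isoform_fractions = c(2, 97, 1),
                             replicate_noise_cv = 0.02)
    sim <- simulate_readout(model, cfg)
    rd <- quantify(sim$peaks, sim$expected)[["sim"]]
    v <- pipeline_verdict(rd$entries)
    if (v$category == implied$category &&
        v$total_points == implied$total_points) ok <- ok + 1L
  }
  expect_identical(ok, n_runs)
})
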