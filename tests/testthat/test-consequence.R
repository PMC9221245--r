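rad51c_seq <- build_rad51c_fixture(sequences = "synthetic")
rad51c_dom <- rad51c_domains()
mg_layout <- rad51c_minigene_layout()

test_that("apply_isoform length accounting matches the amplicon arithmetic", {
  mt <- apply_isoform(rad51c_seq, "FL", context = "minigene", layout = mg_layout)
  expect_identical(mt$amplicon_size_nt, 1062L)
  expect_identical(mt$net_length_change_nt, 0L)
  mt <- apply_isoform(rad51c_seq, "Δ(E7)", context = "minigene", layout = mg_layout)
  expect_identical(mt$net_length_change_nt, -61L)
  expect_identical(mt$amplicon_size_nt, 1001L)
  mt <- apply_isoform(rad51c_seq, "▼(E8p3)", context = "minigene", layout = mg_layout)
  expect_identical(mt$net_length_change_nt, 3L)
  expect_identical(mt$amplicon_size_nt, 1065L)
})

test_that("variants are applied to the pre-mRNA before splicing", {
  # exonic substitution visible in the full-length transcript
  fl <- apply_isoform(rad51c_seq, "FL", variant = "c.904G>A")
  expect_identical(substr(fl$sequence, 904, 904), "A")
  # the two donor-shift transcripts of the exon-6 inclusion differ by one base
  a <- apply_isoform(rad51c_seq, "▼(E6q4)", variant = "c.904G>A")
  b <- apply_isoform(rad51c_seq, "▼(E6q4)", variant = "c.904+1G>T")
  expect_identical(substr(a$sequence, 904, 908), "AGTAA")
  expect_identical(substr(b$sequence, 904, 908), "GTTAA")
  # intronic bases vanish unless included
  d <- apply_isoform(rad51c_seq, "Δ(E2)", variant = "c.146-4_146-2del")
  expect_identical(d$net_length_change_nt, -259L)
  # inclusion longer than the stored flank
  expect_error(apply_isoform(rad51c_seq, "▼(E6q41)"), class = "sequence_required")
})

test_that("published consequence set: categories, NMD split, annotations", {
  labs <- c("Δ(E2)", "Δ(E2p3)", "▼(E2q27)-a", "▼(E2q27)-b", "Δ(E2q175)",
            "Δ(E3p7)", "Δ(E3)", "Δ(E3q1)", "Δ(E4)", "Δ(E5p10)", "Δ(E5)",
            "Δ(E6)", "▼(E6q4)-a", "▼(E6q4)-b", "Δ(E7)", "Δ(E8)", "▼(E8p3)")
  vars <- c("c.146-3C>G", "c.146-4_146-2del", "c.404+2T>C", "c.404+3A>G",
            "c.404+3A>G", "c.405-1G>C", "c.405-1G>C", "c.571+1del",
            "c.572-1G>C", "c.706-1G>T", "c.837+1G>T", "c.838-2A>G",
            "c.904G>A", "c.904+1G>T", "c.905-2del", "c.966-1G>C", "c.966-1G>C")
  cons <- Map(function(l, v) analyze_consequence(rad51c_seq, l, v, rad51c_dom),
              labs, vars)
  categories <- vapply(cons, function(x) x$category, "")
  expect_identical(sum(categories %in% c("PTC_NMD", "PTC_escape")), 14L)
  expect_identical(sum(categories == "PTC_NMD"), 10L)
  expect_identical(sort(labs[categories == "PTC_escape"]),
                   sort(c("▼(E6q4)-a", "▼(E6q4)-b", "Δ(E7)", "Δ(E8)")))
  expect_identical(sum(categories == "in_frame"), 3L)
  ann <- vapply(cons, function(x) x$protein_annotation, "")
  expect_identical(unname(ann[labs == "Δ(E5)"]), "p.Arg237_Val280del")
  expect_identical(unname(ann[labs == "Δ(E7)"]), "p.Glu303TrpFs*41")
  expect_identical(unname(ann[labs == "Δ(E8)"]), "p.Arg322SerFs*22")
  expect_identical(unname(ann[labs == "▼(E6q4)-a"]), "p.Gly302SerFs*47")
  expect_identical(unname(ann[labs == "▼(E6q4)-b"]), "p.Gly302ValFs*47")
  expect_identical(unname(ann[labs == "Δ(E2p3)"]), "p.Glu49del")
  expect_identical(unname(ann[labs == "▼(E8p3)"]), "p.Arg322delinsSerThr")
  # exon-5 deletion removes the Walker-B motif and beta strand 5
  expect_setequal(cons[[which(labs == "Δ(E5)")]]$domains_lost,
                  c("walker_B_beta4", "beta5"))
  # the exon-8 frameshift truncates beta strands 7-9 and the NLS, not beta 6
  expect_setequal(cons[[which(labs == "Δ(E8)")]]$domains_lost,
                  c("beta7", "beta8", "beta9", "NLS"))
})

test_that("an in-frame-by-length inclusion can still carry a PTC", {
  cc <- analyze_consequence(rad51c_seq, "▼(E2q27)-a", "c.404+2T>C")
  expect_identical(cc$net_length_change_nt, 27L)
  expect_true(cc$frame_preserved)
  expect_true(cc$ptc_present)
  expect_identical(cc$category, "PTC_NMD")
})

test_that("NMD calls agree with an independent codon-scan oracle", {
  labs <- c("Δ(E2)", "Δ(E4)", "Δ(E6)", "▼(E6q4)-a", "Δ(E7)", "Δ(E8)", "▼(E2q27)-b")
  vars <- c("c.146-3C>G", "c.572-1G>C", "c.838-2A>G", "c.904G>A",
            "c.905-2del", "c.966-1G>C", "c.404+3A>G")
  for (i in seq_along(labs)) {
    mt <- apply_isoform(rad51c_seq, labs[i], vars[i])
    ora <- oracle_nmd(mt$sequence, mt$cds_start, mt$junctions)
    cc <- analyze_consequence(rad51c_seq, labs[i], vars[i])
    expect_identical(cc$nmd_predicted, ora$nmd, info = labs[i])
    expect_identical(cc$ptc_c_index, ora$stop_end, info = labs[i])
  }
})

test_that("NMD boundary behaves on an engineered synthetic 3-exon model", {
  # stop codon ending 60 nt upstream of the last junction -> NMD; the same
  # transcript with the stop 39 nt upstream escapes
  mk <- function(stop_gap) {
    e1 <- 90L; e2 <- 120L; e3 <- 90L
    total <- e1 + e2 + e3
    stop_at <- (e1 + e2) - stop_gap - 2L  # stop occupies stop_at..stop_at+2
    stopifnot(stop_at %% 3L == 1L)        # codon-aligned by construction
    body <- rep("GCA", total / 3L)
    body[1] <- "ATG"
    body[(stop_at - 1L) / 3L + 1L] <- "TAA"
    body[total / 3L] <- "TGA"
    seqchr <- paste(body, collapse = "")
    transcript_model("SYN", "SYN.1",
      data.frame(index = 1:3, c_start = c(1L, e1 + 1L, e1 + e2 + 1L),
                 c_end = c(e1, e1 + e2, total)),
      cds_end_c = total,
      exon_sequences = list(`1` = substr(seqchr, 1, e1),
                            `2` = substr(seqchr, e1 + 1, e1 + e2),
                            `3` = substr(seqchr, e1 + e2 + 1, total)),
      intron_flanks = list(`1` = list(donor = "GTAAG", acceptor = "CCCAG"),
                           `2` = list(donor = "GTAAG", acceptor = "CCCAG")))
  }
  near <- analyze_consequence(mk(39L), "FL")  # PTC but within 50 nt
  far <- analyze_consequence(mk(60L), "FL")
  expect_true(near$ptc_present)
  expect_false(near$nmd_predicted)
  expect_true(far$ptc_present)
  expect_true(far$nmd_predicted)
})

test_that("frame status equals mod-3 arithmetic on random events (property)", {
  set.seed(7)
  cfg <- simulation_config(seed = 11L, n_exons = 6L)
  model <- simulate_gene(cfg)
  for (rep in 1:60) {
    ev <- random_splice_event(6L)
    iso <- isoform_label(list(ev))
    mt <- tryCatch(apply_isoform(model, iso), minigeneACMG_error = function(e) NULL)
    if (is.null(mt)) next  # shift larger than the exon/flank: rejected upstream
    cc <- analyze_consequence(model, iso)
    expect_identical(cc$frame_preserved, mt$net_length_change_nt %% 3L == 0L)
    delta <- switch(ev$kind,
      exon_skip = -sum(vapply(seq(ev$exon_from, ev$exon_to),
                              function(k) exon_length(model, k), 0L)),
      exonic_deletion_acceptor = , exonic_deletion_donor = -ev$shift_nt,
      ev$shift_nt)
    expect_identical(mt$net_length_change_nt, as.integer(delta))
  }
})

test_that("without sequences the engine degrades to frame arithmetic", {
  m <- build_rad51c_fixture(sequences = "none")
  cc <- analyze_consequence(m, "Δ(E7)", "c.905-2del")
  expect_false(cc$frame_preserved)
  expect_true(is.na(cc$ptc_present))
  expect_identical(cc$category, "uncharacterized")
  expect_identical(cc$protein_annotation, "p.fs?")
})
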