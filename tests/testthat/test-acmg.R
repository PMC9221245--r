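rad51c_seq <- build_rad51c_fixture(sequences = "synthetic")
rad51c_dom <- rad51c_domains()
critical <- rad51c_dom$entries$domain_name[rad51c_dom$entries$critical]

te <- function(label, variant, fraction, insilico = NULL) {
  cons <- analyze_consequence(rad51c_seq, label, variant, rad51c_dom)
  transcript_evidence(cons, fraction, insilico = insilico,
                      critical_domains = critical)
}

fake_te <- function(fraction, direction, strength) {
  structure(list(label = "x", fraction_percent = fraction,
                 direction = direction, strength = strength,
                 evidence = "x"), class = "transcript_evidence")
}

test_that("per-transcript evidence mapping follows the decision-tree rationale", {
  expect_identical(te("Δ(E4)", "c.572-1G>C", 93.8)$evidence, "P_VS")     # PTC-NMD
  expect_identical(te("Δ(E7)", "c.905-2del", 100)$evidence, "P_VS")      # escape, upgraded
  expect_identical(te("Δ(E5)", "c.837+1G>T", 95.3)$evidence, "P_VS")     # in-frame, critical domain
  expect_identical(te("Δ(E2p3)", "c.146-3C>G", 5.2,
                      insilico = list(provean_score = -10.29))$evidence, "P_P")
  expect_identical(te("▼(E8p3)", "c.966-1G>C", 79.4,
                      insilico = list(provean_score = -11.94))$evidence, "P_P")
  expect_identical(te("FL", "c.404+3A>G", 26.3)$evidence, "B_S")         # wild-type FL
  expect_identical(te("FL", "c.904G>A", 2.4,
                      insilico = list(revel_score = 0.5))$evidence, "N/A")
  # escape without the critical-domain upgrade stays strong
  rules <- default_rules()
  rules$evidence$critical_domain_upgrade <- FALSE
  cons <- analyze_consequence(rad51c_seq, "Δ(E7)", "c.905-2del", rad51c_dom)
  expect_identical(transcript_evidence(cons, 100, rules = rules,
                                       critical_domains = critical)$strength,
                   "strong")
})

test_that("aggregate_readout reproduces the published worked examples", {
  unchar <- fake_te(1.1, "none", "not_applicable")
  agg <- aggregate_readout(list(fake_te(73.8, "pathogenic", "very_strong"),
                                fake_te(25.1, "pathogenic", "supporting"), unchar))
  expect_identical(agg$code, "PVS1_O")
  expect_identical(agg$strength, "supporting")
  expect_identical(agg$points, 1L)

  agg <- aggregate_readout(list(fake_te(94.8, "pathogenic", "very_strong"),
                                fake_te(5.2, "pathogenic", "supporting")))
  expect_identical(agg$strength, "very_strong")  # the 5.2% transcript is <= 10%
  expect_identical(agg$points, 8L)

  agg <- aggregate_readout(list(fake_te(78.7, "pathogenic", "very_strong"),
                                fake_te(21.3, "benign", "strong")))
  expect_identical(agg$strength, "not_applicable")
  expect_identical(agg$points, 0L)

  agg <- aggregate_readout(list(fake_te(100, "pathogenic", "very_strong")))
  expect_identical(agg$strength, "very_strong")

  # benign side: near-pure wild-type readout
  agg <- aggregate_readout(list(fake_te(95, "benign", "strong"),
                                fake_te(5, "pathogenic", "very_strong")))
  expect_identical(agg$code, "BP7_O")
  expect_identical(agg$points, -4L)

  expect_error(aggregate_readout(list(fake_te(80, "pathogenic", "strong"),
                                      fake_te(30, "benign", "strong"))),
               class = "input_error")
})

test_that("boundary semantics: >= 90 share, strictly > 10 contributor", {
  agg <- aggregate_readout(list(fake_te(90, "pathogenic", "very_strong"),
                                fake_te(10, "pathogenic", "supporting")))
  expect_identical(agg$strength, "very_strong")   # 10% does not qualify
  agg <- aggregate_readout(list(fake_te(89.99, "pathogenic", "very_strong"),
                                fake_te(10.01, "none", "not_applicable")))
  expect_identical(agg$strength, "not_applicable")
  # all pathogenic but every transcript <= 10%: extrapolated fallback
  agg <- aggregate_readout(rep(list(fake_te(10, "pathogenic", "very_strong")), 9))
  expect_identical(agg$strength, "very_strong")
  expect_true(attr(agg, "extrapolated"))
})

test_that("aggregate_readout is permutation-invariant and monotone", {
  set.seed(99)
  strengths <- c("supporting", "moderate", "strong", "very_strong")
  for (rep in 1:50) {
    n <- sample(2:4, 1)
    fr <- diff(c(0, sort(runif(n - 1)), 1)) * 100
    dir <- sample(c("pathogenic", "benign", "none"), n, replace = TRUE)
    str <- ifelse(dir == "none", "not_applicable",
                  sample(strengths, n, replace = TRUE))
    items <- Map(fake_te, fr, dir, str)
    a <- aggregate_readout(items)
    b <- aggregate_readout(sample(items))
    expect_identical(a$points, b$points)
    # upgrading one pathogenic transcript never weakens the aggregate
    ip <- which(dir == "pathogenic" & str != "very_strong")
    if (length(ip) && a$points > 0) {
      str2 <- str
      str2[ip[1]] <- strengths[match(str[ip[1]], strengths) + 1L]
      a2 <- aggregate_readout(Map(fake_te, fr, dir, str2))
      expect_gte(a2$points, a$points)
    }
  }
})

test_that("aggregate_readout agrees with the brute-force oracle on random readouts", {
  set.seed(123)
  strengths <- c("supporting", "moderate", "strong", "very_strong")
  for (rep in 1:500) {
    n <- sample(1:4, 1)
    fr <- diff(c(0, sort(runif(n - 1)), 1)) * 100
    dir <- sample(c("pathogenic", "benign", "none"), n, replace = TRUE)
    str <- ifelse(dir == "none", "not_applicable",
                  sample(strengths, n, replace = TRUE))
    got <- aggregate_readout(Map(fake_te, fr, dir, str))
    want <- oracle_aggregate(fr, dir, str)
    if (is.na(want$code)) {
      expect_identical(got$strength, "not_applicable")
    } else {
      expect_identical(got$code, want$code)
      expect_identical(got$strength, want$strength)
    }
  }
})

test_that("PM2 applies at the 0.01% allele-frequency ceiling", {
  expect_identical(pm2_evidence(0L, 250394L)$points, 1L)
  expect_identical(pm2_evidence(1L, 246102L)$points, 1L)
  expect_identical(pm2_evidence(1000L, 250000L)$points, 0L)
  expect_identical(pm2_evidence(25L, 250000L)$points, 1L)   # exactly 1e-4
  expect_error(pm2_evidence(-1L, 100L), class = "input_error")
  expect_error(pm2_evidence(0L, 0L), class = "input_error")
})

test_that("point sums map to categories; predictive codes are replaced by assay codes", {
  ev <- function(points) {
    s <- c(`1` = "supporting", `2` = "moderate", `4` = "strong", `8` = "very_strong")
    evidence_strength("PVS1_O", "pathogenic", s[[as.character(points)]])
  }
  expect_identical(classify_variant("v", list(ev(8), pm2_evidence(0L, 2e5L)))$category, "LP")
  expect_identical(classify_variant("v", list(ev(1), pm2_evidence(0L, 2e5L)))$category, "VUS")
  expect_identical(classify_variant("v", list())$category, "VUS")
  expect_identical(classify_variant("v", list(ev(8), ev(2)))$category, "P")
  benign <- evidence_strength("BP7_O", "benign", "very_strong")
  expect_identical(classify_variant("v", list(benign))$category, "B")
  expect_identical(classify_variant("v",
    list(evidence_strength("BP7_O", "benign", "strong")))$category, "LB")
  # PVS1 (predictive) is excluded when an assay code is present...
  v <- classify_variant("v", list(ev(1),
    evidence_strength("PVS1", "pathogenic", "very_strong")))
  expect_identical(v$total_points, 1L)
  # ...but counts when no assay code exists
  v <- classify_variant("v", list(
    evidence_strength("PVS1", "pathogenic", "very_strong")))
  expect_identical(v$total_points, 8L)
})

test_that("rule configuration round-trips through JSON", {
  rules <- default_rules()
  path <- withr::local_tempfile(fileext = ".json")
  write_rules(rules, path)
  rules2 <- read_rules(path)
  expect_equal(rules2$aggregation$share_min_percent,
               rules$aggregation$share_min_percent)
  expect_identical(rules2$evidence$ptc_nmd, rules$evidence$ptc_nmd)
  expect_equal(rules2$pm2$af_max, rules$pm2$af_max)
})
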