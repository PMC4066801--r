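test_that("calibration solves the moment equations for the default targets", {
  cal <- calibrate_generator()
  expect_lt(abs(cal$achieved$mean - 1.34) / 1.34, 0.02)
  expect_lt(abs(cal$achieved$sd - 1.72) / 1.72, 0.02)
  expect_lt(abs(cal$achieved$fraction - 0.28) / 0.28, 0.02)
  expect_true(cal$p_close > 0 && cal$p_close < 1)
  expect_gt(cal$m_far, cal$m_close)
})

test_that("Monte-Carlo moments of the calibrated mixture match the targets", {
  cal <- calibrate_generator()
  set.seed(99)
  n <- 1e6
  comp <- runif(n) < cal$p_close
  d <- rexp(n, 1 / ifelse(comp, cal$m_close, cal$m_far))
  signal <- 2.9 * exp(-d / 800) + 0.25
  se_mean <- sd(signal) / sqrt(n)
  expect_lt(abs(mean(signal) - 1.34), 3 * se_mean)
  target_signal_sd <- 1.72 * sqrt(0.28)
  expect_lt(abs(sd(signal) - target_signal_sd) / target_signal_sd, 0.01)
  expect_equal(cal$noise_sd, 1.72 * sqrt(0.72), tolerance = 1e-12)
})

test_that("zero variance fraction collapses to a mean-only calibration", {
  cal <- calibrate_generator(target_fraction = 0)
  expect_equal(cal$noise_sd, 1.72)
  expect_equal(cal$m_close, cal$m_far)
  expect_lt(abs(cal$achieved$mean - 1.34), 1e-6)
})

test_that("unachievable targets raise informative errors", {
  # required signal SD far above what the amplitude can deliver
  expect_error(calibrate_generator(target_sd = 50), "unachievable")
  # required mean above amplitude + baseline
  expect_error(calibrate_generator(target_mean = 20), "outside")
})

test_that("layout conserves counts, stays genic, and is seed-deterministic", {
  cfg <- cohort_config(n_alus = 1000)
  lay <- sample_layout(cfg, seed = 3)
  expect_equal(nrow(lay$genic_alus), 1000)
  gi <- match(lay$genic_alus$gene_id, lay$genes$gene_id)
  expect_true(all(lay$genic_alus$start >= lay$genes$tx_start[gi]))
  expect_true(all(lay$genic_alus$end <= lay$genes$tx_end[gi]))
  # satellites are intergenic: outside every gene span
  sat <- lay$repeats[!lay$repeats$id %in% lay$genic_alus$id, ]
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sat$chrom, IRanges::IRanges(sat$start + 1L, sat$end)),
    GenomicRanges::GRanges(lay$genes$chrom,
                           IRanges::IRanges(lay$genes$tx_start + 1L, lay$genes$tx_end)))
  expect_equal(length(hits), 0L)
  lay2 <- sample_layout(cfg, seed = 3)
  expect_identical(lay, lay2)
  expect_false(identical(sample_layout(cfg, seed = 4)$repeats, lay$repeats))
})

test_that("every genic element's nearest reverse repeat is its pair partner", {
  lay <- sample_layout(cohort_config(n_alus = 400), seed = 8)
  feats <- build_feature_table(lay$genic_alus, lay$repeats, lay$genes)
  # partners are interleaved pairs: 1-2, 3-4, ...
  partner <- lay$genic_alus$id[rep(seq(1, 399, by = 2), each = 2) + c(1, 0)]
  expect_equal(feats$neighbor_id, partner)
  # realized distances are the drawn pair gaps
  a_end <- lay$genic_alus$end[seq(1, 399, by = 2)]
  b_start <- lay$genic_alus$start[seq(2, 400, by = 2)]
  expect_equal(feats$d[seq(1, 399, by = 2)], as.integer(b_start - a_end))
})

test_that("a strand-uniform layout has no reverse neighbors", {
  lay <- sample_layout(cohort_config(n_alus = 200, reverse_strand_prob = 0),
                       seed = 2)
  expect_true(all(lay$repeats$strand == "+"))
  feats <- build_feature_table(lay$genic_alus, lay$repeats, lay$genes)
  expect_true(all(is.na(feats$d)))
})

test_that("true editability equals the model exactly when noise is off", {
  cfg <- cohort_config(n_alus = 200, noise_sd = 0, beta_ss = 0, beta_rs = 0)
  lay <- sample_layout(cfg, seed = 5)
  feats <- build_feature_table(lay$genic_alus, lay$repeats, lay$genes)
  e <- sample_true_editability(feats, cfg, seed = 6)
  expect_equal(e, pmax(2.9 * exp(-feats$d / 800) + 0.25, 0.02))
  expect_identical(e, sample_true_editability(feats, cfg, seed = 6))
})

test_that("gamma editability noise preserves the conditional mean", {
  cfg <- cohort_config(n_alus = 2, noise_sd = 0.3, beta_ss = 0, beta_rs = 0)
  d_fix <- c(0, 800, 1600)
  feats <- data.frame(d = rep(d_fix, length.out = 90000),
                      nss_10k = 0, nrs_10k = 0)
  e <- sample_true_editability(feats, cfg, seed = 42)
  mu <- 2.9 * exp(-feats$d / 800) + 0.25
  for (dv in d_fix) {
    sel <- feats$d == dv
    se <- sd(e[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(e[sel]) - mean(mu[sel])), 3 * se + 1e-3)
  }
})

test_that("site counts vanish at zero editability and concentrate at high depth", {
  alus <- as_genic(make_repeats(100, 700, "+"))
  alus$gene_strand <- "+"
  cfg0 <- cohort_config(n_alus = 2)
  sc0 <- sample_site_counts(alus, 0, cfg0, seed = 1)
  expect_true(all(sc0$g_reads == 0))
  # 500 sites at depth 200: aggregate within 0.3 percentage points of truth
  cfg <- cohort_config(n_alus = 2, sites_per_alu_mean = 500, coverage_mean = 200)
  sc <- sample_site_counts(alus, 5, cfg, seed = 2)
  agg <- aggregate_site_counts(sc, alus)
  expect_lt(abs(agg$editability_pct - 5), 0.3)
})

test_that("simulated cohorts are reproducible and internally consistent", {
  cfg <- cohort_config(n_alus = 1200)
  coh <- simulate_cohort(cfg, seed = 9)
  # generator/analyzer closure: recomputing features reproduces them exactly
  refeat <- build_feature_table(coh$genic_alus, coh$repeats, coh$genes)
  expect_identical(coh$features, refeat)
  coh2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(coh$site_counts, coh2$site_counts)
  expect_identical(coh$true_editability, coh2$true_editability)
  coh3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(coh$site_counts, coh3$site_counts))
})

test_that("nearly all synthetic elements pass the default coverage filters", {
  coh <- simulate_cohort(cohort_config(n_alus = 2000), seed = 12)
  raw <- aggregate_site_counts(coh$site_counts, coh$genic_alus)
  flt <- apply_coverage_filters(raw)
  expect_gte(nrow(flt) / nrow(coh$genic_alus), 0.99)
})

test_that("parameter recovery holds across replicate cohorts without neighbor terms", {
  errs <- sapply(1:8, function(k) {
    cfg <- cohort_config(n_alus = 10000, beta_ss = 0, beta_rs = 0)
    coh <- simulate_cohort(cfg, seed = 1000 + k, include_counts = FALSE)
    fit <- fit_exponential(coh$features$d, coh$true_editability$true_pct)
    abs(coef(fit) - c(2.9, 800, 0.25)) / c(2.9, 800, 0.25)
  })
  expect_lt(stats::median(errs["decay_bp", ]), 0.05)
  expect_lt(stats::median(errs["amplitude", ]), 0.05)
  expect_lt(stats::median(errs["baseline", ]), 0.10)
})

test_that("cohort files round-trip through the plain-text writers", {
  coh <- simulate_cohort(cohort_config(n_alus = 200), seed = 4)
  dir <- tempfile()
  write_cohort(coh, dir)
  reps <- read_repeat_annotations(file.path(dir, "repeats.bed"), "bed6")
  expect_equal(nrow(reps), nrow(coh$repeats))
  expect_equal(reps$start, coh$repeats$start)
  genes <- read_gene_models(file.path(dir, "genes.tsv"), "refflat")
  expect_equal(genes$tx_start, coh$genes$tx_start)
  sites <- read_site_counts(file.path(dir, "site_counts.tsv"))
  expect_equal(nrow(sites), nrow(coh$site_counts))
})
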