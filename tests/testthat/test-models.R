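test_that("noise-free exponential data are recovered to numerical precision", {
  d <- seq(0, 3900, by = 100)
  e <- 2.9 * exp(-d / 800) + 0.25
  for (mode in c("binned", "per_element")) {
    fit <- fit_exponential(d, e, mode = mode)
    expect_equal(fit$amplitude, 2.9, tolerance = 1e-6)
    expect_equal(fit$decay_bp, 800, tolerance = 1e-6)
    expect_equal(fit$baseline, 0.25, tolerance = 1e-6)
  }
})

test_that("flat data give zero amplitude and the constant as baseline", {
  d <- seq(0, 4000, by = 200)
  fit <- fit_exponential(d, rep(1.7, length(d)))
  expect_equal(fit$amplitude, 0, tolerance = 1e-8)
  expect_equal(fit$baseline, 1.7, tolerance = 1e-8)
})

test_that("prediction matches the closed form at 0, L, and large d", {
  p <- list(amplitude = 2.9, decay_bp = 800, baseline = 0.25)
  expect_equal(predict_exponential(p, 0), 2.9 + 0.25)
  expect_equal(predict_exponential(p, 800), 2.9 / exp(1) + 0.25)
  expect_equal(predict_exponential(p, 1e9), 0.25, tolerance = 1e-9)
})

test_that("residual editability subtracts the curve; per-element residuals center at 0", {
  p <- list(amplitude = 2.9, decay_bp = 800, baseline = 0.25)
  expect_equal(residual_editability(predict_exponential(p, 500), 500, p), 0)
  expect_equal(residual_editability(predict_exponential(p, 500) + 1, 500, p), 1)
  set.seed(8)
  d <- rexp(4000, 1 / 1200)
  e <- 2.9 * exp(-d / 800) + 0.25 + rnorm(4000, 0, 0.5)
  fit <- fit_exponential(d, e, mode = "per_element", max_d = Inf)
  expect_lt(abs(mean(residual_editability(e, d, fit))), 0.01)
})

test_that("rescaling editability rescales amplitude and baseline, not decay", {
  set.seed(12)
  d <- runif(500, 0, 4000)
  e <- 2.9 * exp(-d / 800) + 0.25 + rnorm(500, 0, 0.2)
  f1 <- fit_exponential(d, e, mode = "per_element")
  f5 <- fit_exponential(d, 5 * e, mode = "per_element")
  expect_equal(f5$amplitude, 5 * f1$amplitude, tolerance = 1e-4)
  expect_equal(f5$baseline, 5 * f1$baseline, tolerance = 1e-4)
  expect_equal(f5$decay_bp, f1$decay_bp, tolerance = 1e-4)
})

test_that("fit object methods are coherent", {
  set.seed(2)
  d <- runif(800, 0, 4000)
  e <- 2.9 * exp(-d / 800) + 0.25 + rnorm(800, 0, 0.3)
  fit <- fit_exponential(d, e)
  expect_s3_class(fit, "alu_expfit")
  expect_named(coef(fit), c("amplitude", "decay_bp", "baseline"))
  expect_equal(predict(fit, 0), unname(coef(fit)["amplitude"] + coef(fit)["baseline"]))
  expect_equal(residuals(fit), fit$data$e - fitted(fit))
  expect_output(print(fit), "Exponential editability decay fit")
  expect_output(print(summary(fit)), "variance explained")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n, 2L))
})

test_that("neighbor regression recovers noise-free linear coefficients exactly", {
  set.seed(31)
  nss <- rpois(500, 6); nrs <- rpois(500, 6)
  res <- -0.022 * nss + 0.015 * nrs + 0.11
  fit <- fit_neighbor_regression(res, nss, nrs, baseline = 0.25)
  expect_equal(fit$beta_ss, -0.022, tolerance = 1e-12)
  expect_equal(fit$beta_rs, 0.015, tolerance = 1e-12)
  expect_equal(fit$intercept_combined, 0.25 + 0.11, tolerance = 1e-12)
  # zero residuals -> zero coefficients
  fit0 <- fit_neighbor_regression(rep(0, 500), nss, nrs)
  expect_equal(unname(coef(fit0)), c(0, 0, 0), tolerance = 1e-12)
})

test_that("collinear neighbor counts are rejected", {
  nss <- rpois(100, 5)
  expect_error(fit_neighbor_regression(rnorm(100), nss, nss), "rank deficient")
})

test_that("neighbor effects are linear in the count deltas", {
  p <- list(beta_ss = -0.022, beta_rs = 0.015)
  expect_equal(neighbor_effect(p, 10, 0), -0.22)
  expect_equal(neighbor_effect(p, 0, 10), 0.15)
  expect_equal(neighbor_effect(p, 0, 0), 0)
})

test_that("variance explained handles exact fit, null fit, and degenerate input", {
  e <- c(1, 2, 3, 4)
  expect_equal(as.numeric(variance_explained(e, e)), 1)
  expect_equal(as.numeric(variance_explained(e, rep(mean(e), 4))), 0)
  worse <- variance_explained(e, c(4, 1, 2, 100))
  expect_equal(as.numeric(worse), 0)            # clipped
  expect_lt(attr(worse, "raw"), 0)              # raw retained
  expect_error(variance_explained(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("identically generated strata produce identical fits", {
  d <- seq(0, 3900, by = 100)
  e <- 2.9 * exp(-d / 800) + 0.25
  dat <- data.frame(d = c(d, d), editability_pct = c(e, e),
                    expressed_strand_class = rep(c("polyA", "polyU"), each = length(d)))
  fa <- stratified_exponential_fit(dat, "polyA")
  fu <- stratified_exponential_fit(dat, "polyU")
  expect_equal(coef(fa), coef(fu), tolerance = 1e-9)
  expect_error(stratified_exponential_fit(dat[dat$expressed_strand_class == "polyA", ], "polyU"),
               "empty")
})

test_that("group summaries compute exact means and honor distance correction", {
  dat <- data.frame(
    editability_pct = c(1, 2, 3, 4),
    family = c("AluS", "AluS", "AluY", "AluY"),
    d = c(100, 200, 100, 200)
  )
  out <- summarize_by(dat, "family")
  expect_equal(out$group, c("AluS", "AluY"))
  expect_equal(out$n, c(2L, 2L))
  expect_equal(out$mean_editability, c(1.5, 3.5))
  # single group equals the overall mean
  one <- summarize_by(transform(dat, family = "AluS"), "family")
  expect_equal(one$mean_editability, mean(dat$editability_pct))
})

test_that("distance correction removes a purely distance-mediated group difference", {
  set.seed(55)
  n <- 6000
  grp <- rep(c("AluS", "AluJ"), each = n / 2)
  # AluJ systematically farther from its neighbor; no true group effect
  d <- ifelse(grp == "AluS", rexp(n, 1 / 600), rexp(n, 1 / 2200))
  e <- 2.9 * exp(-d / 800) + 0.25 + rnorm(n, 0, 0.2)
  dat <- data.frame(editability_pct = e, family = grp, d = d)
  fit <- fit_exponential(dat$d, dat$editability_pct, mode = "per_element",
                         max_d = Inf)
  out <- summarize_by(dat, "family", distance_correct = TRUE, fit = fit)
  raw_gap <- abs(diff(out$mean_editability))
  res_gap <- abs(diff(out$mean_residual))
  expect_gt(raw_gap, 0.5)       # raw means differ via distance
  expect_lt(res_gap, 0.05)      # residual means agree
})
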