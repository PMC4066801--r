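# one shared full-scale cohort run for the slow end-to-end tests
.cohort_cache <- new.env(parent = emptyenv())

default_cohort_run <- function(seed = 101) {
  key <- paste0("run", seed)
  if (!exists(key, envir = .cohort_cache)) {
    coh <- simulate_cohort(cohort_config(), seed = seed)
    raw <- aggregate_site_counts(coh$site_counts, coh$genic_alus)
    flt <- apply_coverage_filters(raw)
    dat <- merge_editability_features(flt, coh$features)
    fit <- fit_exponential(dat$d, dat$editability_pct)
    res <- residual_editability(dat$editability_pct, dat$d, fit)
    nb <- fit_neighbor_regression(res, dat$nss_10k, dat$nrs_10k,
                                  baseline = fit$baseline)
    assign(key, list(cohort = coh, raw = raw, data = dat, fit = fit, nb = nb),
           envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}
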