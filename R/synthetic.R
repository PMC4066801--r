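#' Configuration for the synthetic Alu cohort generator
#'
#' The generator emulates the statistical structure of a genome-wide
#' editability survey: a genic layout of inverted Alu pairs flanked by
#' intergenic same-strand satellites, per-element true editability with
#' exponential distance decay plus linear neighbor-count effects, and a
#' site-level read-count layer. Defaults reproduce the survey conditions
#' the models target: editability decay `2.9 * exp(-d/800) + 0.25`
#' (percent), neighbor coefficients `-0.022`/`+0.015` percent per element,
#' cohort mean 1.34 percent, SD 1.72, and 0.28 of variance explained by
#' distance.
#'
#' Layout geometry: each genic element belongs to one inverted pair whose
#' gap is drawn from a two-component exponential mixture (probability
#' `p_close` of mean `m_close`, else mean `m_far`, truncated at
#' `d_max_gen`); pairs sit on a fixed pitch so that each element's nearest
#' reversely oriented repeat is provably its designated partner, and
#' overdispersed counts of same-strand intergenic satellites flank each
#' pair to give the neighbor-count covariates realistic spread.
#'
#' @param n_alus Number of genic Alu elements (even; two per pair).
#' @param reverse_strand_prob Probability that the left member of a pair
#'   is on the minus strand; the exact values 0 and 1 place *all*
#'   elements on one strand (no inverted pairs, `d` absent).
#' @param length_mean,length_sd,length_min,length_max Element length
#'   model, bp: normal truncated to `[length_min, length_max]`.
#' @param family_probs Named probabilities over `AluJ`, `AluS`, `AluY`,
#'   `FLAM`.
#' @param p_close,m_close,m_far Distance-mixture parameters (fraction,
#'   bp, bp); defaults are the calibrated solution for the default
#'   targets.
#' @param d_max_gen Truncation of the distance mixture, bp.
#' @param amplitude,decay_bp,baseline Exponential editability model
#'   (percent, bp, percent).
#' @param beta_ss,beta_rs Neighbor-count coefficients, percent per
#'   element in the 10-kb window.
#' @param noise_sd Per-element editability noise SD, percent.
#' @param variance_fraction_target,target_mean,target_sd Calibration
#'   targets (see [calibrate_generator()]).
#' @param strata Named list of `c(amplitude, decay_bp, baseline)` per
#'   expressed-strand class, used when simulating stratified cohorts.
#' @param coverage_mean Mean read depth per adenosine site.
#' @param sites_per_alu_mean Mean number of covered adenosine sites per
#'   element.
#' @param beta_concentration Concentration of the Beta law for
#'   site-to-site editing-level variability around the element mean.
#' @param editability_floor Lower clamp for true editability, percent.
#' @param pair_pitch Genomic pitch between consecutive pairs, bp.
#' @param satellite_mu,satellite_size,satellite_max Negative-binomial
#'   satellite counts per pair side (mean, dispersion size, cap).
#' @param satellite_margin,satellite_zone Distance band occupied by
#'   satellites on each side of a pair, bp from the pair edge.
#' @return A classed list (`"cohort_config"`).
#' @export
cohort_config <- function(n_alus = 50000,
                          reverse_strand_prob = 0.5,
                          length_mean = 300, length_sd = 60,
                          length_min = 50, length_max = 600,
                          family_probs = c(AluJ = 0.25, AluS = 0.55,
                                           AluY = 0.15, FLAM = 0.05),
                          p_close = 0.32, m_close = 600, m_far = 2000,
                          d_max_gen = 4000,
                          amplitude = 2.9, decay_bp = 800, baseline = 0.25,
                          beta_ss = -0.022, beta_rs = 0.015,
                          noise_sd = 1.72 * sqrt(1 - 0.28),
                          variance_fraction_target = 0.28,
                          target_mean = 1.34, target_sd = 1.72,
                          strata = list(polyA = c(amplitude = 2.46,
                                                  decay_bp = 960,
                                                  baseline = 0.25),
                                        polyU = c(amplitude = 3.33,
                                                  decay_bp = 710,
                                                  baseline = 0.29)),
                          coverage_mean = 50, sites_per_alu_mean = 60,
                          beta_concentration = 20,
                          editability_floor = 0.02,
                          pair_pitch = 30000,
                          satellite_mu = 6, satellite_size = 0.35,
                          satellite_max = 20,
                          satellite_margin = 400, satellite_zone = 10600) {
  cfg <- as.list(environment())
  stopifnot(
    n_alus >= 2, n_alus %% 2 == 0,
    reverse_strand_prob >= 0, reverse_strand_prob <= 1,
    p_close >= 0, p_close <= 1,
    m_close > 0, m_far > 0, d_max_gen > 0,
    length_min > 0, length_min < length_max,
    amplitude >= 0, decay_bp > 0, baseline >= 0,
    noise_sd >= 0,
    variance_fraction_target >= 0, variance_fraction_target <= 1,
    coverage_mean > 0, sites_per_alu_mean > 0, beta_concentration > 0,
    pair_pitch > 2 * (satellite_zone + 1000) + 2 * length_max + d_max_gen
  )
  if (abs(sum(family_probs) - 1) > 1e-8) stop("family_probs must sum to 1")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic Alu cohort configuration\n")
  cat(sprintf("  n genic Alus: %d   distance mixture: p=%.3g, m_close=%.4g, m_far=%.4g (trunc %g bp)\n",
              x$n_alus, x$p_close, x$m_close, x$m_far, x$d_max_gen))
  cat(sprintf("  model: E = %.3g exp(-d/%.4g) + %.3g %+.3g Nss %+.3g Nrs, noise SD %.4g\n",
              x$amplitude, x$decay_bp, x$baseline, x$beta_ss, x$beta_rs, x$noise_sd))
  cat(sprintf("  counts: %.3g sites/element, depth %.3g, Beta concentration %.3g\n",
              x$sites_per_alu_mean, x$coverage_mean, x$beta_concentration))
  invisible(x)
}

# E[exp(-k d / L)] for d ~ Exp(mean m) truncated at t (closed form)
.trunc_exp_moment <- function(m, L, k, t = Inf) {
  r <- 1 / (1 + k * m / L)
  if (!is.finite(t)) return(r)
  r * (1 - exp(-t * (1 / m + k / L))) / (1 - exp(-t / m))
}

.mixture_moments <- function(p, m_close, m_far, L, t = Inf) {
  m1 <- p * .trunc_exp_moment(m_close, L, 1, t) +
    (1 - p) * .trunc_exp_moment(m_far, L, 1, t)
  m2 <- p * .trunc_exp_moment(m_close, L, 2, t) +
    (1 - p) * .trunc_exp_moment(m_far, L, 2, t)
  c(m1 = m1, m2 = m2)
}

#' Moment-matching calibration of the distance mixture and noise
#'
#' Solves, in closed form up to a one-dimensional root search, for
#' distance-mixture parameters and noise SD such that the generated
#' cohort attains a requested mean editability, total SD, and fraction of
#' variance explained by distance. Uses the analytic moments of the
#' (truncated) exponential mixture: for `d ~ Exp(mean m)`,
#' `E[exp(-k d/L)] = 1/(1 + k m/L)`. The mean equation is linear in
#' `p_close` given `m_far`, and the signal-variance equation is solved
#' for `m_far` by root finding; the residual noise is
#' `noise_sd = sqrt(target_sd^2 (1 - f) - var_extra)`.
#'
#' `mean_offset` and `var_extra` let the caller fold in the analytic or
#' empirical contribution of additional model terms (neighbor counts,
#' read-sampling noise) so that the targets refer to the final measured
#' cohort; both default to 0, in which case the equations constrain the
#' distance term alone.
#'
#' @param target_mean,target_sd Cohort mean and SD of editability,
#'   percent (defaults 1.34, 1.72).
#' @param target_fraction Fraction of variance explained by distance
#'   (default 0.28). `0` skips the variance equation: the mixture
#'   collapses to a single exponential solving the mean equation and
#'   `noise_sd = target_sd`.
#' @param amplitude,decay_bp,baseline Exponential model parameters.
#' @param m_close Fixed mean of the close mixture component, bp.
#' @param d_max Mixture truncation, bp (`Inf` for none).
#' @param mean_offset,var_extra Additive mean and variance contributions
#'   of terms outside the distance model, percent and percent squared.
#' @return `list(p_close, m_close, m_far, noise_sd, achieved)` where
#'   `achieved` reports the analytic mean, SD and variance fraction at
#'   the solution.
#' @export
calibrate_generator <- function(target_mean = 1.34, target_sd = 1.72,
                                target_fraction = 0.28,
                                amplitude = 2.9, decay_bp = 800,
                                baseline = 0.25,
                                m_close = 600, d_max = Inf,
                                mean_offset = 0, var_extra = 0) {
  stopifnot(target_sd > 0, target_fraction >= 0, target_fraction <= 1,
            amplitude > 0, decay_bp > 0, m_close > 0)
  L <- decay_bp
  mu1_star <- (target_mean - baseline - mean_offset) / amplitude
  if (mu1_star <= 0 || mu1_star >= 1) {
    stop("calibrate_generator: required signal mean ", signif(mu1_star, 4),
         " (as a fraction of amplitude) is outside (0, 1); targets unachievable")
  }
  noise_var <- target_sd^2 * (1 - target_fraction) - var_extra
  if (noise_var < 0) {
    stop("calibrate_generator: var_extra exceeds the residual variance budget")
  }
  noise_sd <- sqrt(noise_var)

  if (target_fraction == 0) {
    # single-component mean match; signal variance unconstrained
    f <- function(m) .trunc_exp_moment(m, L, 1, d_max) - mu1_star
    sol <- stats::uniroot(f, c(1, 1e7), tol = 1e-10)
    ach <- .achieved_moments(1, sol$root, sol$root, L, d_max, amplitude,
                             baseline, mean_offset, noise_sd, var_extra)
    return(list(p_close = 1, m_close = sol$root, m_far = sol$root,
                noise_sd = noise_sd, achieved = ach))
  }

  v_target <- target_sd^2 * target_fraction
  a_c <- .trunc_exp_moment(m_close, L, 1, d_max)
  if (a_c <= mu1_star) {
    stop("calibrate_generator: m_close too large: close-component signal mean ",
         signif(amplitude * a_c, 4), " below required ",
         signif(amplitude * mu1_star, 4))
  }
  # given m_far: p from the mean equation, then signal-variance residual
  vres <- function(m_far) {
    a_f <- .trunc_exp_moment(m_far, L, 1, d_max)
    p <- (mu1_star - a_f) / (a_c - a_f)
    if (p < 0 || p > 1) return(NA_real_)
    mm <- .mixture_moments(p, m_close, m_far, L, d_max)
    amplitude^2 * (mm["m2"] - mm["m1"]^2) - v_target
  }
  grid <- exp(seq(log(m_close * 1.01), log(1e6), length.out = 400))
  vals <- vapply(grid, vres, 1)
  ok <- which(!is.na(vals))
  if (!length(ok)) stop("calibrate_generator: mean equation infeasible for all m_far")
  sgn <- sign(vals[ok])
  flip <- which(diff(sgn) != 0)
  if (!length(flip)) {
    stop("calibrate_generator: targets unachievable; attainable signal variance ",
         "range is [", signif(min(vals[ok]) + v_target, 4), ", ",
         signif(max(vals[ok]) + v_target, 4), "] against target ",
         signif(v_target, 4))
  }
  i <- ok[flip[1]]; j <- ok[flip[1] + 1]
  sol <- stats::uniroot(vres, c(grid[i], grid[j]), tol = 1e-9)
  m_far <- sol$root
  a_f <- .trunc_exp_moment(m_far, L, 1, d_max)
  p <- (mu1_star - a_f) / (a_c - a_f)
  ach <- .achieved_moments(p, m_close, m_far, L, d_max, amplitude,
                           baseline, mean_offset, noise_sd, var_extra)
  list(p_close = p, m_close = m_close, m_far = m_far,
       noise_sd = noise_sd, achieved = ach)
}

.achieved_moments <- function(p, m_close, m_far, L, d_max, amplitude,
                              baseline, mean_offset, noise_sd, var_extra) {
  mm <- .mixture_moments(p, m_close, m_far, L, d_max)
  sig_var <- amplitude^2 * (mm["m2"] - mm["m1"]^2)
  tot_var <- sig_var + noise_sd^2 + var_extra
  list(mean = unname(amplitude * mm["m1"] + baseline + mean_offset),
       sd = unname(sqrt(tot_var)),
       fraction = unname(sig_var / tot_var))
}

# truncated-normal element lengths via inverse CDF
.sample_lengths <- function(n, cfg) {
  lo <- stats::pnorm(cfg$length_min, cfg$length_mean, cfg$length_sd)
  hi <- stats::pnorm(cfg$length_max, cfg$length_mean, cfg$length_sd)
  round(stats::qnorm(stats::runif(n, lo, hi), cfg$length_mean, cfg$length_sd))
}

# truncated exponential-mixture gaps via inverse CDF
.sample_gaps <- function(n, cfg) {
  comp <- stats::runif(n) < cfg$p_close
  m <- ifelse(comp, cfg$m_close, cfg$m_far)
  cap <- 1 - exp(-cfg$d_max_gen / m)
  round(-m * log(1 - stats::runif(n) * cap))
}

.subfamily_pool <- list(
  AluJ = c("AluJb", "AluJo", "AluJr"),
  AluS = c("AluSx", "AluSx1", "AluSz", "AluSq2", "AluSg", "AluSp"),
  AluY = c("AluY", "AluYa5", "AluYb8"),
  FLAM = c("FLAM_A", "FLAM_C")
)

.sample_names <- function(n, cfg) {
  fam <- sample(names(cfg$family_probs), n, replace = TRUE,
                prob = cfg$family_probs)
  vapply(fam, function(f) {
    pool <- .subfamily_pool[[f]]
    pool[sample.int(length(pool), 1)]
  }, "")
}

# grouped cumulative sum: cumsum of w restarting at each new value of g
# (g must be sorted run-length style)
.grouped_cumsum <- function(w, g) {
  cs <- cumsum(w)
  first <- !duplicated(g)
  base <- cs[which(first)] - w[which(first)]
  cs - base[cumsum(first)]
}

#' Sample a synthetic repeat layout with gene models
#'
#' Places `n_alus / 2` inverted Alu pairs on one synthetic chromosome at a
#' fixed pitch, each pair's gap drawn from the configured truncated
#' exponential mixture, flanked by overdispersed numbers of same-strand
#' intergenic satellite repeats, and covered by one gene per pair whose
#' exon placement varies the intron/exon relation of the pair. By
#' construction every genic element's nearest reversely oriented repeat
#' is its pair partner, so the realized neighbor distances follow the
#' drawn mixture exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the layout is deterministic given
#'   `config` + `seed`.
#' @return `list(repeats, genes, genic_alus)`: the full repeat table
#'   (genic + satellites), the gene table, and the genic table in
#'   [select_genic_alus()] output shape.
#' @export
sample_layout <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cfg <- config
  n_pairs <- cfg$n_alus / 2
  chrom <- "chrS1"

  gaps <- .sample_gaps(n_pairs, cfg)
  len_a <- .sample_lengths(n_pairs, cfg)
  len_b <- .sample_lengths(n_pairs, cfg)
  uniform_strand <- cfg$reverse_strand_prob %in% c(0, 1)
  left_minus <- if (uniform_strand) {
    rep(cfg$reverse_strand_prob == 1, n_pairs)
  } else {
    stats::runif(n_pairs) < cfg$reverse_strand_prob
  }
  strand_a <- ifelse(left_minus, "-", "+")
  strand_b <- if (uniform_strand) strand_a else ifelse(left_minus, "+", "-")

  x <- 20000 + (seq_len(n_pairs) - 1) * cfg$pair_pitch
  a_start <- x
  a_end <- x + len_a
  b_start <- a_end + gaps
  b_end <- b_start + len_b

  genic <- data.frame(
    id = sprintf("alu%07d", seq_len(cfg$n_alus)),
    chrom = chrom,
    start = as.integer(c(rbind(a_start, b_start))),
    end = as.integer(c(rbind(a_end, b_end))),
    strand = c(rbind(strand_a, strand_b)),
    name = .sample_names(cfg$n_alus, cfg),
    stringsAsFactors = FALSE
  )
  genic$family <- parse_family(genic$name)
  genic$length <- genic$end - genic$start

  ## intergenic satellites: same strand as the nearer pair member, so the
  ## partner remains each genic element's nearest reverse repeat
  n_sat_side <- pmin(stats::rnbinom(2 * n_pairs, mu = cfg$satellite_mu,
                                    size = cfg$satellite_size),
                     cfg$satellite_max)
  side <- rep(c("L", "R"), n_pairs)          # per pair: left, right
  pair_of_side <- rep(seq_len(n_pairs), each = 2)
  sat_pair <- rep(pair_of_side, n_sat_side)
  sat_side <- rep(side, n_sat_side)
  n_sat <- length(sat_pair)
  sats <- NULL
  if (n_sat > 0) {
    sat_len <- .sample_lengths(n_sat, cfg)
    sat_gap <- round(stats::runif(n_sat, 20, 90))
    grp <- rep(seq_along(n_sat_side), n_sat_side)
    c_k <- .grouped_cumsum(sat_len + sat_gap, grp)
    keep <- c_k <= cfg$satellite_zone
    is_left <- sat_side == "L"
    sat_start <- ifelse(is_left,
                        a_start[sat_pair] - cfg$satellite_margin - c_k,
                        b_end[sat_pair] + cfg$satellite_margin + c_k - sat_len)
    sat_strand <- ifelse(is_left, strand_a[sat_pair], strand_b[sat_pair])
    sats <- data.frame(
      id = sprintf("sat%07d", seq_len(n_sat)),
      chrom = chrom,
      start = as.integer(sat_start),
      end = as.integer(sat_start + sat_len),
      strand = sat_strand,
      name = .sample_names(n_sat, cfg),
      stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
    sats$family <- parse_family(sats$name)
    sats$length <- sats$end - sats$start
  }

  repeats <- rbind(genic, sats)
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL

  ## one gene per pair (margins inside the satellite band, so satellites
  ## stay intergenic); exon scheme varies the pair's segment relation
  tx_start <- as.integer(a_start - 300)
  tx_end <- as.integer(b_end + 300)
  gene_strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  scheme_u <- stats::runif(n_pairs)
  exons <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    first <- c(tx_start[j], tx_start[j] + 100L)
    last <- c(tx_end[j] - 100L, tx_end[j])
    mid <- NULL
    if (scheme_u[j] < 0.10) {
      # exon spanning the whole pair: same_exon
      mid <- c(a_start[j] - 50L, b_end[j] + 50L)
    } else if (scheme_u[j] < 0.30 && gaps[j] >= 80) {
      # short exon in the spacer: members in different introns
      mid <- c(a_end[j] + 10L, a_end[j] + 40L)
    }                                        # else: same_intron
    exons[[j]] <- matrix(as.integer(c(first, mid, last)), ncol = 2,
                         byrow = TRUE, dimnames = list(NULL, c("start", "end")))
  }
  genes <- data.frame(
    gene_id = sprintf("gene%06d", seq_len(n_pairs)),
    chrom = chrom,
    strand = gene_strand,
    tx_start = tx_start, tx_end = tx_end,
    exons = I(exons),
    stringsAsFactors = FALSE
  )

  genic_alus <- genic
  genic_alus$gene_id <- rep(genes$gene_id, each = 2)
  genic_alus$gene_strand <- rep(gene_strand, each = 2)
  genic_alus$expressed_strand_class <-
    ifelse(genic_alus$strand == genic_alus$gene_strand, "polyA", "polyU")

  list(repeats = repeats, genes = genes, genic_alus = genic_alus)
}

#' Sample true per-element editability
#'
#' `E_i = A exp(-d_i/L) + B + beta_ss Nss_i + beta_rs Nrs_i + noise`,
#' clamped below at `editability_floor`. The noise is conditionally Gamma
#' with mean equal to the model prediction and a constant scale, so the
#' noise variance is proportional to the predicted level and averages
#' `noise_sd^2` over the cohort: a non-negative, right-skewed law whose
#' conditional mean is exact, so the generated cohort supports unbiased
#' recovery of the decay curve (an additive truncated-normal noise of
#' this magnitude would inflate conditional means near the baseline, and
#' a homoscedastic noise would put unrealistically large scatter on
#' weakly edited far-distance elements).
#'
#' @param features Feature table ([build_feature_table()]) with `d`,
#'   `nss_10k`, `nrs_10k` and (for stratified generation)
#'   `expressed_strand_class`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param stratified Use the per-strand parameter sets in
#'   `config$strata` instead of the single exponential model.
#' @return Numeric vector of true editability, percent, aligned with
#'   `features` rows. Elements without a reverse neighbor (`d` absent)
#'   get only baseline + neighbor terms + noise.
#' @export
sample_true_editability <- function(features, config, seed,
                                    stratified = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cfg <- config
  n <- nrow(features)
  decay_term <- function(A, L, B) {
    ifelse(is.na(features$d), B, A * exp(-features$d / L) + B)
  }
  mu <- if (stratified) {
    out <- numeric(n)
    for (cls in names(cfg$strata)) {
      p <- cfg$strata[[cls]]
      sel <- features$expressed_strand_class == cls
      out[sel] <- decay_term(p["amplitude"], p["decay_bp"], p["baseline"])[sel]
    }
    out
  } else {
    decay_term(cfg$amplitude, cfg$decay_bp, cfg$baseline)
  }
  mu <- mu + cfg$beta_ss * features$nss_10k + cfg$beta_rs * features$nrs_10k
  if (cfg$noise_sd == 0) {
    e <- mu
  } else {
    # constant-scale Gamma: variance proportional to the conditional mean,
    # with the scale set so the cohort-average noise variance is noise_sd^2
    mu_pos <- pmax(mu, 0.05)
    theta <- cfg$noise_sd^2 / mean(mu_pos)
    e <- stats::rgamma(n, shape = mu_pos / theta, scale = theta)
  }
  pmin(pmax(e, cfg$editability_floor), 100)
}

#' Sample site-level read counts for a cohort
#'
#' Per element: `Poisson(sites_per_alu_mean)` (min 1, capped at the
#' element length) distinct adenosine positions placed uniformly without
#' replacement; per site an independent depth `Poisson(coverage_mean)`
#' (min 1) and an editing probability drawn from a Beta law with mean
#' `E_i/100` and the configured concentration; edited (G) reads are
#' Binomial. Site strand is the gene strand of the element.
#'
#' @param genic_alus Genic Alu table (with `gene_strand`).
#' @param true_editability True editability vector, percent, aligned
#'   with `genic_alus`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Site count `data.frame` (`chrom`, `pos`, `strand`, `a_reads`,
#'   `g_reads`), the [read_site_counts()] shape.
#' @export
sample_site_counts <- function(genic_alus, true_editability, config, seed) {
  stopifnot(inherits(config, "cohort_config"),
            nrow(genic_alus) == length(true_editability),
            all(true_editability >= 0), all(true_editability <= 100))
  set.seed(seed)
  cfg <- config
  n <- nrow(genic_alus)
  n_sites <- pmin(pmax(stats::rpois(n, cfg$sites_per_alu_mean), 1L),
                  genic_alus$length)
  pos_list <- vector("list", n)
  for (i in seq_len(n)) {
    pos_list[[i]] <- genic_alus$start[i] +
      sample.int(genic_alus$length[i], n_sites[i]) - 1L
  }
  alu_of_site <- rep(seq_len(n), n_sites)
  pos <- unlist(pos_list, use.names = FALSE)
  total <- length(pos)
  depth <- pmax(stats::rpois(total, cfg$coverage_mean), 1L)
  p_bar <- true_editability[alu_of_site] / 100
  conc <- cfg$beta_concentration
  p_site <- numeric(total)
  pos_p <- p_bar > 0 & p_bar < 1
  p_site[pos_p] <- stats::rbeta(sum(pos_p), conc * p_bar[pos_p],
                                conc * (1 - p_bar[pos_p]))
  p_site[p_bar >= 1] <- 1
  g <- stats::rbinom(total, depth, p_site)
  data.frame(
    chrom = genic_alus$chrom[alu_of_site],
    pos = pos,
    strand = genic_alus$gene_strand[alu_of_site],
    a_reads = depth - g,
    g_reads = g,
    stringsAsFactors = FALSE
  )
}

# analytic variance of the per-element editability estimator induced by
# the read-count layer, in percent^2 (used to fold measurement noise into
# the calibration variance budget)
.measurement_variance <- function(cfg) {
  p <- cfg$target_mean / 100
  ns <- cfg$sites_per_alu_mean
  dp <- cfg$coverage_mean
  v_p <- p * (1 - p) / (cfg$beta_concentration + 1)
  e_pq <- p * (1 - p) * cfg$beta_concentration / (cfg$beta_concentration + 1)
  sum_d <- ns * dp
  sum_d2 <- ns * (dp + dp^2)
  1e4 * (v_p * sum_d2 / sum_d^2 + e_pq / sum_d)
}

#' Simulate a complete synthetic cohort
#'
#' Composes layout, architecture features, true editability, and
#' (optionally) site-level read counts, end-to-end deterministic given
#' `config` + `seed`. With `calibrate = TRUE` (default) the distance
#' mixture and noise SD are first recalibrated by moment matching so the
#' measured cohort attains the configured targets: a provisional layout
#' supplies the empirical mean and variance of the neighbor-count terms,
#' the read-count layer's variance contribution is added analytically,
#' and [calibrate_generator()] solves for `(p_close, m_far, noise_sd)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed driving every sampling stage (sub-seeds are
#'   derived internally).
#' @param include_counts Also sample site-level read counts (default
#'   `TRUE`).
#' @param calibrate Recalibrate the mixture and noise to the configured
#'   targets before generating (default `TRUE`).
#' @param stratified Generate per-element editability from the
#'   strand-class parameter sets in `config$strata`.
#' @return `list(repeats, genes, genic_alus, features, true_editability,
#'   site_counts, config, calibration, seed)`; `features` are computed by
#'   [build_feature_table()] on the generated layout, so recomputing them
#'   reproduces the stored table exactly.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1,
                            include_counts = TRUE, calibrate = TRUE,
                            stratified = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  sub_seed <- function(k) as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
  cfg <- config
  calibration <- NULL
  if (calibrate) {
    pilot_n <- min(cfg$n_alus, 20000L)
    pilot_cfg <- cfg
    pilot_cfg$n_alus <- as.integer(pilot_n - pilot_n %% 2)
    pilot <- sample_layout(pilot_cfg, sub_seed(91))
    pf <- build_feature_table(pilot$genic_alus, pilot$repeats, pilot$genes)
    nb_term <- cfg$beta_ss * pf$nss_10k + cfg$beta_rs * pf$nrs_10k
    meas_var <- if (include_counts) .measurement_variance(cfg) else 0
    calibration <- calibrate_generator(
      target_mean = cfg$target_mean, target_sd = cfg$target_sd,
      target_fraction = cfg$variance_fraction_target,
      amplitude = cfg$amplitude, decay_bp = cfg$decay_bp,
      baseline = cfg$baseline,
      m_close = cfg$m_close, d_max = cfg$d_max_gen,
      mean_offset = mean(nb_term),
      var_extra = stats::var(nb_term) + meas_var
    )
    cfg$p_close <- calibration$p_close
    cfg$m_far <- calibration$m_far
    cfg$noise_sd <- calibration$noise_sd
  }
  layout <- sample_layout(cfg, sub_seed(1))
  features <- build_feature_table(layout$genic_alus, layout$repeats,
                                  layout$genes)
  truth <- sample_true_editability(features, cfg, sub_seed(2),
                                   stratified = stratified)
  counts <- if (include_counts) {
    sample_site_counts(layout$genic_alus, truth, cfg, sub_seed(3))
  }
  list(
    repeats = layout$repeats, genes = layout$genes,
    genic_alus = layout$genic_alus, features = features,
    true_editability = data.frame(alu_id = layout$genic_alus$id,
                                  true_pct = truth,
                                  stringsAsFactors = FALSE),
    site_counts = counts,
    config = cfg, calibration = calibration, seed = seed
  )
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `repeats.bed` (BED6 + family), `genes.tsv` (refFlat),
#' `site_counts.tsv` and `truth.tsv` into `dir`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_repeat_bed(cohort$repeats, file.path(dir, "repeats.bed"))
  g <- cohort$genes
  refflat <- data.frame(
    g$gene_id, g$gene_id, g$chrom, g$strand, g$tx_start, g$tx_end,
    g$tx_start, g$tx_start,
    vapply(g$exons, nrow, 1L),
    vapply(g$exons, function(m) paste0(paste(m[, "start"], collapse = ","), ","), ""),
    vapply(g$exons, function(m) paste0(paste(m[, "end"], collapse = ","), ","), "")
  )
  utils::write.table(refflat, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(cohort$site_counts)) {
    utils::write.table(cohort$site_counts, file.path(dir, "site_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$true_editability, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
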