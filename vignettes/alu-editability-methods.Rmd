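---
title: "Modelling Alu editability from genomic architecture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Alu editability from genomic architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluedit)
```

# The statistic and the model

A-to-I editing requires double-stranded RNA. In primate transcripts the
dominant substrate is the fold-back duplex formed by two Alu repeats in
opposite orientation on the same pre-mRNA, so the editability of an Alu —
the percentage of its sequenced adenosine read bases observed as G —
should be governed first of all by how good a duplex the element can
form. The package models per-element editability `E` (percent) as

\[
E \;=\; A\,e^{-d/L} + \beta_{ss} N_{ss} + \beta_{rs} N_{rs} + B + \varepsilon ,
\]

where

* `d` is the gap (bp) between the element and the nearest reversely
  oriented Alu on the chromosome, zero for touching, overlapping or
  nested pairs;
* `A` (percent) is the excess editability of a zero-distance pair and
  `L` (bp) the decay scale — the distance over which pairing probability,
  and with it ADAR recruitment, falls off;
* `N_ss`, `N_rs` count same-strand and reverse-strand Alus within a
  10 000-bp window on each side (gap distance, boundary inclusive):
  same-strand neighbors compete for the reverse partner
  (`beta_ss < 0`), reverse-strand neighbors supply alternative partners
  (`beta_rs > 0`);
* `B` (percent) is the large-distance asymptote, dominated by the
  false-positive floor of upstream site detection rather than by real
  editing;
* `varepsilon` is per-element scatter from everything the architecture
  covariates do not capture (sequence context, expression, site
  composition).

The model is fitted sequentially, as the analysis it implements does:
first the exponential in `d` alone (`fit_exponential()`), then ordinary
least squares of the residual editability on `(N_ss, N_rs)`
(`fit_neighbor_regression()`); the combined intercept is the exponential
baseline plus the OLS intercept. A joint fit is deliberately out of
scope. The fraction of per-element variance explained by distance is
`1 - SS_res/SS_tot` of the fitted curve against the raw per-element
values (`variance_explained()`), clipped to `[0, 1]` for reporting with
the raw value kept as an attribute.

Further covariates are treated descriptively rather than inserted into
the regression: element and neighbor length, intron/exon co-residence of
the pair, pair percent identity, and subfamily (AluJ, AluS, AluY, with
the short single-armed FLAM carried as a family of its own). Because
most of them correlate with `d`, `summarize_by()` offers
distance-corrected group means (group means of the residual from the
global exponential fit) next to the raw means.

# Quantification rules

`aggregate_site_counts()` pools A/G read counts over every covered
adenosine position inside an element: `E = 100 * sum(g) / sum(a + g)`.
Choices worth stating:

* Reads are attributed to the annotated gene strand; an in-element site
  whose strand contradicts it is an error, not a silent skip, because it
  signals inconsistent upstream strand handling.
* An element is *genic* only if its full interval lies inside a
  transcript span. Partial overlaps are excluded. When several genes
  contain an element, the smallest span wins, ties by lexicographic
  gene id — a deterministic rule for a case the underlying analysis
  leaves unspecified.
* Coverage filters (`apply_coverage_filters()`) are inclusive:
  `n_sites >= 30` and `total reads >= 1000` survive.
* The strong-site variant (`strong_site_editability()`, threshold 25 %)
  zeroes the numerator of sub-threshold sites while keeping their depth
  in the denominator. The alternative — dropping such sites entirely —
  would change the denominator and make the two statistics
  incomparable; with our rule the strong-site value is provably at most
  the aggregate value, which the tests assert on randomized inputs.
* Sites with zero depth are rejected at parse time.

# Architecture features

All internal coordinates are 0-based half-open; dialect conversion
(RepeatMasker `.out` is 1-based inclusive, strand `C` meaning
complement) happens only in the readers. The neighbor pool for `d` and
the window counts is *all* annotated Alus, genic or not — an intergenic
repeat pairs in the pre-mRNA just as well, as long as it is transcribed
along with the gene.

Pair distance is edge-to-edge gap, 0 for touching/overlapping/nested.
Nearest-neighbor ties break deterministically (smaller start, then id);
the implementation uses a sorted-vector search rather than
`GenomicRanges::distanceToNearest`, which does not return all tied
candidates across both sides. Window membership is by gap distance with
an inclusive boundary. Segment relation assigns each element of a pair
to the exon or intron containing its midpoint (an Alu can straddle a
boundary; the midpoint rule is the documented arbitrary choice). Pair
identity is a Smith–Waterman local alignment (match +2, mismatch −3,
gap open −5, gap extend −2 — BLASTN-like constants, fixed for
reproducibility) of one element against the reverse complement of its
neighbor, reported as `100 · matches / alignment columns`; `N` never
matches. The test suite checks it against an exhaustive
dynamic-programming oracle that enumerates all optimal alignments of
30-mers.

# Fitting

`fit_exponential()` minimizes least squares with bounded
Levenberg–Marquardt (via minpack.lm), multi-start in the decay
(`L0 ∈ {200, 1000, 3000}` bp, `A0` = range of bin means, `B0` = min bin
mean), bounds `A ≥ 0`, `L ∈ [10, 1e6]` bp, `B ≥ 0`, objective tolerance
`1e-10`. The default mode fits bin means over 100-bp distance bins,
restricted to `d ≤ 4000` bp, *weighted by bin occupancy*: the weights
make the estimate equivalent to per-element least squares (we measured
a ~2.4× smaller sampling SD of the baseline than with unweighted bin
means) while keeping the figure-style binned presentation; a
`per_element` mode is available for sensitivity analysis. Records
beyond `max_d` are excluded from the curve but always included in the
per-element variance-explained computation — the only reading under
which "fraction of total variance" is meaningful. A flat response is
returned as amplitude 0 with the decay left at its starting scale
(unidentifiable) rather than as an error.

# The synthetic cohort generator

`simulate_cohort()` exists so that every stage — file parsing,
quantification, interval features, fitting — can be exercised on data
with known truth. Its defaults *are* the survey conditions the models
target: decay (2.9, 800, 0.25), neighbor coefficients (−0.022, +0.015),
cohort mean 1.34 %, SD 1.72, distance-explained fraction 0.28, ~50
reads per site, ~60 covered adenosines per element (about the number of
adenosines in a typical ~300-bp Alu), strand-stratified parameter sets
(2.46, 960, 0.25) / (3.33, 710, 0.29) for polyA/polyU when stratified
generation is requested.

**Layout.** Genic elements are generated as isolated inverted pairs on
a fixed 30-kb pitch along one synthetic chromosome, each pair covered
by one gene; the pair gap is drawn from a two-component exponential
mixture (probability `p_close` of mean `m_close`, else `m_far`),
truncated at 4000 bp. Around each pair, overdispersed numbers of
*intergenic, same-strand* satellite repeats (negative-binomial per
side, mean 6, size 0.35, capped at 20) populate the 10-kb windows. This
geometry is not cosmetic — it guarantees, by construction, that every
genic element's nearest reversely oriented repeat is its designated
partner, so the realized `d` values follow the drawn mixture exactly,
while the satellite counts give the regressors `N_ss`/`N_rs` large
variance that is independent of `d` (no omitted-variable attenuation in
the residual regression). Gene exon schemes vary so that pairs land in
the same intron, the same exon, or different segments. Features are
computed by the same `build_feature_table()` the analysis uses, so the
generator/analyzer closure is exact by construction and asserted in the
tests.

**Calibration.** `calibrate_generator()` matches moments analytically.
For `d ~ Exp(mean m)` truncated at `T`,
`E[e^{-kd/L}]` is closed-form, so the cohort mean and the
distance-signal variance are explicit functions of
`(p_close, m_close, m_far)`. Given `m_close` (600 bp), the mean
equation is linear in `p_close` and the variance equation is solved for
`m_far` by a one-dimensional root search; the residual noise is
`noise_sd = sqrt(target_sd^2 (1 - fraction) - var_extra)`.
`simulate_cohort()` runs a pilot layout first and folds the empirical
mean and variance of the neighbor-count terms, plus the analytic
variance of the read-sampling layer, into the calibration
(`mean_offset`, `var_extra`), so the targets refer to the cohort as
*measured* by the pipeline, not to an idealized signal. Infeasible
targets (signal SD beyond what the amplitude can deliver) are an error
that states the attainable bound.

**Noise.** Per-element noise is conditionally Gamma with the mean equal
to the model prediction and a constant scale, so the noise variance is
proportional to the predicted level and averages `noise_sd^2` over the
cohort; values are clamped below at 0.02 % (the detection floor). Two
alternatives were rejected. A truncated normal (re-draw below the
floor) inflates the conditional mean near the baseline by up to a full
percentage point at the calibrated noise level, which would bias the
recovered curve and destroy the variance decomposition. A
*homoscedastic* Gamma keeps conditional means exact but puts
SD-1.4 scatter on elements whose expected editability is 0.25 %, which
is both unphysical for a non-negative fraction measured as near-zero
and statistically hostile to estimating the baseline. The
constant-scale family is the canonical choice for level-dependent
spread in non-negative data. Its conditional-mean exactness is asserted
by Monte-Carlo tests. When the linear predictor is itself below the
floor region (possible for far elements with many same-strand
neighbors), it is floored at 0.05 % before the Gamma draw; the
satellite-count cap keeps this sub-population below a fraction of a
percent of the cohort, small enough not to bias the recovered neighbor
coefficients measurably.

**Read counts.** Sites per element are Poisson (min 1, at most one per
bp), placed uniformly without replacement; depth per site is Poisson
(min 1); per-site editing probabilities are Beta around the element
mean with concentration 20 — site-to-site variability is real and
large, and 20 gives site CVs of the right order without modelling
sequence context; edited counts are Binomial. With the default depth
(~3000 reads per element against a 1000-read filter), over 99 % of
synthetic elements pass the coverage filters, which the tests assert.

**What it does not emulate.** No real Alu sequences (identity features
are tested on constructed strings), no subfamily phylogeny, no
expression variation across genes, no hyper-editing, no shape match to
any empirical distance histogram beyond the calibrated moments, and no
true family/segment/length effects on editability — group summaries on
synthetic cohorts are null-distributed by design, which is exactly what
makes them useful for testing the distance correction. Passing tests
therefore demonstrate correctness of the machinery and recoverability
of the stated models under realistic noise, not biological conclusions
about real cohorts.

# Determinism and numerical choices

Every sampling stage takes an explicit seed; `simulate_cohort()`
derives per-stage sub-seeds from one master seed (kept within 32-bit
integer range), and identical config + seed reproduces bit-identical
tables. Tie-breaks (nearest neighbor, multi-gene containment) are
deterministic and documented. Thresholds read as "at least" are
inclusive. The exponential fit's multi-start makes the reported optimum
start-independent in practice; convergence failures raise errors rather
than returning silent defaults, except the exactly-flat response noted
above.

# Problem sizes used by the tests

The acceptance-style checks run the full pipeline on one calibrated
cohort of 50 000 elements (~3 M synthetic site counts) and a stratified
truth-level cohort of 60 000; property checks use 100 random layouts of
up to 500 elements against O(n²) oracles, 30-mers against the
exhaustive alignment oracle, and replicate cohorts of 10 000 for
parameter-recovery medians. These sizes were chosen to keep the full
suite around two minutes while leaving the stochastic recovery
tolerances honest (at 50 000 elements the neighbor-coefficient
standard errors are ~5 % and ~7 % of the true values — close to the
information limit the calibrated noise allows, which is why the
recovery tolerances in the tests are not tighter).

# Known limitations

* The neighbor pool assumes chromosome-wide annotations; with truncated
  annotation input, `d` is computed against what is provided.
* Pair identity uses one fixed scoring scheme; it is a proxy for duplex
  stability, not a thermodynamic model (RNA secondary-structure
  prediction is out of scope).
* The two-stage fit inherits the identification limits of the analysis
  it reproduces: a strong correlation between neighbor counts and
  distance in unusual genomes would attenuate the OLS coefficients.
* Overlapping genic Alus each receive any site they contain; site
  counts are not partitioned between overlapping elements.
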