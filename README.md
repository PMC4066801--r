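# aluedit

Genomic architecture and A-to-I editability of Alu elements.

## The problem

A-to-I RNA editing by ADAR enzymes is the most abundant post-transcriptional
modification in primates, and nearly all of it falls inside Alu repeats:
two nearby Alu copies on opposite strands of the same transcript fold back
into a long double-stranded hairpin, the ADAR substrate. Editing levels at
individual adenosines are noisy and strongly site-dependent, but the
element-level average — the **editability**

```
E = 100 * (edited G read bases) / (A + G read bases)      [percent]
```

pooled over every covered adenosine of the element — is a robust statistic
whose variation across the genome is largely explained by a handful of
genomic-architecture covariates. `aluedit` is a tested implementation of
that analysis for people who have per-site editing counts (from any
upstream editing-detection pipeline) plus standard repeat and gene
annotations, and want the element-level picture:

* per-Alu editability with coverage filters (≥ 30 covered adenosines,
  ≥ 1000 sequenced A/I read bases), restricted to Alus fully inside
  RefSeq-style genes, with reads attributed to the gene strand;
* architecture covariates per element: gap distance `d` to the nearest
  reversely oriented Alu (0 for touching/nested pairs), same-strand and
  reverse-strand neighbor counts `Nss`/`Nrs` in 10-kb and 2-kb windows,
  intron/exon co-residence of the pair, local-alignment percent identity
  of the pair, subfamily relations (AluJ/AluS/AluY/FLAM);
* the models: exponential distance decay

  `E = A · exp(−d/L) + B`

  fitted by bounded nonlinear least squares (binned, occupancy-weighted,
  or per-element), followed by OLS of the residual editability on the
  neighbor counts,

  `E ≈ A · exp(−d/L) + β_ss·Nss + β_rs·Nrs + B'`,

  variance decomposition (fraction of per-element variance explained by
  distance), strand-stratified fits (polyA vs polyU expressed strand),
  and distance-corrected group summaries.

Because the genome-scale data sets behind such surveys are far too large
for a test suite, the package ships a first-class synthetic-cohort
generator (`simulate_cohort()`) with a moment-matching calibrator: it
reproduces the survey's statistical structure (mean editability 1.34 %,
SD 1.72, 28 % of variance explained by distance, decay scale ~800 bp)
down to the site-level read counts, so every stage of the pipeline is
testable end to end.

## Worked example

Simulate a calibrated cohort, quantify, and fit:

```r
library(aluedit)

coh  <- simulate_cohort(cohort_config(n_alus = 6000), seed = 11)
raw  <- aggregate_site_counts(coh$site_counts, coh$genic_alus)
kept <- apply_coverage_filters(raw)               # >= 30 sites, >= 1000 reads
dat  <- merge_editability_features(kept, coh$features)

fit <- fit_exponential(dat$d, dat$editability_pct)
fit
#> Exponential editability decay fit (binned mode)
#>   E = 2.857 * exp(-d / 760.9) + 0.2767
#>   n = 6000 elements (6000 within max_d = 4000 bp)
#>   variance explained (per element): 0.282
```

The fitted curve says a zero-distance inverted pair is edited ~2.9 + 0.28
≈ 3.1 % on average, editability halves every ~530 bp of separation
(`L·ln 2`), and the large-distance floor (~0.28 %) is the false-positive
level of upstream site detection. Distance alone explains 28 % of the
per-element variance. The residual neighbor-count regression:

```r
res <- residual_editability(dat$editability_pct, dat$d, fit)
nb  <- fit_neighbor_regression(res, dat$nss_10k, dat$nrs_10k,
                               baseline = fit$baseline)
nb
#> Neighbor-count regression on residual editability
#>   residual ~ -0.02191 * Nss +0.01059 * Nrs +0.04456
#>   combined-model intercept: 0.3212 %   n = 6000

neighbor_effect(nb, 10, 0)   # ten extra same-strand neighbors
#> [1] -0.2190572
```

Each same-strand Alu within 10 kb competes for the reverse partner and
costs ~0.02 percentage points of editability; each reversely oriented
neighbor adds ~0.01–0.015. Distance-corrected family summaries separate a
real family effect from "younger families sit closer to a partner":

```r
summarize_by(dat, "family", distance_correct = TRUE, fit = fit)
#>   group    n mean_editability mean_residual
#> 1  AluJ 1552         1.392903    0.06171049
#> 2  AluS 3260         1.310684   -0.02825966
#> 3  AluY  888         1.356399    0.02024046
#> 4  FLAM  300         1.233498   -0.08691294
```

(The synthetic generator puts no true family effect in, and the residual
means are correspondingly near zero.)

On real files the one-call orchestrator is:

```r
run_pipeline("rmsk.tsv", "ucsc_rmsk", "genes.txt", "refflat",
             "site_counts.tsv", out_dir = "results")
```

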