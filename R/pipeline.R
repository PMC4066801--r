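#' Run the full editability-architecture pipeline
#'
#' End-to-end orchestration: read annotations, gene models and site-level
#' counts; restrict to genic Alus; quantify per-element editability with
#' coverage filters; compute architecture features; fit the exponential
#' distance model, the residual neighbor-count regression, per-strand
#' stratified fits; and write group summaries. Stage-by-stage record
#' counts are logged to `stderr` and returned; any stage failure aborts
#' with the stage name.
#'
#' @param repeats_path,repeats_dialect Repeat annotation file and dialect
#'   (see [read_repeat_annotations()]).
#' @param genes_path,genes_dialect Gene model file and dialect
#'   (see [read_gene_models()]).
#' @param sites_path Site count TSV (see [read_site_counts()]).
#' @param sequences Optional named sequences for pair identity
#'   (see [build_feature_table()]).
#' @param out_dir Output directory; when non-`NULL`, per-Alu TSVs, the
#'   fit report JSON and group-summary TSVs are written there.
#' @param min_sites,min_depth Coverage filters
#'   (see [apply_coverage_filters()]).
#' @param mode,bin_width,max_d Exponential fit options
#'   (see [fit_exponential()]).
#' @param window_large,window_small Neighbor-count windows in bp.
#' @param strata Strand classes to fit separately (default both); `NULL`
#'   to skip.
#' @param groupings Group summaries to compute (see [summarize_by()]).
#' @return A list with `counts` (records per stage), `exp_fit`,
#'   `neighbor_fit`, `strata_fits`, `summaries`, and the merged
#'   per-element `data`.
#' @export
run_pipeline <- function(repeats_path, repeats_dialect,
                         genes_path, genes_dialect,
                         sites_path, sequences = NULL, out_dir = NULL,
                         min_sites = 30, min_depth = 1000,
                         mode = "binned", bin_width = 100, max_d = 4000,
                         window_large = 10000, window_small = 2000,
                         strata = c("polyA", "polyU"),
                         groupings = c("family", "segment_relation")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(err) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(err),
           call. = FALSE)
    })
  }
  log_count <- function(...) message(sprintf(...))

  repeats <- stage("annotations", read_repeat_annotations(repeats_path, repeats_dialect))
  genes <- stage("annotations", read_gene_models(genes_path, genes_dialect))
  log_count("annotations: %d Alu repeats, %d genes", nrow(repeats), nrow(genes))

  genic <- stage("genic_selection", select_genic_alus(repeats, genes))
  log_count("genic_selection: %d of %d repeats genic (%d filtered)",
            nrow(genic), nrow(repeats), nrow(repeats) - nrow(genic))

  sites <- stage("quantify", read_site_counts(sites_path))
  raw <- stage("quantify", aggregate_site_counts(sites, genic))
  flt <- stage("quantify", apply_coverage_filters(raw, min_sites, min_depth))
  log_count("quantify: %d sites; %d covered Alus; %d pass coverage filters (%d filtered)",
            nrow(sites), nrow(raw), nrow(flt), nrow(raw) - nrow(flt))

  features <- stage("features", build_feature_table(
    genic, repeats, genes, sequences = sequences,
    window_large = window_large, window_small = window_small))
  data <- stage("features", merge_editability_features(flt, features))
  log_count("features: %d records merged, %d with a reverse neighbor",
            nrow(data), sum(!is.na(data$d)))

  exp_fit <- stage("fit", fit_exponential(data$d, data$editability_pct,
                                          mode = mode, bin_width = bin_width,
                                          max_d = max_d))
  res <- residual_editability(data$editability_pct, data$d, exp_fit)
  nb_fit <- stage("fit", fit_neighbor_regression(res, data$nss_10k,
                                                 data$nrs_10k,
                                                 baseline = exp_fit$baseline))
  strata_fits <- list()
  for (cls in strata) {
    strata_fits[[cls]] <- stage(
      paste0("fit_", cls),
      stratified_exponential_fit(data, cls, mode = mode,
                                 bin_width = bin_width, max_d = max_d))
  }
  summaries <- list()
  for (grp in groupings) {
    summaries[[grp]] <- stage(
      "summaries",
      summarize_by(data, grp, distance_correct = TRUE, fit = exp_fit))
  }

  report <- list(
    counts = list(
      repeats = nrow(repeats), genes = nrow(genes), genic = nrow(genic),
      sites = nrow(sites), covered = nrow(raw), kept = nrow(flt),
      filtered = nrow(raw) - nrow(flt)
    ),
    exp_fit = exp_fit, neighbor_fit = nb_fit,
    strata_fits = strata_fits, summaries = summaries,
    data = data
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_editability_table(flt, file.path(out_dir, "editability.tsv"))
    write_feature_table(features, file.path(out_dir, "features.tsv"))
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (grp in names(summaries)) {
      utils::write.table(summaries[[grp]],
                         file.path(out_dir, paste0("summary_", grp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' Machine-readable subset of a pipeline report
#'
#' Flattens the fitted model objects of a [run_pipeline()] report into
#' plain lists suitable for JSON serialization.
#'
#' @param report A [run_pipeline()] return value.
#' @return A nested list of scalars and tables.
#' @export
report_json <- function(report) {
  fit_list <- function(f) {
    list(amplitude = f$amplitude, decay_bp = f$decay_bp,
         baseline = f$baseline, r2_binned = f$r2_binned,
         variance_explained_per_element =
           as.numeric(f$variance_explained_per_element),
         n = f$n, n_fit = f$n_fit, mode = f$mode)
  }
  list(
    counts = report$counts,
    exp_fit = fit_list(report$exp_fit),
    neighbor_fit = list(
      beta_ss = report$neighbor_fit$beta_ss,
      beta_rs = report$neighbor_fit$beta_rs,
      intercept_combined = report$neighbor_fit$intercept_combined,
      n = report$neighbor_fit$n
    ),
    strata_fits = lapply(report$strata_fits, fit_list),
    summaries = report$summaries
  )
}
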