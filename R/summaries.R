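#' Group summaries of editability, optionally distance-corrected
#'
#' Mean editability per group of elements, with group defined by family,
#' subfamily agreement with the nearest reverse neighbor, intron/exon
#' relation, or binned element length, pair identity, or neighbor length.
#' Because group membership often correlates with neighbor distance,
#' `distance_correct = TRUE` additionally reports the group mean of the
#' residual from the exponential distance model, which removes the
#' distance-mediated part of any apparent group effect.
#'
#' @param data Merged per-element table ([merge_editability_features()]):
#'   must contain `editability_pct` plus the columns the grouping needs
#'   (`family`, `same_subfamily`/`same_family`, `segment_relation`,
#'   `length`, `pair_identity_pct`, `neighbor_length`, `d`).
#' @param grouping One of `"family"`, `"subfamily_match"`,
#'   `"segment_relation"`, `"length_bin"`, `"identity_bin"`,
#'   `"neighbor_length_bin"`.
#' @param distance_correct Also report mean residual editability from
#'   `fit` (default `FALSE`).
#' @param fit An `"alu_expfit"` object; required when
#'   `distance_correct = TRUE`. When omitted it is fitted to `data`
#'   (binned mode, defaults).
#' @param length_breaks,identity_breaks Bin edges for the binned
#'   groupings.
#' @return A `data.frame` with `group`, `n`, `mean_editability` and (when
#'   requested) `mean_residual`; rows ordered by group label. Elements for
#'   which the grouping is undefined fall in group `"unknown"`.
#' @export
summarize_by <- function(data,
                         grouping = c("family", "subfamily_match",
                                      "segment_relation", "length_bin",
                                      "identity_bin", "neighbor_length_bin"),
                         distance_correct = FALSE, fit = NULL,
                         length_breaks = seq(0, 700, by = 50),
                         identity_breaks = seq(0, 100, by = 10)) {
  grouping <- match.arg(grouping)
  g <- switch(grouping,
    family = data$family,
    subfamily_match = ifelse(is.na(data$same_subfamily), NA,
                             ifelse(data$same_subfamily, "same_subfamily",
                                    ifelse(data$same_family, "same_family_only",
                                           "different_family"))),
    segment_relation = data$segment_relation,
    length_bin = as.character(cut(data$length, breaks = length_breaks,
                                  include.lowest = TRUE, right = FALSE)),
    identity_bin = as.character(cut(data$pair_identity_pct,
                                    breaks = identity_breaks,
                                    include.lowest = TRUE, right = FALSE)),
    neighbor_length_bin = as.character(cut(data$neighbor_length,
                                           breaks = length_breaks,
                                           include.lowest = TRUE,
                                           right = FALSE))
  )
  g[is.na(g)] <- "unknown"
  res <- NULL
  if (distance_correct) {
    if (is.null(fit)) fit <- fit_exponential(data$d, data$editability_pct)
    res <- residual_editability(data$editability_pct, data$d, fit)
  }
  groups <- sort(unique(g))
  out <- data.frame(
    group = groups,
    n = as.integer(tapply(data$editability_pct, g, length)[groups]),
    mean_editability = as.numeric(tapply(data$editability_pct, g, mean)[groups]),
    stringsAsFactors = FALSE
  )
  if (distance_correct) {
    out$mean_residual <- as.numeric(
      tapply(res, g, function(v) mean(v, na.rm = TRUE))[groups])
  }
  rownames(out) <- NULL
  out
}
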