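#' Regress residual editability on neighborhood Alu counts
#'
#' Second stage of the combined distance + neighborhood model: ordinary
#' least squares of distance-corrected residual editability on the
#' same-strand (`Nss`) and reverse-strand (`Nrs`) neighbor counts, with an
#' intercept. Same-strand neighbors compete for the reverse partner and
#' depress editability (`beta_ss < 0` on real cohorts); reverse-strand
#' neighbors offer additional pairing partners and raise it
#' (`beta_rs > 0`). The combined model intercept is the exponential
#' baseline plus the OLS intercept, so that
#' `E ~ A*exp(-d/L) + beta_ss*Nss + beta_rs*Nrs + intercept_combined`.
#'
#' @param residuals Residual editability in percent
#'   ([residual_editability()]).
#' @param nss,nrs Neighbor counts (same length as `residuals`).
#' @param baseline Baseline of the first-stage exponential fit, in percent
#'   (default 0 gives `intercept_combined == intercept_ols`).
#' @return An object of class `"alu_neighborfit"` with `beta_ss`,
#'   `beta_rs`, `intercept_ols`, `intercept_combined` and the underlying
#'   `lm` fit. Supports `print` and `coef`.
#' @export
fit_neighbor_regression <- function(residuals, nss, nrs, baseline = 0) {
  stopifnot(length(residuals) == length(nss), length(nss) == length(nrs))
  keep <- !is.na(residuals) & !is.na(nss) & !is.na(nrs)
  df <- data.frame(r = residuals[keep], nss = as.numeric(nss[keep]),
                   nrs = as.numeric(nrs[keep]))
  X <- cbind(1, df$nss, df$nrs)
  if (qr(X)$rank < 3) {
    stop("fit_neighbor_regression: design matrix (1, nss, nrs) is rank deficient")
  }
  fit <- stats::lm(r ~ nss + nrs, data = df)
  cf <- stats::coef(fit)
  structure(list(
    beta_ss = unname(cf["nss"]),
    beta_rs = unname(cf["nrs"]),
    intercept_ols = unname(cf["(Intercept)"]),
    intercept_combined = baseline + unname(cf["(Intercept)"]),
    n = nrow(df),
    lm = fit
  ), class = "alu_neighborfit")
}

#' @export
print.alu_neighborfit <- function(x, digits = 4, ...) {
  cat("Neighbor-count regression on residual editability\n")
  cat(sprintf("  residual ~ %+.*g * Nss %+.*g * Nrs %+.*g\n",
              digits, x$beta_ss, digits, x$beta_rs, digits, x$intercept_ols))
  cat(sprintf("  combined-model intercept: %.4g %%   n = %d\n",
              x$intercept_combined, x$n))
  invisible(x)
}

#' @export
coef.alu_neighborfit <- function(object, ...) {
  c(beta_ss = object$beta_ss, beta_rs = object$beta_rs,
    intercept_combined = object$intercept_combined)
}

#' Editability change predicted by the neighbor-count model
#'
#' Linear effect of adding `delta_nss` same-strand and `delta_nrs`
#' reverse-strand elements to an element's 10-kb neighborhood, all else
#' fixed: `beta_ss * delta_nss + beta_rs * delta_nrs` (percent).
#'
#' @param params An `"alu_neighborfit"` object or anything with `beta_ss`
#'   and `beta_rs` fields.
#' @param delta_nss,delta_nrs Count changes.
#' @return Predicted editability change in percent.
#' @examples
#' neighbor_effect(list(beta_ss = -0.022, beta_rs = 0.015), 10, 0)
#' @export
neighbor_effect <- function(params, delta_nss, delta_nrs) {
  bss <- params$beta_ss
  brs <- params$beta_rs
  if (is.null(bss) || is.null(brs)) stop("params must provide beta_ss and beta_rs")
  bss * delta_nss + brs * delta_nrs
}
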