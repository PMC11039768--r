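#' Fit indices for a fitted uSEM
#'
#' Chi-square and the four standard indices (CFI, NNFI, RMSEA, SRMR), all
#' computed on the stacked 2p-variate covariance. The baseline model is the
#' usual independence model (all 2p variables mutually uncorrelated, variances
#' free), for which the discrepancy is -log|R| with R the stacked correlation
#' matrix. chi2 = (n_eff - 1) * F_ML.
#'
#' @param fit a `fitted_usem`.
#' @param pattern the [path_pattern()] the fit used (defaults to `fit$pattern`).
#' @param S stacked sample covariance (defaults to `fit$S`).
#' @return A list of class `fit_indices`: `chi2`, `df`, `chi2_null`,
#'   `df_null`, `CFI`, `NNFI`, `RMSEA`, `SRMR`.
#' @export
compute_fit_indices <- function(fit, pattern = fit$pattern, S = fit$S) {
  p <- pattern$p
  n1 <- fit$n_eff - 1
  chi2 <- n1 * fit$F_ML
  q <- p * (p + 1) / 2 + sum(pattern$free_A) + sum(pattern$free_Phi) + p
  df <- 2 * p * (2 * p + 1) / 2 - q
  # baseline: independence among the 2p stacked variables
  R <- stats::cov2cor(S)
  F_null <- -as.numeric(determinant(R, logarithm = TRUE)$modulus)
  chi2_null <- n1 * F_null
  df_null <- 2 * p * (2 * p + 1) / 2 - 2 * p
  d <- max(chi2 - df, 0)
  d_null <- max(chi2_null - df_null, 0)
  CFI <- if (max(d, d_null) == 0) 1 else 1 - d / max(d_null, d)
  NNFI <- if (df == 0 || chi2_null / df_null <= 1) 1 else
    ((chi2_null / df_null) - (chi2 / df)) / ((chi2_null / df_null) - 1)
  RMSEA <- if (df == 0) 0 else sqrt(d / (df * n1))
  Sig <- fit$state$Sig
  sd_ <- sqrt(diag(S))
  res <- (S - Sig) / outer(sd_, sd_)
  SRMR <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  structure(list(chi2 = chi2, df = df, chi2_null = chi2_null,
                 df_null = df_null, CFI = CFI, NNFI = NNFI,
                 RMSEA = RMSEA, SRMR = SRMR),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi2(%g) = %.3f | CFI %.4f NNFI %.4f RMSEA %.4f SRMR %.4f\n",
    x$df, x$chi2, x$CFI, x$NNFI, x$RMSEA, x$SRMR))
  invisible(x)
}

#' How many of the four excellent-fit criteria are met
#'
#' Criteria (inclusive at the threshold): CFI >= 0.95, NNFI >= 0.95,
#' RMSEA <= 0.05, SRMR <= 0.05.
#'
#' @param idx a `fit_indices` object or a list with the four indices.
#' @param thresholds named list of the four cutoffs.
#' @return Integer 0-4.
#' @export
fit_criteria_met <- function(idx,
                             thresholds = list(cfi_min = 0.95, nnfi_min = 0.95,
                                               rmsea_max = 0.05,
                                               srmr_max = 0.05)) {
  sum(idx$CFI >= thresholds$cfi_min,
      idx$NNFI >= thresholds$nnfi_min,
      idx$RMSEA <= thresholds$rmsea_max,
      idx$SRMR <= thresholds$srmr_max)
}

#' Excellent model fit: at least two of the four criteria met
#'
#' @inheritParams fit_criteria_met
#' @return `TRUE` iff at least 2 of the 4 criteria are satisfied.
#' @export
excellent_fit <- function(idx,
                          thresholds = list(cfi_min = 0.95, nnfi_min = 0.95,
                                            rmsea_max = 0.05,
                                            srmr_max = 0.05)) {
  stopifnot(all(is.finite(c(idx$CFI, idx$NNFI, idx$RMSEA, idx$SRMR))))
  fit_criteria_met(idx, thresholds) >= 2L
}
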