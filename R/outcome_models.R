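#' Build the six primary regression specifications
#'
#' Two predictor families (within-network and between-network density
#' metrics, filtered by the eligibility set) crossed with the three clinical
#' outcomes: slips (negative binomial), craving during treatment and
#' cue-induced craving (linear on the log-transformed outcome).
#'
#' @param eligibility an `eligibility_set` from [eligible_metrics()].
#' @return List of 6 specs, each `outcome`, `family`, `predictors`,
#'   `covariates`.
#' @export
primary_specs <- function(eligibility) {
  within <- density_metric_names()[1:6]
  between <- density_metric_names()[7:12]
  inc <- names(eligibility$included)[eligibility$included]
  cov <- c("age", "sex", "ftnd", "treatment")
  specs <- list()
  for (outc in c("slips", "craving_treatment", "cue_craving")) {
    for (fam in c("within", "between")) {
      specs[[paste(outc, fam, sep = ".")]] <- list(
        outcome = outc,
        family = if (outc == "slips") "negative_binomial"
        else "gaussian_log_outcome",
        predictor_family = fam,
        predictors = intersect(if (fam == "within") within else between, inc),
        covariates = cov)
    }
  }
  specs
}

model_frame <- function(spec, densities, outcomes, extra_covariates = NULL) {
  tab <- if (is.data.frame(densities)) densities else density_table(densities)
  df <- merge(tab, as.data.frame(outcomes), by = "subject_id")
  if (nrow(df) < nrow(tab))
    stop("unknown subject id when joining densities with outcomes")
  cols <- c(spec$outcome, spec$predictors, spec$covariates, extra_covariates)
  df <- df[c("subject_id", cols)]
  df[stats::complete.cases(df), , drop = FALSE]   # listwise deletion
}

bt <- function(x) if (length(x)) paste0("`", x, "`") else character(0)

#' Negative-binomial regression of a count outcome on density metrics
#'
#' ML negative binomial with log link (dispersion estimated jointly), Wald
#' per-predictor tests, and a model likelihood-ratio chi-square against the
#' covariate-only null.
#'
#' @param spec one element of [primary_specs()] with family
#'   `negative_binomial`.
#' @param densities cohort density table or list of profiles.
#' @param outcomes an `outcome_table`.
#' @param extra_covariates optional additional covariate names (e.g.
#'   `"baseline_cpd"`).
#' @return List of class `regression_result`: `coefficients` (data.frame
#'   `term, b, se, z, p`), `lr_chi2`, `lr_df`, `lr_p`, `theta`, `n_used`,
#'   `converged`, `dropped` (zero-variance predictors removed).
#' @export
fit_count_outcome_model <- function(spec, densities, outcomes,
                                    extra_covariates = NULL) {
  stopifnot(spec$family == "negative_binomial")
  df <- model_frame(spec, densities, outcomes, extra_covariates)
  y <- df[[spec$outcome]]
  if (any(y < 0) || any(y != round(y)))
    stop("count outcome must be non-negative integers")
  preds <- spec$predictors
  novar <- preds[vapply(preds, function(v) stats::sd(df[[v]]) == 0,
                        logical(1))]
  if (length(novar)) {
    warning("dropping zero-variance predictor(s): ",
            paste(novar, collapse = ", "))
    preds <- setdiff(preds, novar)
  }
  covs <- c(spec$covariates, extra_covariates)
  rhs_full <- paste(c(bt(preds), covs, "1"), collapse = " + ")
  rhs_null <- paste(c(covs, "1"), collapse = " + ")
  f_full <- stats::as.formula(paste(bt(spec$outcome), "~", rhs_full))
  f_null <- stats::as.formula(paste(bt(spec$outcome), "~", rhs_null))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(f_full, data = df, control =
                                    stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(coefficients = NULL, lr_chi2 = NA, lr_df = NA,
                          lr_p = NA, theta = NA, n_used = nrow(df),
                          converged = FALSE, dropped = novar),
                     class = "regression_result"))
  }
  null <- suppressWarnings(MASS::glm.nb(f_null, data = df, control =
                                          stats::glm.control(maxit = 100)))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = gsub("`", "", rownames(sm)), b = sm[, 1],
                      se = sm[, 2], z = sm[, 3], p = sm[, 4],
                      row.names = NULL)
  lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(null)))
  lr_df <- length(preds)
  structure(list(coefficients = coefs,
                 lr_chi2 = lr, lr_df = lr_df,
                 lr_p = stats::pchisq(lr, lr_df, lower.tail = FALSE),
                 theta = fit$theta, n_used = nrow(df),
                 converged = isTRUE(fit$converged), dropped = novar,
                 fit = fit),
            class = "regression_result")
}

log_transform_outcome <- function(y) {
  if (any(y <= 0)) log(y - min(y) + 1) else log(y)
}

#' Linear regression of a log-transformed continuous outcome
#'
#' The outcome is log-transformed (shifted log `log(y - min(y) + 1)` when any
#' value is nonpositive, e.g. the post-minus-pre cue-craving difference).
#' Reports unstandardized b, standardized beta (= b * sd(x) / sd(log y)),
#' R-squared and the overall F test.
#'
#' @inheritParams fit_count_outcome_model
#' @return `regression_result` with `coefficients` (`term, b, beta, se, t,
#'   p`), `r_squared`, `F`, `df1`, `df2`, `F_p`, `n_used`.
#' @export
fit_continuous_outcome_model <- function(spec, densities, outcomes,
                                         extra_covariates = NULL) {
  stopifnot(spec$family == "gaussian_log_outcome")
  df <- model_frame(spec, densities, outcomes, extra_covariates)
  y <- log_transform_outcome(df[[spec$outcome]])
  if (stats::sd(y) == 0) stop("outcome constant after transform")
  df$.ly <- y
  preds <- spec$predictors
  novar <- preds[vapply(preds, function(v) stats::sd(df[[v]]) == 0,
                        logical(1))]
  if (length(novar)) {
    warning("dropping zero-variance predictor(s): ",
            paste(novar, collapse = ", "))
    preds <- setdiff(preds, novar)
  }
  covs <- c(spec$covariates, extra_covariates)
  rhs <- paste(c(bt(preds), covs, "1"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".ly ~", rhs)), data = df)
  sm <- summary(fit)
  cf <- sm$coefficients
  terms_ <- rownames(cf)
  sdx <- vapply(terms_, function(tm) {
    tm2 <- gsub("`", "", tm)
    if (tm2 %in% names(df)) stats::sd(df[[tm2]]) else NA_real_
  }, numeric(1))
  beta <- cf[, 1] * sdx / stats::sd(y)
  coefs <- data.frame(term = gsub("`", "", terms_), b = cf[, 1], beta = beta,
                      se = cf[, 2], t = cf[, 3], p = cf[, 4],
                      row.names = NULL)
  fstat <- sm$fstatistic
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 F = unname(fstat[1]), df1 = unname(fstat[2]),
                 df2 = unname(fstat[3]),
                 F_p = stats::pf(fstat[1], fstat[2], fstat[3],
                                 lower.tail = FALSE),
                 n_used = nrow(df), converged = TRUE, dropped = novar,
                 fit = fit),
            class = "regression_result")
}

#' Bonferroni correction across the family of models
#'
#' @param model_pvalues numeric vector of model-level p-values.
#' @param m number of models in the family (defaults to the number of
#'   p-values supplied).
#' @return List: `threshold` (= 0.05 / m), `significant` (logical vector).
#' @export
apply_bonferroni <- function(model_pvalues, m = length(model_pvalues)) {
  stopifnot(m >= 1)
  threshold <- 0.05 / m
  list(threshold = threshold, significant = model_pvalues < threshold, m = m)
}

#' Fit all six primary outcome models
#'
#' @param densities cohort density table or list of profiles.
#' @param outcomes an `outcome_table`.
#' @param eligibility an `eligibility_set`; computed from `densities` if
#'   omitted.
#' @param extra_covariates optional extra covariates for every model.
#' @return List: `results` (6 `regression_result`s), `model_p` (model-level
#'   p-values: LR chi-square p for count models, overall F p for linear
#'   models), `bonferroni`.
#' @export
fit_outcome_models <- function(densities, outcomes, eligibility = NULL,
                               extra_covariates = NULL) {
  if (is.null(eligibility)) eligibility <- eligible_metrics(densities)
  specs <- primary_specs(eligibility)
  results <- lapply(specs, function(sp) {
    if (!length(sp$predictors)) return(NULL)
    if (sp$family == "negative_binomial")
      fit_count_outcome_model(sp, densities, outcomes, extra_covariates)
    else
      fit_continuous_outcome_model(sp, densities, outcomes, extra_covariates)
  })
  model_p <- vapply(results, function(r) {
    if (is.null(r)) return(NA_real_)
    if (!is.null(r$lr_p)) r$lr_p else r$F_p
  }, numeric(1))
  list(results = results, model_p = model_p,
       bonferroni = apply_bonferroni(model_p, m = length(specs)))
}
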