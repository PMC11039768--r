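#!/usr/bin/env Rscript
# Stage 5: link density metrics to clinical outcomes.
#
# Six regressions (within/between predictor families x slips, craving during
# treatment, cue-induced craving): negative binomial for the slips count,
# OLS on the log-transformed craving outcomes, with age, sex, nicotine
# dependence and treatment arm as covariates, Bonferroni-corrected across
# the six models.

suppressPackageStartupMessages(library(netgimme))
tab <- read.csv("results/density/metrics.csv", check.names = FALSE)
outcomes <- read_outcomes("results/cohort/outcomes.csv")
el <- eligible_metrics(tab, threshold = 0.25)

mods <- suppressWarnings(fit_outcome_models(tab, outcomes, eligibility = el))
dir.create("results/outcomes", showWarnings = FALSE, recursive = TRUE)
rows <- list()
for (nm in names(mods$results)) {
  r <- mods$results[[nm]]
  if (is.null(r) || is.null(r$coefficients)) next
  cf <- r$coefficients
  # common schema across count (z) and linear (beta, t) models
  rows[[nm]] <- data.frame(
    model = nm, term = cf$term, b = cf$b,
    beta = if ("beta" %in% names(cf)) cf$beta else NA_real_,
    se = cf$se,
    stat = if ("z" %in% names(cf)) cf$z else cf$t,
    p = cf$p)
  if (!is.null(r$lr_chi2)) {
    cat(sprintf("%-28s LR chi2 = %.3f (df %d, p = %.4f), theta = %.2f, n = %d\n",
                nm, r$lr_chi2, r$lr_df, r$lr_p, r$theta, r$n_used))
  } else {
    cat(sprintf("%-28s R2 = %.3f, F(%d, %d) = %.3f (p = %.4f), n = %d\n",
                nm, r$r_squared, r$df1, r$df2, r$F, r$F_p, r$n_used))
  }
}
coef_tab <- do.call(rbind, rows)
write.csv(coef_tab, "results/outcomes/coefficients.csv", row.names = FALSE)
bc <- mods$bonferroni
cat(sprintf("\nBonferroni threshold across %d models: %.4f\n", bc$m,
            bc$threshold))
sig <- names(mods$model_p)[!is.na(mods$model_p) & bc$significant]
cat("Models surviving correction:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
jsonlite::write_json(
  list(threshold = bc$threshold, model_p = as.list(mods$model_p)),
  "results/outcomes/model_significance.json", auto_unbox = TRUE, digits = NA)
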