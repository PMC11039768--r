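# synthetic cohort of density profiles + outcomes with known coupling
outcome_fixture <- function(n = 200, seed = 3,
                            coeffs = default_outcome_coeffs()) {
  atlas <- default_atlas()
  set.seed(seed)
  profs <- lapply(seq_len(n), function(k) {
    n_edge <- sample(4:12, 1)
    g <- data.frame(source = sample(11, n_edge, TRUE),
                    target = sample(11, n_edge, TRUE),
                    lag = rbinom(n_edge, 1, 0.4),
                    estimate = runif(n_edge, 0.2, 0.5) *
                      sign(runif(n_edge, -1, 1)))
    g <- g[!(g$lag == 0 & g$source == g$target), , drop = FALSE]
    compute_density_profile(g, atlas, subject_id = sprintf("s%03d", k))
  })
  out <- simulate_outcomes(profs, coeffs = coeffs, seed = seed + 1)
  list(profs = profs, tab = density_table(profs), outcomes = out,
       eligibility = eligible_metrics(profs))
}

test_that("negative-binomial fit matches an independent ML oracle", {
  fx <- outcome_fixture(n = 120, seed = 8)
  specs <- primary_specs(fx$eligibility)
  sp <- specs[["slips.within"]]
  res <- fit_count_outcome_model(sp, fx$tab, fx$outcomes)
  expect_true(res$converged)
  # independent ML maximization of the NB log-likelihood
  df <- merge(fx$tab, as.data.frame(fx$outcomes), by = "subject_id")
  Xm <- as.matrix(cbind(1, df[c(sp$predictors, sp$covariates)]))
  y <- df$slips
  nll <- function(par) {
    beta <- par[-length(par)]; th <- exp(par[length(par)])
    mu <- exp(Xm %*% beta)
    -sum(lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
           th * log(th / (th + mu)) + y * log(mu / (th + mu)))
  }
  o <- optim(c(rep(0, ncol(Xm)), 0), nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  o <- optim(o$par, nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  ord <- c("(Intercept)", sp$predictors, sp$covariates)
  got <- res$coefficients$b[match(ord, res$coefficients$term)]
  # same maximum of the likelihood ...
  expect_equal(nll(c(got, log(res$theta))), o$value, tolerance = 1e-6)
  # ... and the same parameter point, to the precision the (flat) likelihood
  # pins down
  expect_equal(got, o$par[seq_len(ncol(Xm))], tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(res$theta, exp(o$par[length(o$par)]), tolerance = 1e-3)
})

test_that("planted count-model coefficients are recovered with right signs", {
  fx <- outcome_fixture(n = 200, seed = 21)
  specs <- primary_specs(fx$eligibility)
  res <- fit_count_outcome_model(specs[["slips.within"]], fx$tab,
                                 fx$outcomes)
  cf <- res$coefficients
  b_sn <- cf[cf$term == "SN-SN_pos", ]
  expect_gt(b_sn$b, 0)                        # planted +20
  expect_lt(abs(b_sn$b - 20) / b_sn$se, 2.5)  # near truth in SE units
  resb <- fit_count_outcome_model(specs[["slips.between"]], fx$tab,
                                  fx$outcomes)
  b_df <- resb$coefficients[resb$coefficients$term == "DMN-FPN_pos", ]
  expect_lt(b_df$b, 0)                        # planted -20
  expect_gt(res$lr_chi2, 0)
  expect_lt(res$lr_p, 0.05)
  # adding baseline cigarettes/day leaves the signs unchanged
  resc <- fit_count_outcome_model(specs[["slips.within"]], fx$tab,
                                  fx$outcomes,
                                  extra_covariates = "baseline_cpd")
  expect_gt(resc$coefficients$b[resc$coefficients$term == "SN-SN_pos"], 0)
})

test_that("linear model: planted signs, beta identity, df bookkeeping", {
  fx <- outcome_fixture(n = 200, seed = 22)
  specs <- primary_specs(fx$eligibility)
  sp <- specs[["craving_treatment.between"]]
  res <- fit_continuous_outcome_model(sp, fx$tab, fx$outcomes)
  cf <- res$coefficients
  expect_lt(cf$beta[cf$term == "DMN-SN_neg"], 0)   # planted -10
  expect_gt(cf$beta[cf$term == "SN-FPN_pos"], 0)   # planted +10
  # standardized beta identity: beta = b * sd(x) / sd(log y)
  df <- merge(fx$tab, as.data.frame(fx$outcomes), by = "subject_id")
  ly <- log(df$craving_treatment)
  for (tm in sp$predictors) {
    expect_equal(cf$beta[cf$term == tm],
                 cf$b[cf$term == tm] * sd(df[[tm]]) / sd(ly),
                 tolerance = 1e-10)
  }
  # 6 predictors + 4 covariates at n_used = 48 gives F(10, 37)
  sub <- fx$tab[1:48, ]
  subo <- as.data.frame(fx$outcomes)[1:48, ]
  spfull <- sp; spfull$predictors <- density_metric_names()[7:12]
  res48 <- fit_continuous_outcome_model(spfull, sub,
                                        as_outcome_table(subo))
  expect_equal(res48$df1, 10)
  expect_equal(res48$df2, 37)
  expect_equal(res48$n_used, 48)
})

test_that("degenerate predictors and outcomes are handled as specified", {
  fx <- outcome_fixture(n = 60, seed = 30)
  specs <- primary_specs(fx$eligibility)
  sp <- specs[["slips.within"]]
  sp$predictors <- "SN-SN_pos"
  sp$covariates <- character(0)
  tab0 <- fx$tab
  tab0[["SN-SN_pos"]] <- 0.1                      # no variation
  expect_warning(res <- fit_count_outcome_model(sp, tab0, fx$outcomes),
                 "zero-variance")
  expect_equal(res$coefficients$b[res$coefficients$term == "(Intercept)"],
               log(mean(fx$outcomes$slips)), tolerance = 1e-6)

  spc <- specs[["craving_treatment.within"]]
  outc <- as.data.frame(fx$outcomes)
  outc$craving_treatment <- 2.5                   # constant after transform
  expect_error(fit_continuous_outcome_model(spc, fx$tab,
                                            as_outcome_table(outc)),
               "constant")
  outn <- as.data.frame(fx$outcomes)
  outn$slips[1] <- 2.5                            # non-integer count
  expect_error(fit_count_outcome_model(specs[["slips.within"]], fx$tab,
                                       as_outcome_table(outn)))
})

test_that("shifted log is used only when the outcome has nonpositive values", {
  y_pos <- c(1, 2, 3)
  expect_equal(netgimme:::log_transform_outcome(y_pos), log(y_pos))
  y_mix <- c(-1, 0, 2)
  expect_equal(netgimme:::log_transform_outcome(y_mix), log(y_mix + 2))
})

test_that("Bonferroni correction across the six models", {
  bc <- apply_bonferroni(rep(0.5, 6))
  expect_equal(bc$threshold, 0.05 / 6)
  expect_equal(round(bc$threshold, 3), 0.008)
  expect_equal(apply_bonferroni(0.2, m = 1)$threshold, 0.05)
  # p = 0.010 does not survive correction across 6 models
  bc2 <- apply_bonferroni(c(0.010, 0.002), m = 6)
  expect_false(bc2$significant[1])
  expect_true(bc2$significant[2])
})
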