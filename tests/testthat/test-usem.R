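test_that("optimal discrepancy matches a brute-force oracle", {
  fx <- fixture3()
  fit <- fit_usem(fx$X, fx$pattern, standardize = FALSE)
  expect_true(fit$converged)
  or <- oracle_fml(fx$X, fx$pattern$free_A, fx$pattern$free_Phi)
  expect_lt(abs(fit$F_ML - or$F), 1e-6)
  # AR-only pattern as a second, more misspecified case
  pat0 <- ar_only_pattern(3)
  fit0 <- fit_usem(fx$X, pat0, standardize = FALSE)
  or0 <- oracle_fml(fx$X, pat0$free_A, pat0$free_Phi)
  expect_lt(abs(fit0$F_ML - or0$F), 1e-6)
})

test_that("estimates are consistent: within 0.05 of truth at T = 20000", {
  A <- matrix(0, 3, 3); Phi <- matrix(0, 3, 3)
  A[2, 1] <- 0.4; A[3, 2] <- -0.25
  diag(Phi) <- c(0.3, 0.45, 0.25); Phi[1, 3] <- 0.2
  X <- sim_var(A, Phi, 20000, seed = 77)
  pat <- path_pattern(A != 0, Phi != 0 | diag(TRUE, 3))
  fit <- fit_usem(X, pat, standardize = FALSE)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$A_hat - A)), 0.05)
  expect_lt(max(abs(fit$Phi_hat - Phi)), 0.05)
  expect_lt(max(abs(fit$psi_hat - 1)), 0.05)
})

test_that("white noise under the empty pattern: near-zero discrepancy", {
  set.seed(5)
  X <- matrix(rnorm(4000 * 3), 4000, 3)
  fit <- fit_usem(X, ar_only_pattern(3, ar = FALSE), standardize = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$F_ML, 0.01)
  expect_equal(unname(fit$psi_hat), rep(1, 3), tolerance = 0.1)
  expect_equal(fit$n_eff, 3999L)
})

test_that("freeing an extra path never increases the optimum (nesting)", {
  set.seed(8)
  for (rep in 1:3) {
    A <- matrix(0, 3, 3); Phi <- diag(runif(3, 0.2, 0.5))
    A[2, 1] <- runif(1, 0.2, 0.4)
    X <- sim_var(A, Phi, 400, seed = 30 + rep)
    pat <- ar_only_pattern(3)
    f0 <- fit_usem(X, pat, standardize = FALSE)
    cand <- all_candidates(pat)
    pick <- cand[sample(nrow(cand), 3), ]
    for (k in 1:3) {
      pat2 <- netgimme:::pattern_add(pat, pick$lag[k], pick$source[k],
                                     pick$target[k])
      f2 <- fit_usem(X, pat2, standardize = FALSE)
      expect_lte(f2$F_ML, f0$F_ML + 1e-8)
    }
  }
})

test_that("estimates are equivariant under ROI relabeling", {
  fx <- fixture3()
  perm <- c(3, 1, 2)
  Xp <- fx$X[, perm]
  pat_p <- path_pattern(fx$pattern$free_A[perm, perm],
                        fx$pattern$free_Phi[perm, perm])
  fit <- fit_usem(fx$X, fx$pattern, standardize = FALSE)
  fitp <- fit_usem(Xp, pat_p, standardize = FALSE)
  expect_equal(fitp$A_hat, fit$A_hat[perm, perm], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fitp$Phi_hat, fit$Phi_hat[perm, perm], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fitp$F_ML, fit$F_ML, tolerance = 1e-8)
})

test_that("chi-square is calibrated: mean near its df on true-model data", {
  A <- matrix(0, 3, 3); Phi <- diag(c(0.4, 0.3, 0.2))
  A[2, 1] <- 0.35
  pat <- path_pattern(A != 0, diag(TRUE, 3))
  chis <- vapply(1:40, function(r) {
    X <- sim_var(A, Phi, 2000, seed = 500 + r)
    f <- fit_usem(X, pat, standardize = FALSE)
    (f$n_eff - 1) * f$F_ML
  }, numeric(1))
  idx_df <- compute_fit_indices(
    fit_usem(sim_var(A, Phi, 2000, seed = 1), pat, standardize = FALSE))$df
  expect_lt(abs(mean(chis) - idx_df) / idx_df, 0.15)
})

test_that("degenerate inputs are rejected with clear errors", {
  set.seed(3)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Xc <- cbind(X, X[, 3])            # collinear: singular stacked covariance
  expect_error(fit_usem(Xc, ar_only_pattern(4), standardize = FALSE),
               "singular|longer")
  expect_error(fit_usem(X[1:10, ], ar_only_pattern(3)), "too few")
  expect_error(path_pattern(diag(TRUE, 3), diag(TRUE, 3)), "self-loop")
})
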