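test_that("default truth mirrors the reported group-path counts", {
  str <- make_true_structure(default_atlas(), simulation_params(seed = 2))
  gp <- str$group_paths
  expect_equal(sum(gp$lag == 0), 10)           # contemporaneous group paths
  expect_equal(sum(gp$lag == 1), 3)            # lagged group paths
  expect_length(str$ar_coefficients, 11)       # AR for every ROI
  expect_equal(unname(table(str$subgroup_assignment)), c(39L, 10L),
               ignore_attr = TRUE)
  expect_equal(nrow(str$subgroup_paths[["1"]]), 6)
  expect_equal(nrow(str$subgroup_paths[["2"]]), 18)
  # determinism
  str2 <- make_true_structure(default_atlas(), simulation_params(seed = 2))
  expect_identical(str$group_paths, str2$group_paths)
  expect_identical(str$individual_paths, str2$individual_paths)
})

test_that("degenerate rates give every subject the identical truth", {
  prm <- simulation_params(n_subjects = 4L, subgroup_sizes = NULL,
                           individual_rate = 0, seed = 3)
  str <- make_true_structure(default_atlas(), prm)
  t1 <- subject_truth(str, "sub01")
  for (id in c("sub02", "sub03", "sub04")) {
    tk <- subject_truth(str, id)
    expect_identical(tk$A, t1$A)
    expect_identical(tk$Phi, t1$Phi)
  }
})

test_that("every generated subject is stationary and shapes are right", {
  prm <- simulation_params(n_subjects = 6L, T_len = 120L,
                           subgroup_sizes = c(4L, 2L),
                           subgroup_extra = c(2L, 2L), seed = 4)
  str <- make_true_structure(default_atlas(), prm)
  for (id in names(str$subgroup_assignment))
    expect_true(is_stationary(subject_truth(str, id)))
  coh <- simulate_cohort(str, prm)
  expect_length(coh, 6)
  expect_equal(dim(coh[[1]]$data), c(120L, 11L))
  # same master seed twice: bit-identical; per-subject seeds differ
  coh2 <- simulate_cohort(str, prm)
  expect_identical(coh[[1]]$data, coh2[[1]]$data)
  expect_false(identical(coh[[1]]$data, coh[[2]]$data))
})

test_that("null dynamics give white noise; planted paths match closed forms", {
  atlas <- network_atlas(paste0("r", 1:3), c("DMN", "SN", "FPN"))
  base <- list(group_paths = data.frame(), subgroup_paths = list(),
               individual_paths = list(),
               ar_coefficients = rep(0, 3), noise_sd = rep(1, 3),
               subgroup_assignment = c(s1 = 1L), atlas = atlas)
  class(base) <- "true_structure"
  base$individual_paths <- list(s1 = data.frame(
    lag = integer(), source = integer(), target = integer(),
    coefficient = numeric()))

  ts <- simulate_subject_timeseries(base, "s1", T_len = 500, seed = 9)
  ac <- apply(ts$data, 2, function(x)
    cor(x[-1], x[-length(x)]))
  expect_true(all(abs(ac) < 0.1))

  # single AR path phi = 0.5: lag-1 autocorrelation about 0.5
  ar <- base; ar$ar_coefficients <- c(0.5, 0, 0)
  ts2 <- simulate_subject_timeseries(ar, "s1", T_len = 5000, seed = 10)
  r <- cor(ts2$data[-1, 1], ts2$data[-5000, 1])
  expect_equal(r, 0.5, tolerance = 0.05)

  # single contemporaneous path a21 = 0.5: corr = 0.5/sqrt(1.25)
  cp <- base
  cp$individual_paths$s1 <- data.frame(lag = 0L, source = 1L, target = 2L,
                                       coefficient = 0.5)
  ts3 <- simulate_subject_timeseries(cp, "s1", T_len = 5000, seed = 11)
  expect_equal(cor(ts3$data[, 1], ts3$data[, 2]), 0.5 / sqrt(1.25),
               tolerance = 0.03)
})

test_that("sample covariance converges to the Lyapunov solution", {
  A <- matrix(0, 4, 4); Phi <- matrix(0, 4, 4)
  A[2, 1] <- 0.4; A[3, 2] <- -0.3
  diag(Phi) <- c(0.5, 0.3, 0.4, 0.2); Phi[4, 1] <- 0.25
  atlas <- network_atlas(paste0("r", 1:4), c("DMN", "DMN", "SN", "SN"))
  str <- list(group_paths = data.frame(
    lag = c(0L, 0L, 1L), source = c(1L, 2L, 1L), target = c(2L, 3L, 4L),
    coefficient = c(0.4, -0.3, 0.25)),
    subgroup_paths = list(), individual_paths = list(),
    ar_coefficients = diag(Phi), noise_sd = rep(1, 4),
    subgroup_assignment = c(s1 = 1L), atlas = atlas)
  class(str) <- "true_structure"
  V <- stationary_covariance(list(A = A, Phi = Phi), rep(1, 4))
  ts <- simulate_subject_timeseries(str, "s1", T_len = 20000, seed = 12)
  Shat <- cov(ts$data)
  expect_lt(max(abs(Shat - V) / max(abs(V))), 0.02)
})

test_that("outcome generator: null coupling, determinism, dispersion guard", {
  atlas <- default_atlas()
  set.seed(20)
  # synthetic density profiles with spread in every metric
  profs <- lapply(1:200, function(k) {
    g <- data.frame(source = sample(11, 8), target = sample(11, 8),
                    lag = rbinom(8, 1, 0.5),
                    estimate = runif(8, -0.5, 0.5))
    g <- g[!(g$lag == 1 & g$source == g$target) & g$source != g$target, ]
    compute_density_profile(g, atlas, "possible",
                            subject_id = sprintf("s%03d", k))
  })
  zero <- default_outcome_coeffs()
  zero$slips[c("snsn_pos", "dmnfpn_pos")] <- list(0, 0)
  zero$craving[c("dmnsn_neg", "snfpn_pos")] <- list(0, 0)
  zero$cue["snfpn_neg"] <- list(0)
  out <- simulate_outcomes(profs, coeffs = zero, seed = 5)
  expect_true(all(out$slips >= 0 & out$slips == round(out$slips)))
  tab <- density_table(profs)
  for (m in c("SN-SN_pos", "DMN-FPN_pos", "DMN-SN_neg"))
    expect_lt(abs(cor(tab[[m]], out$slips)), 0.15)
  out2 <- simulate_outcomes(profs, coeffs = zero, seed = 5)
  expect_identical(out, out2)
  bad <- default_outcome_coeffs(); bad$slips$theta <- 0
  expect_error(simulate_outcomes(profs, coeffs = bad), "theta")
})
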