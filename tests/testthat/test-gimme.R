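make_shared_cohort <- function(K, T_len, a = 0.4, seed = 1, p = 4) {
  A <- matrix(0, p, p); Phi <- diag(rep(0.35, p))
  A[2, 1] <- a
  lapply(seq_len(K), function(k) sim_var(A, Phi, T_len, seed = seed * 100 + k))
}

test_that("group search recovers a shared planted path and nothing else", {
  cfg <- search_config()
  ok <- vapply(1:3, function(r) {
    coh <- make_shared_cohort(10, 300, seed = r)
    grp <- group_search(coh, cfg)
    nrow(grp$group_paths) == 1 &&
      grp$group_paths$lag == 0 &&
      grp$group_paths$source == 1 && grp$group_paths$target == 2
  }, logical(1))
  expect_gte(mean(ok), 2 / 3)
})

test_that("white-noise cohort yields no non-AR group paths", {
  cfg <- search_config()
  for (r in 1:2) {
    set.seed(1000 + r)
    coh <- lapply(1:8, function(k) matrix(rnorm(300 * 4), 300, 4))
    grp <- group_search(coh, cfg)
    expect_equal(nrow(grp$group_paths), 0)
  }
})

test_that("a path shared by only 60% of subjects is not a group path", {
  # strong-signal regime below the 75% majority
  p <- 4
  A1 <- matrix(0, p, p); A1[2, 1] <- 0.5
  Phi <- diag(rep(0.35, p))
  coh <- c(lapply(1:6, function(k) sim_var(A1, Phi, 400, seed = 40 + k)),
           lapply(1:4, function(k) sim_var(matrix(0, p, p), Phi, 400,
                                           seed = 60 + k)))
  grp <- group_search(coh, search_config())
  expect_false("0 1 2" %in% path_keys(grp$group_paths))
})

test_that("group search is invariant to subject order", {
  coh <- make_shared_cohort(6, 250, seed = 9)
  g1 <- group_search(coh, search_config())
  g2 <- group_search(rev(coh), search_config())
  expect_setequal(path_keys(g1$group_paths), path_keys(g2$group_paths))
})

test_that("similarity counts shared (path, sign) features only", {
  feats <- list(s1 = c("0:1:2 1", "0:3:4 -1", "1:2:3 1"),
                s2 = c("0:1:2 1", "0:3:4 -1", "1:2:3 1"),
                s3 = c("0:1:2 -1", "1:4:2 1"),
                s4 = character(0))
  sim <- netgimme:::similarity_from_features(feats)
  expect_equal(sim["s1", "s2"], 3L)     # identical sets of size 3
  expect_equal(sim["s1", "s3"], 0L)     # same path, opposite sign: no credit
  expect_equal(sim["s1", "s4"], 0L)     # disjoint
  expect_true(isSymmetric(sim))
  expect_true(all(diag(sim) == 0))
})

test_that("walktrap subgrouping: blocks, zero matrix, contiguous ids", {
  # two disconnected blocks of uniform within-block similarity
  sim <- matrix(0L, 7, 7)
  sim[1:4, 1:4] <- 5L; sim[5:7, 5:7] <- 5L; diag(sim) <- 0L
  sol <- detect_subgroups(sim, search_config())
  expect_equal(sol$n_subgroups, 2)
  expect_length(unique(sol$assignment[1:4]), 1)
  expect_length(unique(sol$assignment[5:7]), 1)
  expect_equal(sort(unique(sol$assignment)), 1:2)
  expect_false(sol$degenerate)

  z <- matrix(0L, 5, 5)
  solz <- detect_subgroups(z, search_config())
  expect_true(solz$degenerate)
  expect_equal(solz$n_subgroups, 5)
})

test_that("individual search stops early, honors the cap, tags paths", {
  fx <- fixture3(T_len = 500, seed = 71)
  cfg <- search_config()
  # the true pattern already fits excellently: nothing added
  ind <- individual_search(fx$X, fx$pattern, config = cfg)
  expect_true(excellent_fit(ind$indices))
  expect_equal(nrow(ind$individual_paths), 0)

  # cap of zero returns the base pattern unchanged
  pat0 <- ar_only_pattern(3)
  cfg0 <- search_config(max_paths = 0L)
  ind0 <- individual_search(fx$X, pat0, config = cfg0)
  expect_identical(ind0$pattern$free_A, pat0$free_A)
  expect_identical(ind0$pattern$free_Phi, pat0$free_Phi)

  # one strong idiosyncratic contemporaneous path is found
  ind1 <- individual_search(fx$X, pat0, config = cfg)
  expect_true(ind1$pattern$free_A[2, 1])
})

test_that("full search: level tags partition edges, nesting, determinism", {
  run <- cached_small_run()
  res <- run$result
  gk <- path_keys(res$group_paths)
  for (id in names(res$edges)) {
    e <- res$edges[[id]]
    expect_true(all(e$level %in% c("group", "subgroup", "individual")))
    # group paths present in every subject's final pattern
    expect_true(all(gk %in% path_keys(e)))
    # level tags are unique per edge (partition)
    expect_equal(anyDuplicated(path_keys(e)), 0)
    # every subject converged
    expect_true(res$fits[[id]]$converged)
  }
  # subgroup paths present in all members' patterns
  for (sg in names(res$subgroup_paths)) {
    members <- names(res$subgroups$assignment)[
      res$subgroups$assignment == as.integer(sg)]
    for (id in members)
      expect_true(all(path_keys(res$subgroup_paths[[sg]]) %in%
                        path_keys(res$edges[[id]])))
  }
  # determinism: same cohort, same config, identical result
  res2 <- run_gimme(run$cohort, search_config())
  expect_identical(res2$group_paths, res$group_paths)
  expect_identical(res2$subgroups$assignment, res$subgroups$assignment)
  expect_equal(res2$mean_fit, res$mean_fit, tolerance = 1e-10)
})
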