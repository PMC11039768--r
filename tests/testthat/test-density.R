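test_that("density counting: categories, signs, denominators", {
  atlas <- default_atlas()      # DMN rois 1:2, SN 3:7, FPN 8:11
  empty <- data.frame(source = integer(), target = integer(),
                      lag = integer(), estimate = numeric())
  pr0 <- compute_density_profile(empty, atlas)
  expect_true(all(pr0$values == 0))

  # two positive contemporaneous SN-SN edges, mode "possible": 2 / (2*5*4)
  g <- data.frame(source = c(3, 4), target = c(5, 6), lag = 0,
                  estimate = c(0.3, 0.2))
  pr <- compute_density_profile(g, atlas, "possible")
  expect_equal(unname(pr$values["SN-SN_pos"]), 2 / 40)
  expect_equal(unname(pr$counts["SN-SN_pos"]), 2)

  # sign split within a category
  g2 <- data.frame(source = c(3, 4), target = c(5, 6), lag = 0,
                   estimate = c(0.3, -0.2))
  pr2 <- compute_density_profile(g2, atlas)
  expect_equal(unname(pr2$counts[c("SN-SN_pos", "SN-SN_neg")]), c(1, 1))

  # AR self-loops are excluded; lagged cross paths count
  g3 <- data.frame(source = c(3, 1), target = c(3, 9), lag = 1,
                   estimate = c(0.5, -0.4))
  pr3 <- compute_density_profile(g3, atlas)
  expect_equal(sum(pr3$counts), 1)
  expect_equal(unname(pr3$counts["DMN-FPN_neg"]), 1)

  # zero estimate: sign undefined
  g4 <- data.frame(source = 3, target = 5, lag = 0, estimate = 0)
  expect_error(compute_density_profile(g4, atlas), "zero estimate")
})

test_that("count conservation and total-mode sum-to-one on random graphs", {
  atlas <- default_atlas()
  set.seed(31)
  for (r in 1:10) {
    n_edge <- sample(1:25, 1)
    g <- data.frame(source = sample(11, n_edge, TRUE),
                    target = sample(11, n_edge, TRUE),
                    lag = rbinom(n_edge, 1, 0.5),
                    estimate = runif(n_edge, -1, 1) + 1e-6)
    g <- g[!(g$lag == 0 & g$source == g$target), , drop = FALSE]
    non_ar <- sum(!(g$lag == 1 & g$source == g$target))
    pr_p <- compute_density_profile(g, atlas, "possible")
    expect_equal(sum(pr_p$counts), non_ar)
    if (non_ar > 0) {
      pr_t <- compute_density_profile(g, atlas, "total")
      expect_equal(sum(pr_t$values), 1)
    }
  }
})

test_that("densities are invariant to ROI relabeling within a network", {
  atlas <- default_atlas()
  # swap two SN rois (3 and 5) in the edge list
  g <- data.frame(source = c(3, 5, 1, 8), target = c(5, 9, 3, 2), lag = 0,
                  estimate = c(0.4, -0.3, 0.2, 0.5))
  swap <- function(v) ifelse(v == 3, 5L, ifelse(v == 5, 3L, v))
  g2 <- transform(g, source = swap(source), target = swap(target))
  expect_equal(compute_density_profile(g, atlas)$values,
               compute_density_profile(g2, atlas)$values)
})

test_that("eligibility boundary: 13/49 in, 6/49 out, 16/49 in", {
  atlas <- default_atlas()
  # build 49 synthetic profiles with controlled nonzero counts
  make_prof <- function(has_dmnsn_neg, has_dmndmn_neg, has_snfpn_neg, id) {
    edges <- data.frame(source = 3, target = 4, lag = 0, estimate = 0.5)
    if (has_dmnsn_neg)
      edges <- rbind(edges, data.frame(source = 1, target = 3, lag = 0,
                                       estimate = -0.4))
    if (has_dmndmn_neg)
      edges <- rbind(edges, data.frame(source = 1, target = 2, lag = 0,
                                       estimate = -0.4))
    if (has_snfpn_neg)
      edges <- rbind(edges, data.frame(source = 3, target = 8, lag = 0,
                                       estimate = -0.4))
    compute_density_profile(edges, atlas, subject_id = id)
  }
  profs <- lapply(1:49, function(k)
    make_prof(k <= 13, k <= 6, k <= 16, sprintf("s%02d", k)))
  el <- eligible_metrics(profs, threshold = 0.25)
  expect_equal(el$min_n, 13)                       # ceiling(0.25 * 49)
  expect_true(el$included[["DMN-SN_neg"]])         # 13 subjects: retained
  expect_false(el$included[["DMN-DMN_neg"]])       # 6 subjects: excluded
  expect_true(el$included[["SN-FPN_neg"]])         # 16 subjects: retained
  expect_true(el$included[["SN-SN_pos"]])          # all 49
  expect_equal(unname(el$n_nonzero[["DMN-SN_neg"]]), 13)
})

test_that("density summary reports nonzero counts, mean, sd, range", {
  atlas <- default_atlas()
  g1 <- data.frame(source = 3, target = 4, lag = 0, estimate = 0.5)
  g2 <- data.frame(source = c(3, 1), target = c(4, 2), lag = 0,
                   estimate = c(0.25, 0.3))
  profs <- list(compute_density_profile(g1, atlas, subject_id = "a"),
                compute_density_profile(g2, atlas, subject_id = "b"))
  sm <- density_summary(profs)
  row <- sm[sm$metric == "SN-SN_pos", ]
  expect_equal(row$n_nonzero, 2)
  expect_equal(row$mean, 1 / 40)
  row2 <- sm[sm$metric == "DMN-DMN_pos", ]
  expect_equal(row2$n_nonzero, 1)
  expect_equal(row2$max, 1 / 4)           # one of 2*2*(2-1) admissible paths
})
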