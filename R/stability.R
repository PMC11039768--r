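#' Rewire a fraction of similarity-graph edges
#'
#' Selects `ceiling(alpha * m)` of the m nonzero dyads (unordered subject
#' pairs) and swaps each one's weight with a uniformly chosen other dyad.
#' The multiset of off-diagonal weights, the symmetry and the zero diagonal
#' are preserved exactly; `alpha = 0` returns the input unchanged.
#'
#' @param sim symmetric nonnegative similarity matrix, zero diagonal.
#' @param alpha fraction of nonzero dyads to perturb, in [0, 1].
#' @param seed RNG seed.
#' @return The rewired similarity matrix.
#' @export
rewire_graph <- function(sim, alpha, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1)
  K <- nrow(sim)
  ut <- which(upper.tri(sim))
  nz <- ut[sim[ut] != 0]
  if (length(nz) < 2) stop("graph must have at least 2 nonzero dyads")
  if (alpha == 0) return(sim)
  set.seed(seed)
  k <- ceiling(alpha * length(nz))
  chosen <- sample(nz, k)
  out <- sim
  for (cell in chosen) {
    other <- sample(setdiff(ut, cell), 1)
    tmp <- out[cell]
    out[cell] <- out[other]
    out[other] <- tmp
  }
  # mirror the upper triangle
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 0
  out
}

#' Variation of information and adjusted Rand index of two partitions
#'
#' VI = H(P|Q) + H(Q|P), reported in bits; ARI is the chance-adjusted Rand
#' agreement.
#'
#' @param P,Q partition assignments over the same subjects (integer vectors
#'   or factors; names, if present, must agree).
#' @return List `vi`, `ari`.
#' @export
compare_partitions <- function(P, Q) {
  if (length(P) != length(Q))
    stop("partitions are over different subject sets")
  if (!is.null(names(P)) && !is.null(names(Q)) &&
      !identical(names(P), names(Q)))
    stop("partitions are over different subject sets")
  n <- length(P)
  ct <- table(P, Q)
  pij <- ct / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nzr <- pij > 0
  Hp <- -sum(pi_[pi_ > 0] * log2(pi_[pi_ > 0]))
  Hq <- -sum(pj_[pj_ > 0] * log2(pj_[pj_ > 0]))
  I <- sum(pij[nzr] * log2(pij[nzr] / outer(pi_, pj_)[nzr]))
  vi <- Hp + Hq - 2 * I
  # adjusted Rand
  a <- rowSums(ct); b <- colSums(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  ari <- if (maxidx == expected) 1 else (sum_ij - expected) /
    (maxidx - expected)
  list(vi = max(vi, 0), ari = ari)
}

# partition with a random fraction of subjects reassigned to a different
# existing subgroup
random_reassign <- function(assignment, fraction) {
  groups <- sort(unique(assignment))
  if (length(groups) < 2)
    stop("reassignment benchmark undefined for a single-subgroup solution")
  n <- length(assignment)
  k <- ceiling(fraction * n)
  move <- sample.int(n, k)
  out <- assignment
  for (i in move) out[i] <- sample(setdiff(groups, assignment[i]), 1)
  out
}

#' Perturbation-based stability assessment of a subgrouping solution
#'
#' For each perturbation fraction, rewires the similarity graph `n_reps`
#' times, re-runs Walktrap, and averages VI/ARI against the original
#' solution. The benchmark is the average VI/ARI between the original
#' partition and copies with a random `reassign_fraction` (20 percent) of
#' subjects moved to different subgroups. The solution is declared stable if
#' the smallest fraction whose mean VI reaches the benchmark is at least
#' 0.20 (or is never reached).
#'
#' @param sim similarity matrix the solution was obtained from.
#' @param solution a `subgroup_solution` from [detect_subgroups()].
#' @param alphas increasing perturbation fractions (default 0.01..1 step
#'   0.01).
#' @param n_reps replicates per fraction (default 100).
#' @param seed RNG seed.
#' @param config a [search_config()] (Walktrap steps).
#' @param reassign_fraction node fraction for the benchmark (default 0.20).
#' @return List of class `stability_result` with `curve` (data.frame
#'   `alpha, vi_mean, ari_mean`), `benchmark_vi`, `benchmark_ari`,
#'   `alpha_star`, `stable`, `assessable`.
#' @export
assess_stability <- function(sim, solution, alphas = seq(0.01, 1, 0.01),
                             n_reps = 100L, seed = 1L,
                             config = search_config(),
                             reassign_fraction = 0.20) {
  stopifnot(all(diff(alphas) > 0), all(alphas >= 0), all(alphas <= 1))
  orig <- solution$assignment
  if (length(unique(orig)) < 2) {
    return(structure(list(curve = NULL, benchmark_vi = NA_real_,
                          benchmark_ari = NA_real_, alpha_star = NA_real_,
                          stable = NA, assessable = FALSE,
                          note = "single-subgroup solution: not assessable"),
                     class = "stability_result"))
  }
  seeds <- derive_seeds(seed, length(alphas) * n_reps + n_reps)
  vi_mean <- ari_mean <- numeric(length(alphas))
  sctr <- 0L
  for (ai in seq_along(alphas)) {
    vis <- aris <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      sctr <- sctr + 1L
      pert <- rewire_graph(sim, alphas[ai], seed = seeds[sctr])
      psol <- detect_subgroups(pert, config)
      cmp <- compare_partitions(orig, psol$assignment)
      vis[r] <- cmp$vi; aris[r] <- cmp$ari
    }
    vi_mean[ai] <- mean(vis); ari_mean[ai] <- mean(aris)
  }
  bvi <- bari <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sctr <- sctr + 1L
    set.seed(seeds[sctr])
    re <- random_reassign(orig, reassign_fraction)
    cmp <- compare_partitions(orig, re)
    bvi[r] <- cmp$vi; bari[r] <- cmp$ari
  }
  benchmark_vi <- mean(bvi); benchmark_ari <- mean(bari)
  reached <- which(vi_mean >= benchmark_vi)
  alpha_star <- if (length(reached)) alphas[reached[1]] else NA_real_
  evaluable <- any(alphas >= reassign_fraction)
  stable <- if (!evaluable) NA else if (is.na(alpha_star)) TRUE else
    alpha_star >= reassign_fraction
  structure(list(curve = data.frame(alpha = alphas, vi_mean = vi_mean,
                                    ari_mean = ari_mean),
                 benchmark_vi = benchmark_vi, benchmark_ari = benchmark_ari,
                 alpha_star = alpha_star, stable = stable,
                 assessable = evaluable,
                 note = if (!evaluable)
                   "grid does not reach the 20% benchmark fraction"),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  if (isFALSE(x$assessable) && is.null(x$curve)) {
    cat("stability: not assessable (", x$note, ")\n"); return(invisible(x))
  }
  cat("stability: alpha* =", x$alpha_star, "| benchmark VI =",
      round(x$benchmark_vi, 3), "bits | stable =", x$stable, "\n")
  invisible(x)
}
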