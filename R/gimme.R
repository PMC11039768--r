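#' Search configuration
#'
#' @param gamma_group fraction of subjects a candidate must significantly
#'   improve to become a group path (default 0.75).
#' @param gamma_sub same criterion within a subgroup (default 0.50).
#' @param alpha significance level for modification indices and pruning.
#' @param walktrap_steps random-walk length for community detection.
#' @param max_paths cap on individual-level additions per subject.
#' @param ar_start start from the AR-only pattern (default) or literally
#'   empty.
#' @param allow_reciprocal admit contemporaneous reciprocal pairs.
#' @param standardize z-score series before fitting.
#' @param thresholds excellent-fit cutoffs, see [excellent_fit()].
#' @return List of class `search_config`.
#' @export
search_config <- function(gamma_group = 0.75, gamma_sub = 0.50, alpha = 0.05,
                          walktrap_steps = 4L, max_paths = 20L,
                          ar_start = TRUE, allow_reciprocal = TRUE,
                          standardize = TRUE,
                          thresholds = list(cfi_min = 0.95, nnfi_min = 0.95,
                                            rmsea_max = 0.05,
                                            srmr_max = 0.05)) {
  stopifnot(gamma_group >= 0.5, gamma_group <= 1, alpha > 0, alpha < 1)
  structure(list(gamma_group = gamma_group, gamma_sub = gamma_sub,
                 alpha = alpha, walktrap_steps = walktrap_steps,
                 max_paths = max_paths, ar_start = ar_start,
                 allow_reciprocal = allow_reciprocal,
                 standardize = standardize, thresholds = thresholds),
            class = "search_config")
}

cohort_matrices <- function(cohort) {
  lapply(cohort, function(ts)
    if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts))
}

fit_all <- function(mats, pattern, config, starts = NULL) {
  lapply(seq_along(mats), function(k) {
    st <- if (!is.null(starts)) starts[[k]] else NULL
    tryCatch(fit_usem(mats[[k]], pattern, standardize = config$standardize,
                      start = st),
             error = function(e) NULL)
  })
}

# add one path to a pattern
pattern_add <- function(pattern, lag, source, target) {
  fA <- pattern$free_A; fP <- pattern$free_Phi
  if (lag == 0) fA[target, source] <- TRUE else fP[target, source] <- TRUE
  path_pattern(fA, fP)
}

pattern_remove <- function(pattern, lag, source, target) {
  fA <- pattern$free_A; fP <- pattern$free_Phi
  if (lag == 0) fA[target, source] <- FALSE else fP[target, source] <- FALSE
  path_pattern(fA, fP)
}

# shared add/prune majority loop used at group and subgroup level.
# base_free: paths that are free before the search and must never be pruned.
majority_search <- function(mats, base_pattern, gamma, config,
                            protected_paths) {
  K <- length(mats)
  pattern <- base_pattern
  fits <- fit_all(mats, pattern, config)
  added <- data.frame(lag = integer(), source = integer(), target = integer())
  repeat {
    ok <- !vapply(fits, is.null, logical(1)) &
      vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
    if (!all(ok))
      warning(sum(!ok), " subject(s) excluded from this iteration's count")
    use <- which(ok)
    if (!length(use)) break
    cand <- all_candidates(pattern, config$allow_reciprocal)
    if (!nrow(cand)) break
    key <- path_key(cand$lag, cand$source, cand$target)
    counts <- stats::setNames(numeric(nrow(cand)), key)
    misum <- stats::setNames(numeric(nrow(cand)), key)
    for (k in use) {
      mi <- modification_indices(fits[[k]], pattern, cand)
      mk <- path_key(mi$lag, mi$source, mi$target)
      sig <- mi$p_value < config$alpha
      counts[mk[sig]] <- counts[mk[sig]] + 1
      misum[mk] <- misum[mk] + mi$mi
    }
    # best candidate: largest count, then largest summed MI, then the
    # (lag, target, source) lexicographic order all_candidates() provides
    best <- order(-counts, -misum)[1]
    if (counts[best] / K < gamma) break
    pattern <- pattern_add(pattern, cand$lag[best], cand$source[best],
                           cand$target[best])
    added <- rbind(added, cand[best, c("lag", "source", "target")])
    fits <- fit_all(mats, pattern, config, starts = fits)
  }
  # majority pruning of the added paths: drop paths Wald-significant for
  # fewer than gamma of subjects (base/AR protected)
  repeat {
    if (!nrow(added)) break
    ok <- which(vapply(fits, function(f) !is.null(f) && f$converged,
                       logical(1)))
    sigcount <- numeric(nrow(added))
    zsum <- numeric(nrow(added))
    for (k in ok) {
      pt <- path_table(fits[[k]])
      pk <- path_key(pt$lag, pt$source, pt$target)
      ak <- path_key(added$lag, added$source, added$target)
      m <- match(ak, pk)
      sig <- !is.na(pt$p_value[m]) & pt$p_value[m] < config$alpha
      sigcount <- sigcount + sig
      zsum <- zsum + abs(pt$z[m])
    }
    fail <- which(sigcount / K < gamma)
    if (!length(fail)) break
    worst <- fail[order(sigcount[fail], zsum[fail])][1]
    pattern <- pattern_remove(pattern, added$lag[worst], added$source[worst],
                              added$target[worst])
    added <- added[-worst, , drop = FALSE]
    fits <- fit_all(mats, pattern, config, starts = fits)
  }
  # Direction revision. Paths picked early in the search can point the
  # wrong way because the model was still misspecified at that stage, and
  # a contemporaneous and a lagged path on the same node pair tend to flip
  # together. With the full pattern in place, enumerate the orientation
  # combinations of the added paths on each unordered node pair and keep
  # the one with the lowest total discrepancy over subjects.
  revisable <- which(added$source != added$target)
  if (length(revisable)) {
    pair_id <- paste(pmin(added$source[revisable], added$target[revisable]),
                     pmax(added$source[revisable], added$target[revisable]))
    for (pid in unique(pair_id)) {
      rows <- revisable[pair_id == pid]
      if (length(rows) > 3) next               # combinatorial guard
      total_F <- function(fl) sum(vapply(fl, function(f)
        if (!is.null(f) && f$converged) f$F_ML else NA_real_, numeric(1)))
      best <- list(F = total_F(fits), pattern = pattern, fits = fits,
                   flip = rep(FALSE, length(rows)))
      if (is.na(best$F)) next
      masks <- expand.grid(rep(list(c(FALSE, TRUE)), length(rows)))
      for (m in seq_len(nrow(masks))[-1]) {
        flip <- unlist(masks[m, ])
        cand <- pattern
        okv <- TRUE
        for (q in seq_along(rows)) {
          if (!flip[q]) next
          r <- rows[q]
          sr <- added$source[r]; tg <- added$target[r]
          free <- if (added$lag[r] == 0) cand$free_A else cand$free_Phi
          if (free[sr, tg]) { okv <- FALSE; break }   # reversal occupied
          cand <- pattern_add(pattern_remove(cand, added$lag[r], sr, tg),
                              added$lag[r], tg, sr)
        }
        if (!okv) next
        cand_fits <- fit_all(mats, cand, config, starts = fits)
        fc <- total_F(cand_fits)
        if (!is.na(fc) && fc < best$F - 1e-9)
          best <- list(F = fc, pattern = cand, fits = cand_fits, flip = flip)
      }
      if (any(best$flip)) {
        pattern <- best$pattern; fits <- best$fits
        for (q in which(best$flip)) {
          r <- rows[q]
          tmp <- added$source[r]
          added$source[r] <- added$target[r]; added$target[r] <- tmp
        }
      }
    }
  }
  list(pattern = pattern, added = added, fits = fits)
}

#' Group-level path search
#'
#' Starting from the AR-only pattern, iteratively adds the candidate path
#' whose modification index is significant for the largest number of
#' subjects, as long as that number reaches `gamma_group` of the cohort
#' (75 percent by default); ties are broken by larger summed MI, then by
#' (lag, target, source) order. Afterwards, added group paths that are
#' Wald-significant for fewer than `gamma_group` of subjects are pruned.
#'
#' @param cohort list of [roi_timeseries()] (or matrices), same ROI set.
#' @param config a [search_config()].
#' @return List: `pattern` (the group [path_pattern()]), `group_paths`
#'   (data.frame `lag, source, target`), `fits` (per-subject `fitted_usem`).
#' @export
group_search <- function(cohort, config = search_config()) {
  mats <- cohort_matrices(cohort)
  stopifnot(length(mats) >= 2)
  p <- ncol(mats[[1]])
  base <- ar_only_pattern(p, ar = config$ar_start)
  res <- majority_search(mats, base, config$gamma_group, config,
                         protected_paths = NULL)
  list(pattern = res$pattern, group_paths = res$added, fits = res$fits)
}

#' Sign-aware sparse count similarity matrix
#'
#' For each subject the feature set contains (i) every group path tagged with
#' the sign of that subject's estimate and (ii) every non-group candidate
#' whose modification index is significant at `alpha` for that subject,
#' tagged with the sign of its expected parameter change. The similarity of
#' two subjects is the number of shared (path, sign) features; the diagonal
#' is zero.
#'
#' @param cohort list of time series (only used if `fits` not given).
#' @param group result of [group_search()] (pattern + fits).
#' @param config a [search_config()].
#' @return Integer similarity matrix with subject ids as dimnames.
#' @export
build_similarity_matrix <- function(cohort, group,
                                    config = search_config()) {
  fits <- group$fits
  pattern <- group$pattern
  K <- length(fits)
  feats <- vector("list", K)
  gp <- group$group_paths
  for (k in seq_len(K)) {
    f <- fits[[k]]
    fs <- character(0)
    if (!is.null(f)) {
      if (nrow(gp)) {
        est <- mapply(function(lag, sr, tg)
          if (lag == 0) f$A_hat[tg, sr] else f$Phi_hat[tg, sr],
          gp$lag, gp$source, gp$target)
        fs <- c(fs, paste(path_key(gp$lag, gp$source, gp$target),
                          sign(est)))
      }
      mi <- modification_indices(f, pattern)
      sig <- mi[!is.na(mi$p_value) & mi$p_value < config$alpha, , drop = FALSE]
      if (nrow(sig))
        fs <- c(fs, paste(path_key(sig$lag, sig$source, sig$target),
                          sign(sig$epc)))
    }
    feats[[k]] <- unique(fs)
  }
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("sub%02d", seq_len(K))
  similarity_from_features(stats::setNames(feats, ids))
}

# count of shared (path, sign) features per subject pair; zero diagonal
similarity_from_features <- function(feats) {
  K <- length(feats)
  sim <- matrix(0L, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) if (a < b) {
    sim[a, b] <- sim[b, a] <- length(intersect(feats[[a]], feats[[b]]))
  }
  dimnames(sim) <- list(names(feats), names(feats))
  sim
}

#' Detect subgroups by Walktrap community detection
#'
#' Runs Walktrap on the weighted undirected graph whose edge weights are the
#' similarity counts. An all-zero similarity matrix yields one singleton
#' subgroup per subject, flagged via `degenerate = TRUE`.
#'
#' @param sim similarity matrix from [build_similarity_matrix()].
#' @param config a [search_config()] (supplies `walktrap_steps`).
#' @return List of class `subgroup_solution`: `assignment` (named integer
#'   vector, ids contiguous from 1), `modularity`, `n_subgroups`,
#'   `degenerate`.
#' @export
detect_subgroups <- function(sim, config = search_config()) {
  stopifnot(isSymmetric(unname(sim)), all(diag(sim) == 0), all(sim >= 0))
  K <- nrow(sim)
  ids <- rownames(sim)
  if (is.null(ids)) ids <- sprintf("sub%02d", seq_len(K))
  if (all(sim == 0)) {
    return(structure(list(
      assignment = stats::setNames(seq_len(K), ids),
      modularity = NA_real_, n_subgroups = K, degenerate = TRUE),
      class = "subgroup_solution"))
  }
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                           weighted = TRUE)
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = config$walktrap_steps)
  memb <- igraph::membership(wt)
  # relabel contiguous from 1 in order of first appearance
  memb <- as.integer(factor(memb, levels = unique(memb)))
  structure(list(assignment = stats::setNames(memb, ids),
                 modularity = igraph::modularity(
                   g, memb, weights = igraph::E(g)$weight),
                 n_subgroups = max(memb), degenerate = FALSE),
            class = "subgroup_solution")
}

#' Subgroup-level path search
#'
#' Within each subgroup of size >= 2, the same add/prune majority loop as the
#' group search, with threshold `gamma_sub` over the subgroup members and the
#' group pattern as protected base. Singleton subgroups get an empty set.
#'
#' @param cohort named list of time series.
#' @param group result of [group_search()].
#' @param solution a `subgroup_solution`.
#' @param config a [search_config()].
#' @return Named list (by subgroup id) of data.frames `lag, source, target`.
#' @export
subgroup_search <- function(cohort, group, solution,
                            config = search_config()) {
  mats <- cohort_matrices(cohort)
  out <- list()
  for (sg in seq_len(solution$n_subgroups)) {
    members <- which(solution$assignment == sg)
    if (length(members) < 2) {
      out[[as.character(sg)]] <- data.frame(lag = integer(),
                                            source = integer(),
                                            target = integer())
      next
    }
    res <- majority_search(mats[members], group$pattern, config$gamma_sub,
                           config, protected_paths = group$group_paths)
    out[[as.character(sg)]] <- res$added
  }
  out
}

#' Individual-level path search for one subject
#'
#' Starting from the subject's group+subgroup pattern, repeatedly adds the
#' largest-MI candidate with p < alpha and refits, stopping as soon as
#' excellent fit (2 of 4 indices) is reached, no candidate is significant, or
#' `max_paths` additions have been made. Finally, individual-level paths that
#' lost significance are pruned (group, subgroup and AR paths protected).
#'
#' @param ts one subject's time series.
#' @param base_pattern the group+subgroup [path_pattern()].
#' @param protected data.frame of group/subgroup paths (never pruned).
#' @param config a [search_config()].
#' @return List: `pattern`, `fit`, `indices`, `individual_paths`.
#' @export
individual_search <- function(ts, base_pattern, protected = NULL,
                              config = search_config()) {
  X <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  pattern <- base_pattern
  fit <- fit_usem(X, pattern, standardize = config$standardize)
  added <- data.frame(lag = integer(), source = integer(), target = integer())
  n_added <- 0L
  last_good <- fit
  repeat {
    idx <- compute_fit_indices(fit)
    if (excellent_fit(idx, config$thresholds)) break
    if (n_added >= config$max_paths) break
    mi <- modification_indices(fit, pattern)
    mi <- mi[!is.na(mi$p_value) & mi$p_value < config$alpha, , drop = FALSE]
    if (!nrow(mi)) break
    best <- which.max(mi$mi)
    pattern <- pattern_add(pattern, mi$lag[best], mi$source[best],
                           mi$target[best])
    added <- rbind(added, mi[best, c("lag", "source", "target")])
    n_added <- n_added + 1L
    fit <- fit_usem(X, pattern, standardize = config$standardize, start = fit)
    if (fit$converged) last_good <- fit
  }
  if (!fit$converged) fit <- last_good
  # prune individual-level paths only
  if (nrow(added)) {
    repeat {
      pt <- path_table(fit)
      pk <- path_key(pt$lag, pt$source, pt$target)
      ak <- path_key(added$lag, added$source, added$target)
      m <- match(ak, pk)
      bad <- which(is.na(pt$p_value[m]) | pt$p_value[m] >= config$alpha)
      if (!length(bad)) break
      worst <- bad[which.max(pt$p_value[m][bad])]
      pattern <- pattern_remove(pattern, added$lag[worst],
                                added$source[worst], added$target[worst])
      added <- added[-worst, , drop = FALSE]
      fit <- fit_usem(X, pattern, standardize = config$standardize,
                      start = fit)
    }
  }
  list(pattern = pattern, fit = fit, indices = compute_fit_indices(fit),
       individual_paths = added)
}

#' Run the full three-stage connectivity model search
#'
#' Group search, sign-aware similarity + Walktrap subgrouping, subgroup
#' search, then per-subject individual search; aggregates everything into a
#' `gimme_result`.
#'
#' @param cohort named list of [roi_timeseries()] (or matrices).
#' @param config a [search_config()].
#' @return An object of class `gimme_result`: `group_paths`,
#'   `group_pattern`, `similarity`, `subgroups`, `subgroup_paths`,
#'   per-subject `fits`, `patterns`, `indices`, `edges` (tagged edge lists),
#'   `mean_fit` (cohort-average indices).
#' @export
run_gimme <- function(cohort, config = search_config()) {
  ids <- names(cohort)
  if (is.null(ids)) {
    ids <- sprintf("sub%02d", seq_along(cohort))
    names(cohort) <- ids
  }
  grp <- group_search(cohort, config)
  sim <- build_similarity_matrix(cohort, grp, config)
  sol <- detect_subgroups(sim, config)
  sgp <- subgroup_search(cohort, grp, sol, config)
  fits <- list(); patterns <- list(); indices <- list(); edges <- list()
  for (k in seq_along(cohort)) {
    sg <- as.character(sol$assignment[[ids[k]]])
    sg_paths <- sgp[[sg]]
    if (is.null(sg_paths))
      sg_paths <- data.frame(lag = integer(), source = integer(),
                             target = integer())
    base <- grp$pattern
    for (r in seq_len(nrow(sg_paths)))
      base <- pattern_add(base, sg_paths$lag[r], sg_paths$source[r],
                          sg_paths$target[r])
    prot <- rbind(grp$group_paths, sg_paths)
    ind <- individual_search(cohort[[k]], base, prot, config)
    fits[[ids[k]]] <- ind$fit
    patterns[[ids[k]]] <- ind$pattern
    indices[[ids[k]]] <- ind$indices
    edges[[ids[k]]] <- tag_edges(ind$fit, grp$group_paths, sg_paths,
                                 ind$individual_paths)
  }
  mean_fit <- colMeans(do.call(rbind, lapply(indices, function(i)
    unlist(i[c("CFI", "NNFI", "RMSEA", "SRMR")]))))
  structure(list(group_paths = grp$group_paths,
                 group_pattern = grp$pattern,
                 similarity = sim, subgroups = sol, subgroup_paths = sgp,
                 fits = fits, patterns = patterns, indices = indices,
                 edges = edges, mean_fit = mean_fit, config = config),
            class = "gimme_result")
}

# per-subject edge list with level tags; AR paths tagged "group"
tag_edges <- function(fit, group_paths, subgroup_paths, individual_paths) {
  pt <- path_table(fit)
  if (!nrow(pt)) return(cbind(pt, level = character(0)))
  key <- path_key(pt$lag, pt$source, pt$target)
  level <- rep("individual", nrow(pt))
  level[pt$lag == 1 & pt$source == pt$target] <- "group"  # AR
  if (nrow(group_paths))
    level[key %in% path_key(group_paths$lag, group_paths$source,
                            group_paths$target)] <- "group"
  if (nrow(subgroup_paths))
    level[key %in% path_key(subgroup_paths$lag, subgroup_paths$source,
                            subgroup_paths$target)] <- "subgroup"
  if (nrow(individual_paths))
    level[key %in% path_key(individual_paths$lag, individual_paths$source,
                            individual_paths$target)] <- "individual"
  cbind(pt, level = level)
}

#' @export
print.gimme_result <- function(x, ...) {
  cat("gimme_result:", length(x$fits), "subjects |",
      nrow(x$group_paths), "group paths |",
      x$subgroups$n_subgroups, "subgroups\n")
  cat(sprintf("mean fit: CFI %.4f NNFI %.4f RMSEA %.4f SRMR %.4f\n",
              x$mean_fit["CFI"], x$mean_fit["NNFI"], x$mean_fit["RMSEA"],
              x$mean_fit["SRMR"]))
  invisible(x)
}

#' Density profiles from a gimme_result
#'
#' @param result a `gimme_result`.
#' @param atlas a [network_atlas()].
#' @param mode density denominator mode, see [compute_density_profile()].
#' @return List of `density_profile`, one per subject.
#' @export
result_density_profiles <- function(result, atlas,
                                    mode = c("possible", "total")) {
  mode <- match.arg(mode)
  lapply(names(result$edges), function(id) {
    e <- result$edges[[id]]
    compute_density_profile(
      data.frame(source = e$source, target = e$target, lag = e$lag,
                 estimate = e$estimate), atlas, mode, subject_id = id)
  })
}
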