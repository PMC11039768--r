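#' Simulation parameters for the synthetic cohort
#'
#' Defaults reproduce the study's dimensions: 49 subjects, 11 ROIs, 500 time
#' points, with group-level path counts matching the reported group map
#' (10 contemporaneous + 3 lagged + 11 AR) and two subgroups of sizes 39/10
#' carrying 6 and 18 extra paths. Path magnitudes are a stated convention
#' (the study reports counts, not coefficients): AR ~ U(0.2, 0.6), other
#' paths +/- U(0.2, 0.4) with a configurable sign mix.
#'
#' @param n_subjects cohort size.
#' @param T_len time points per subject.
#' @param burn_in initial samples discarded.
#' @param ar_range range of AR coefficients.
#' @param path_range magnitude range of non-AR paths.
#' @param neg_prob probability a non-AR path is negative.
#' @param subgroup_sizes integer vector of subgroup sizes (sums to
#'   `n_subjects`); `NULL` for no subgroup structure.
#' @param subgroup_extra number of subgroup-specific paths per subgroup.
#' @param individual_rate expected number of individual-specific paths per
#'   subject.
#' @param noise_sd innovation standard deviation (recycled over ROIs).
#' @param seed master seed.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 49L, T_len = 500L, burn_in = 200L,
                              ar_range = c(0.2, 0.6),
                              path_range = c(0.2, 0.4),
                              neg_prob = 0.3,
                              subgroup_sizes = c(39L, 10L),
                              subgroup_extra = c(6L, 18L),
                              individual_rate = 2,
                              noise_sd = 1,
                              seed = 1L) {
  if (!is.null(subgroup_sizes) && sum(subgroup_sizes) != n_subjects)
    stop("subgroup_sizes must sum to n_subjects")
  structure(list(n_subjects = as.integer(n_subjects),
                 T_len = as.integer(T_len), burn_in = as.integer(burn_in),
                 ar_range = ar_range, path_range = path_range,
                 neg_prob = neg_prob, subgroup_sizes = subgroup_sizes,
                 subgroup_extra = subgroup_extra,
                 individual_rate = individual_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_params")
}

# deterministic stream of per-entity seeds below 2^31
derive_seeds <- function(master, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

rand_sign <- function(n, neg_prob) ifelse(stats::runif(n) < neg_prob, -1, 1)

# Draw n distinct directed (lag, source, target) paths from `pool`,
# excluding keys in `taken`. Contemporaneous pairs are kept unordered-unique
# (never both i->j and j->i across the truth): reciprocal contemporaneous
# pairs are weakly identified and make recovery ill-posed by construction.
draw_paths <- function(pool, n, taken) {
  out <- pool[0, , drop = FALSE]
  for (k in seq_len(n)) {
    keep <- !(path_key(pool$lag, pool$source, pool$target) %in% taken)
    pool <- pool[keep, , drop = FALSE]
    if (!nrow(pool)) stop("not enough admissible paths to draw from")
    pick <- pool[sample.int(nrow(pool), 1), , drop = FALSE]
    out <- rbind(out, pick)
    taken <- c(taken, path_key(pick$lag, pick$source, pick$target),
               if (pick$lag == 0)
                 path_key(0, pick$target, pick$source))
  }
  out
}

# keys of paths plus, for contemporaneous ones, their reversals
taken_keys <- function(df) {
  k <- path_key(df$lag, df$source, df$target)
  c0 <- df$lag == 0
  c(k, path_key(0, df$target[c0], df$source[c0]))
}

roi_pairs_within <- function(atlas, network, lag) {
  rois <- which(atlas$network_of == network)
  g <- expand.grid(source = rois, target = rois)
  g <- g[g$source != g$target, ]
  data.frame(lag = lag, source = g$source, target = g$target)
}

roi_pairs_between <- function(atlas, net1, net2, lag) {
  r1 <- which(atlas$network_of == net1)
  r2 <- which(atlas$network_of == net2)
  g <- rbind(expand.grid(source = r1, target = r2),
             expand.grid(source = r2, target = r1))
  data.frame(lag = lag, source = g$source, target = g$target)
}

#' Ground-truth path structure for a synthetic cohort
#'
#' The default group-level truth mirrors the reported group map:
#' contemporaneous paths within the SN (2), FPN (4), DMN (1) and between
#' SN-FPN (1) and SN-DMN (2); lagged paths within the FPN (2) and DMN (1);
#' AR paths for all ROIs. Optional subgroups add subgroup-specific paths and
#' each subject receives Poisson(`individual_rate`) individual paths.
#' Coefficient draws are rejection-resampled until every subject's composite
#' system is stationary (spectral radius of (I-A)^-1 Phi < 1).
#'
#' @param atlas a [network_atlas()] (11-ROI study atlas by default).
#' @param params a [simulation_params()].
#' @return List of class `true_structure`: `group_paths`, `subgroup_paths`,
#'   `individual_paths` (data.frames `lag, source, target, coefficient`),
#'   `ar_coefficients`, `noise_sd`, `subgroup_assignment`, `atlas`.
#' @export
make_true_structure <- function(atlas = default_atlas(),
                                params = simulation_params()) {
  set.seed(params$seed)
  p <- length(atlas$roi_names)
  draw_group <- function() {
    g <- rbind(
      draw_paths(roi_pairs_within(atlas, "SN", 0), 2, character(0)),
      draw_paths(roi_pairs_within(atlas, "FPN", 0), 4, character(0)),
      draw_paths(roi_pairs_within(atlas, "DMN", 0), 1, character(0)),
      draw_paths(roi_pairs_between(atlas, "SN", "FPN", 0), 1, character(0)),
      draw_paths(roi_pairs_between(atlas, "SN", "DMN", 0), 2, character(0)),
      draw_paths(roi_pairs_within(atlas, "FPN", 1), 2, character(0)),
      draw_paths(roi_pairs_within(atlas, "DMN", 1), 1, character(0)))
    g$coefficient <- stats::runif(nrow(g), params$path_range[1],
                                  params$path_range[2]) *
      rand_sign(nrow(g), params$neg_prob)
    g
  }
  all_nonar <- rbind(
    do.call(rbind, lapply(0:1, function(lag) {
      g <- expand.grid(source = seq_len(p), target = seq_len(p))
      g <- g[g$source != g$target, ]
      data.frame(lag = lag, source = g$source, target = g$target)
    })))
  subj_ids <- sprintf("sub%02d", seq_len(params$n_subjects))

  for (try in 1:200) {
    group <- draw_group()
    taken <- taken_keys(group)
    ar <- stats::runif(p, params$ar_range[1], params$ar_range[2])
    # subgroup structure
    sub_paths <- list(); assignment <- rep(1L, params$n_subjects)
    if (!is.null(params$subgroup_sizes)) {
      assignment <- rep(seq_along(params$subgroup_sizes),
                        params$subgroup_sizes)
      for (sg in seq_along(params$subgroup_sizes)) {
        nsg <- params$subgroup_extra[sg]
        ps <- draw_paths(all_nonar, nsg, taken)
        ps$coefficient <- stats::runif(nsg, params$path_range[1],
                                       params$path_range[2]) *
          rand_sign(nsg, params$neg_prob)
        sub_paths[[as.character(sg)]] <- ps
        taken <- c(taken, taken_keys(ps))
      }
    }
    names(assignment) <- subj_ids
    # individual paths
    ind_paths <- list()
    for (s in seq_len(params$n_subjects)) {
      nind <- stats::rpois(1, params$individual_rate)
      taken_s <- c(taken_keys(group),
                   if (length(sub_paths)) {
                     sg <- sub_paths[[as.character(assignment[s])]]
                     taken_keys(sg)
                   })
      ps <- draw_paths(all_nonar, nind, taken_s)
      if (nind > 0) {
        ps$coefficient <- stats::runif(nind, params$path_range[1],
                                       params$path_range[2]) *
          rand_sign(nind, params$neg_prob)
      } else ps$coefficient <- numeric(0)
      ind_paths[[subj_ids[s]]] <- ps
    }
    str <- structure(list(group_paths = group, subgroup_paths = sub_paths,
                          individual_paths = ind_paths,
                          ar_coefficients = ar,
                          noise_sd = rep(params$noise_sd, length.out = p),
                          subgroup_assignment = assignment, atlas = atlas),
                     class = "true_structure")
    ok <- all(vapply(subj_ids, function(s)
      is_stationary(subject_truth(str, s)), logical(1)))
    if (ok) return(str)
  }
  stop("could not draw a stationary structure after 200 attempts")
}

#' Composite (A, Phi) truth matrices for one subject
#'
#' @param structure a `true_structure`.
#' @param subject_id subject identifier.
#' @return List with matrices `A`, `Phi` and `edges` (the subject's non-AR
#'   true paths with level tags).
#' @export
subject_truth <- function(structure, subject_id) {
  p <- length(structure$atlas$roi_names)
  A <- matrix(0, p, p); Phi <- matrix(0, p, p)
  diag(Phi) <- structure$ar_coefficients
  add <- function(paths) {
    for (k in seq_len(nrow(paths))) {
      if (paths$lag[k] == 0) A[paths$target[k], paths$source[k]] <<-
          paths$coefficient[k]
      else Phi[paths$target[k], paths$source[k]] <<- paths$coefficient[k]
    }
  }
  lv <- function(df, level) if (nrow(df))
    cbind(df, level = level) else cbind(df, level = character(0))
  edges <- lv(structure$group_paths, "group")
  add(structure$group_paths)
  if (length(structure$subgroup_paths)) {
    sg <- as.character(structure$subgroup_assignment[[subject_id]])
    if (sg %in% names(structure$subgroup_paths)) {
      add(structure$subgroup_paths[[sg]])
      edges <- rbind(edges, lv(structure$subgroup_paths[[sg]], "subgroup"))
    }
  }
  ip <- structure$individual_paths[[subject_id]]
  if (!is.null(ip) && nrow(ip)) {
    add(ip)
    edges <- rbind(edges, lv(ip, "individual"))
  }
  list(A = A, Phi = Phi, edges = edges)
}

#' Stationarity of a composite uSEM system
#'
#' @param truth list with matrices `A` and `Phi`.
#' @return `TRUE` iff (I-A) is invertible and the reduced-form transition
#'   matrix (I-A)^-1 Phi has spectral radius < 1.
#' @export
is_stationary <- function(truth) {
  p <- nrow(truth$A)
  ImA <- diag(p) - truth$A
  if (abs(det(ImA)) < 1e-10) return(FALSE)
  M <- solve(ImA, truth$Phi)
  max(Mod(eigen(M, only.values = TRUE)$values)) < 1
}

#' Simulate one subject's ROI time series from the truth
#'
#' Generates via the reduced form eta_t = (I-A)^-1 (Phi eta_{t-1} + zeta_t)
#' with diagonal Gaussian innovations, discarding `burn_in` initial samples.
#'
#' @param structure a `true_structure`.
#' @param subject_id subject identifier.
#' @param T_len number of retained time points.
#' @param seed RNG seed for this subject.
#' @param burn_in discarded initial samples (default 200).
#' @param tr_seconds repetition time recorded on the output.
#' @return An [roi_timeseries()].
#' @export
simulate_subject_timeseries <- function(structure, subject_id, T_len = 500L,
                                        seed = 1L, burn_in = 200L,
                                        tr_seconds = 0.72) {
  truth <- subject_truth(structure, subject_id)
  if (!is_stationary(truth))
    stop("subject ", subject_id, " has a non-stationary composite system")
  p <- nrow(truth$A)
  B <- solve(diag(p) - truth$A)
  BPhi <- B %*% truth$Phi
  set.seed(seed)
  ntot <- T_len + burn_in
  E <- matrix(stats::rnorm(ntot * p), ntot, p) %*%
    diag(structure$noise_sd, p) %*% t(B)
  eta <- matrix(0, ntot, p)
  eta[1, ] <- E[1, ]
  for (t in 2:ntot) eta[t, ] <- BPhi %*% eta[t - 1, ] + E[t, ]
  X <- eta[(burn_in + 1):ntot, , drop = FALSE]
  colnames(X) <- structure$atlas$roi_names
  roi_timeseries(subject_id, X, structure$atlas, tr_seconds)
}

#' Simulate a full cohort of ROI time series
#'
#' @param structure a `true_structure`.
#' @param params a [simulation_params()] (supplies T, burn-in and the master
#'   seed from which per-subject seeds are derived).
#' @return Named list of [roi_timeseries()], one per subject.
#' @export
simulate_cohort <- function(structure, params = simulation_params()) {
  ids <- names(structure$subgroup_assignment)
  seeds <- derive_seeds(params$seed + 1L, length(ids))
  out <- lapply(seq_along(ids), function(k)
    simulate_subject_timeseries(structure, ids[k], params$T_len,
                                seed = seeds[k], burn_in = params$burn_in))
  stats::setNames(out, ids)
}

#' Closed-form stationary covariance of a subject's composite system
#'
#' Solves the discrete Lyapunov equation of the reduced form
#' eta_t = M eta_{t-1} + u_t with M = (I-A)^-1 Phi and
#' Var(u) = (I-A)^-1 Psi (I-A)^-T.
#'
#' @param truth list with `A`, `Phi`.
#' @param noise_sd per-ROI innovation standard deviations.
#' @return The p x p stationary covariance.
#' @export
stationary_covariance <- function(truth, noise_sd) {
  p <- nrow(truth$A)
  B <- solve(diag(p) - truth$A)
  M <- B %*% truth$Phi
  Q <- B %*% diag(noise_sd^2, p) %*% t(B)
  # vec(V) = (I - M (x) M)^-1 vec(Q)
  V <- solve(diag(p * p) - kronecker(M, M), as.numeric(Q))
  matrix(V, p, p)
}
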