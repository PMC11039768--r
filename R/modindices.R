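#' All admissible candidate paths for a pattern
#'
#' Every directed path not currently free: contemporaneous (lag 0) off-
#' diagonal entries of A and lag-1 entries of Phi. Contemporaneous self-loops
#' are never admissible.
#'
#' @param pattern a [path_pattern()].
#' @param allow_reciprocal if `FALSE`, a contemporaneous candidate i -> j is
#'   dropped when j -> i is already free.
#' @return data.frame with columns `lag` (0/1), `source`, `target`
#'   (column indices).
#' @export
all_candidates <- function(pattern, allow_reciprocal = TRUE) {
  p <- pattern$p
  out <- list()
  for (lag in 0:1) {
    free <- if (lag == 0) pattern$free_A else pattern$free_Phi
    for (tg in seq_len(p)) for (sr in seq_len(p)) {
      if (lag == 0 && sr == tg) next
      if (free[tg, sr]) next
      if (lag == 0 && !allow_reciprocal && pattern$free_A[sr, tg]) next
      out[[length(out) + 1L]] <- c(lag, sr, tg)
    }
  }
  m <- do.call(rbind, out)
  df <- data.frame(lag = m[, 1], source = m[, 2], target = m[, 3])
  # deterministic lexicographic order: (lag, target, source)
  df[order(df$lag, df$target, df$source), , drop = FALSE]
}

path_key <- function(lag, source, target) paste(lag, source, target, sep = ":")

#' Modification indices for candidate paths
#'
#' One-degree-of-freedom score (Lagrange multiplier) statistics estimating
#' the chi-square improvement from freeing each currently fixed path, using
#' the expected information adjusted for the estimated free parameters. Also
#' returns the expected parameter change (EPC), whose sign is used by the
#' sign-aware subject similarity.
#'
#' @param fit a converged `fitted_usem`.
#' @param pattern the pattern the fit used.
#' @param candidates data.frame as from [all_candidates()]; defaults to all
#'   admissible candidates. Candidates that are already free are excluded.
#' @return data.frame `lag, source, target, mi, p_value, epc`, in the
#'   candidates' order; candidates whose adjusted information is singular are
#'   dropped with a warning.
#' @export
modification_indices <- function(fit, pattern = fit$pattern,
                                 candidates = NULL) {
  if (is.null(candidates)) candidates <- all_candidates(pattern)
  # drop already-free or inadmissible rows
  keep <- vapply(seq_len(nrow(candidates)), function(k) {
    lag <- candidates$lag[k]; sr <- candidates$source[k]
    tg <- candidates$target[k]
    if (lag == 0 && sr == tg) return(FALSE)
    free <- if (lag == 0) pattern$free_A else pattern$free_Phi
    !free[tg, sr]
  }, logical(1))
  candidates <- candidates[keep, , drop = FALSE]
  if (!nrow(candidates))
    return(data.frame(lag = integer(), source = integer(), target = integer(),
                      mi = numeric(), p_value = numeric(), epc = numeric()))
  st <- fit$state
  n1 <- fit$n_eff - 1
  D <- fit$D
  Dinv <- tryCatch(solve(D), error = function(e) NULL)
  if (is.null(Dinv)) stop("information matrix of the fitted model is singular")
  # columns: vec(t(K_j)) for each free parameter, so tr(K_a K_j) = vec(K_a).M
  q <- nrow(fit$ptab)
  twop2 <- (2 * fit$p)^2
  M <- matrix(0, twop2, q)
  for (k in seq_len(q)) {
    Kk <- st$Siginv %*% usem_dsigma(st, fit$ptab$type[k],
                                    fit$ptab$i[k], fit$ptab$j[k])
    M[, k] <- as.numeric(t(Kk))
  }
  vW <- as.numeric(st$W)
  mi <- pv <- epc <- rep(NA_real_, nrow(candidates))
  dropped <- FALSE
  for (k in seq_len(nrow(candidates))) {
    type <- if (candidates$lag[k] == 0) "A" else "Phi"
    dS <- usem_dsigma(st, type, candidates$target[k], candidates$source[k])
    Ka <- st$Siginv %*% dS
    vKa <- as.numeric(Ka)
    g <- sum(vW * as.numeric(dS))
    d_at <- as.numeric(vKa %*% M)
    Daa <- sum(vKa * as.numeric(t(Ka)))
    dtil <- Daa - as.numeric(d_at %*% Dinv %*% d_at)
    if (!is.finite(dtil) || dtil < 1e-10) { dropped <- TRUE; next }
    mi[k] <- n1 / 2 * g^2 / dtil
    pv[k] <- stats::pchisq(mi[k], df = 1, lower.tail = FALSE)
    epc[k] <- -g / dtil
  }
  if (dropped)
    warning("some candidates skipped: singular adjusted information")
  ok <- is.finite(mi)
  data.frame(lag = candidates$lag, source = candidates$source,
             target = candidates$target, mi = mi, p_value = pv,
             epc = epc)[ok, , drop = FALSE]
}

#' Prune non-significant free paths
#'
#' Removes free, unprotected paths whose two-sided Wald p-value is >= alpha.
#' AR (lag-1 self) paths are protected by default; group/subgroup paths can
#' be protected by the caller.
#'
#' @param fit a `fitted_usem`.
#' @param pattern the pattern the fit used.
#' @param alpha significance level (default 0.05).
#' @param protected data.frame `lag, source, target` of paths that must never
#'   be pruned, in addition to AR paths.
#' @return A new [path_pattern()].
#' @export
prune_paths <- function(fit, pattern = fit$pattern, alpha = 0.05,
                        protected = NULL) {
  p <- pattern$p
  prot <- character(0)
  prot <- c(prot, path_key(1, seq_len(p), seq_len(p)))  # AR always protected
  if (!is.null(protected) && nrow(protected))
    prot <- c(prot, path_key(protected$lag, protected$source,
                             protected$target))
  fA <- pattern$free_A; fP <- pattern$free_Phi
  for (lag in 0:1) {
    free <- if (lag == 0) fA else fP
    z <- if (lag == 0) fit$z_A else fit$z_Phi
    idx <- which(free, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      tg <- idx[r, 1]; sr <- idx[r, 2]
      if (path_key(lag, sr, tg) %in% prot) next
      pval <- 2 * stats::pnorm(-abs(z[tg, sr]))
      if (is.na(pval) || pval >= alpha) {
        if (lag == 0) fA[tg, sr] <- FALSE else fP[tg, sr] <- FALSE
      }
    }
  }
  path_pattern(fA, fP)
}

#' Wald p-values of the free paths of a fit
#'
#' @param fit a `fitted_usem`.
#' @return data.frame `lag, source, target, estimate, se, z, p_value`.
#' @export
path_table <- function(fit) {
  pat <- fit$pattern
  rows <- list()
  for (lag in 0:1) {
    free <- if (lag == 0) pat$free_A else pat$free_Phi
    est <- if (lag == 0) fit$A_hat else fit$Phi_hat
    se <- if (lag == 0) fit$se_A else fit$se_Phi
    idx <- which(free, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      tg <- idx[r, 1]; sr <- idx[r, 2]
      z <- est[tg, sr] / se[tg, sr]
      rows[[length(rows) + 1L]] <- data.frame(
        lag = lag, source = sr, target = tg, estimate = est[tg, sr],
        se = se[tg, sr], z = z, p_value = 2 * stats::pnorm(-abs(z)))
    }
  }
  if (!length(rows))
    return(data.frame(lag = integer(), source = integer(), target = integer(),
                      estimate = numeric(), se = numeric(), z = numeric(),
                      p_value = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$lag, out$target, out$source), , drop = FALSE]
}
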