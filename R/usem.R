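#' Path pattern: which uSEM paths are free
#'
#' A unified SEM (uSEM) for p ROI signals eta_t is
#'   eta_t = A eta_t + Phi eta_{t-1} + zeta_t,  zeta_t ~ N(0, diag(psi)),
#' where A holds contemporaneous directed paths (diagonal forbidden) and Phi
#' holds lag-1 paths (diagonal = autoregressive, AR, paths). `free_A[i, j]`
#' (and likewise `free_Phi`) means the path from ROI j (source) to ROI i
#' (target) is estimated; entries that are not free are fixed at zero.
#'
#' @param free_A logical p x p matrix; diagonal must be all `FALSE`.
#' @param free_Phi logical p x p matrix.
#' @return An object of class `path_pattern`.
#' @export
path_pattern <- function(free_A, free_Phi) {
  free_A <- as.matrix(free_A); free_Phi <- as.matrix(free_Phi)
  p <- nrow(free_A)
  stopifnot(is.logical(free_A), is.logical(free_Phi),
            ncol(free_A) == p, all(dim(free_Phi) == c(p, p)))
  if (any(diag(free_A)))
    stop("contemporaneous self-loops are not admissible")
  structure(list(free_A = free_A, free_Phi = free_Phi, p = p),
            class = "path_pattern")
}

#' AR-only starting pattern
#'
#' All lag-1 self paths free, nothing else: the canonical null network the
#' group-level search starts from.
#'
#' @param p number of ROIs.
#' @param ar if `FALSE`, the literal empty pattern (no AR either).
#' @return A [path_pattern()].
#' @export
ar_only_pattern <- function(p, ar = TRUE) {
  fA <- matrix(FALSE, p, p)
  fP <- matrix(FALSE, p, p)
  if (ar) diag(fP) <- TRUE
  path_pattern(fA, fP)
}

#' @export
print.path_pattern <- function(x, ...) {
  cat("path_pattern: p =", x$p, "|", sum(x$free_A), "contemporaneous,",
      sum(x$free_Phi), "lagged free paths\n")
  invisible(x)
}

n_free <- function(pattern) sum(pattern$free_A) + sum(pattern$free_Phi)

#' Stacked lag-1 covariance of a time series
#'
#' Sample covariance of the 2p-vector (eta_{t-1}, eta_t) over the T-1 usable
#' pairs; the quantity the uSEM discrepancy is evaluated against.
#'
#' @param X numeric T x p matrix.
#' @param standardize z-score each column first (default `TRUE`).
#' @return List with `S` (2p x 2p), `n_eff` (= T-1) and `p`.
#' @export
stacked_cov <- function(X, standardize = TRUE) {
  X <- as.matrix(X)
  if (standardize) X <- scale(X)
  T_ <- nrow(X); p <- ncol(X)
  Z <- cbind(X[-T_, , drop = FALSE], X[-1L, , drop = FALSE])
  list(S = stats::cov(Z), n_eff = T_ - 1L, p = p)
}

# Model-implied 2p x 2p covariance. V (covariance of the lagged block) is
# saturated, hence profiled out at its ML value, the sample lagged block.
usem_sigma <- function(A, Phi, psi, V) {
  p <- nrow(A)
  B <- solve(diag(p) - A)
  PhiV <- Phi %*% V
  Sig21 <- B %*% PhiV
  Sig22 <- B %*% (PhiV %*% t(Phi) + diag(psi, p)) %*% t(B)
  Sig22 <- (Sig22 + t(Sig22)) / 2
  Sig <- rbind(cbind(V, t(Sig21)), cbind(Sig21, Sig22))
  list(Sig = Sig, B = B, Sig21 = Sig21, Sig22 = Sig22)
}

# F_ML and analytic gradient at packed parameters.
# theta = c(A[free], Phi[free], log(psi)); V fixed at sample lagged block.
usem_objective <- function(theta, env) {
  p <- env$p
  A <- matrix(0, p, p); Phi <- matrix(0, p, p)
  A[env$idxA] <- theta[env$posA]
  Phi[env$idxPhi] <- theta[env$posPhi]
  psi <- exp(theta[env$posPsi])
  ImA <- diag(p) - A
  if (abs(det(ImA)) < 1e-12)
    return(list(F = 1e10, grad = NULL, ok = FALSE))
  m <- usem_sigma(A, Phi, psi, env$V)
  R <- tryCatch(chol(m$Sig), error = function(e) NULL)
  if (is.null(R)) return(list(F = 1e10, grad = NULL, ok = FALSE))
  Siginv <- chol2inv(R)
  ldSig <- 2 * sum(log(diag(R)))
  Fv <- ldSig + sum(Siginv * env$S) - env$ldS - 2 * p
  if (!is.finite(Fv)) return(list(F = 1e10, grad = NULL, ok = FALSE))
  W <- Siginv %*% (m$Sig - env$S) %*% Siginv
  lo <- (p + 1):(2 * p)
  W21 <- W[lo, 1:p, drop = FALSE]
  W22 <- W[lo, lo, drop = FALSE]
  B <- m$B
  tBW21 <- t(B) %*% W21
  tBW22B <- t(B) %*% W22 %*% B
  gA <- 2 * (tBW21 %*% t(m$Sig21) + t(B) %*% W22 %*% m$Sig22)
  gPhi <- 2 * (tBW21 %*% env$V + tBW22B %*% Phi %*% env$V)
  gpsi <- diag(tBW22B) * psi   # chain rule through log(psi)
  list(F = Fv, grad = c(gA[env$idxA], gPhi[env$idxPhi], gpsi),
       ok = TRUE, A = A, Phi = Phi, psi = psi, B = B, Sig = m$Sig,
       Siginv = Siginv, W = W, Sig21 = m$Sig21, Sig22 = m$Sig22)
}

# dSigma/dparam as a full 2p x 2p matrix (raw psi metric).
# type "A": candidate/free contemporaneous path j -> i; "Phi": lagged; "psi".
usem_dsigma <- function(st, type, i, j) {
  p <- nrow(st$B)
  dS <- matrix(0, 2 * p, 2 * p)
  lo <- (p + 1):(2 * p)
  if (type == "A") {
    d21 <- outer(st$B[, i], st$Sig21[j, ])
    Z <- outer(st$B[, i], st$Sig22[j, ])
    d22 <- Z + t(Z)
  } else if (type == "Phi") {
    d21 <- outer(st$B[, i], st$V[j, ])
    Z <- outer(st$B[, i], st$Sig21[, j])
    d22 <- Z + t(Z)
  } else {
    d21 <- matrix(0, p, p)
    d22 <- outer(st$B[, i], st$B[, i])
  }
  dS[lo, 1:p] <- d21
  dS[1:p, lo] <- t(d21)
  dS[lo, lo] <- d22
  dS
}

# expected-information matrix D_ij = tr(Siginv dSig_i Siginv dSig_j)
# over the supplied parameter list; returns D and the K_i = Siginv dSig_i.
usem_information <- function(st, params) {
  q <- nrow(params)
  K <- vector("list", q)
  for (k in seq_len(q))
    K[[k]] <- st$Siginv %*% usem_dsigma(st, params$type[k],
                                        params$i[k], params$j[k])
  D <- matrix(0, q, q)
  for (a in seq_len(q)) {
    tKa <- t(K[[a]])
    for (b in a:q) {
      D[a, b] <- D[b, a] <- sum(tKa * K[[b]])
    }
  }
  list(D = D, K = K)
}

# parameter table (type, i = target/row, j = source/col) for a pattern
param_table <- function(pattern) {
  p <- pattern$p
  iA <- which(pattern$free_A, arr.ind = TRUE)
  iP <- which(pattern$free_Phi, arr.ind = TRUE)
  rbind(
    if (nrow(iA)) data.frame(type = "A", i = iA[, 1], j = iA[, 2]),
    if (nrow(iP)) data.frame(type = "Phi", i = iP[, 1], j = iP[, 2]),
    data.frame(type = "psi", i = seq_len(p), j = seq_len(p)))
}

#' Fit a unified SEM to one subject's time series
#'
#' Minimizes the maximum-likelihood discrepancy
#' \deqn{F = \log|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \log|S| - 2p}
#' over the free contemporaneous (A) and lag-1 (Phi) paths and the diagonal
#' innovation variances, with the lagged-block covariance saturated, against
#' the stacked covariance S of (eta_{t-1}, eta_t). Quasi-Newton optimization
#' from zero starts (AR paths at 0.3) followed by Fisher-scoring polish;
#' Wald standard errors come from the inverse expected information.
#'
#' @param ts an [roi_timeseries()] or numeric T x p matrix.
#' @param pattern a [path_pattern()].
#' @param standardize z-score each ROI before fitting (default `TRUE`).
#' @param start optional `fitted_usem` from a previous fit of a (sub)pattern,
#'   used as warm start.
#' @param grad_tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum quasi-Newton iterations.
#' @return An object of class `fitted_usem` with estimates `A_hat`,
#'   `Phi_hat`, `psi_hat`, standard errors `se_A`, `se_Phi`, Wald `z_A`,
#'   `z_Phi`, the optimal discrepancy `F_ML`, `n_eff`, and a `converged` flag.
#' @export
fit_usem <- function(ts, pattern, standardize = TRUE, start = NULL,
                     grad_tol = 1e-6, max_iter = 500L) {
  X <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  sc <- stacked_cov(X, standardize = standardize)
  p <- sc$p
  stopifnot(pattern$p == p)
  q_all <- p * (p + 1) / 2 + n_free(pattern) + p
  if (sc$n_eff - 1L <= q_all)
    stop("too few time points (", nrow(X), ") for ", q_all,
         " free parameters")
  ldS <- determinant(sc$S, logarithm = TRUE)
  if (ldS$sign <= 0 || !is.finite(ldS$modulus))
    stop("stacked sample covariance is singular; a longer series is needed")
  env <- list2env(list(
    p = p, S = sc$S, ldS = as.numeric(ldS$modulus),
    V = sc$S[1:p, 1:p, drop = FALSE],
    idxA = which(pattern$free_A), idxPhi = which(pattern$free_Phi)))
  nA <- length(env$idxA); nP <- length(env$idxPhi)
  env$posA <- seq_len(nA)
  env$posPhi <- nA + seq_len(nP)
  env$posPsi <- nA + nP + seq_len(p)

  theta0 <- c(rep(0, nA),
              ifelse(env$idxPhi %in% which(diag(TRUE, p)), 0.3, 0),
              log(pmax(diag(env$S[(p + 1):(2 * p), (p + 1):(2 * p),
                                  drop = FALSE]), 1e-4)))
  if (!is.null(start) && inherits(start, "fitted_usem")) {
    theta0[env$posA] <- start$A_hat[env$idxA]
    theta0[env$posPhi] <- start$Phi_hat[env$idxPhi]
    theta0[env$posPsi] <- log(pmax(start$psi_hat, 1e-6))
  }

  fn <- function(th) usem_objective(th, env)$F
  gr <- function(th) {
    o <- usem_objective(th, env)
    if (is.null(o$grad)) rep(0, length(th)) else o$grad
  }
  opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  theta <- opt$par
  st <- usem_objective(theta, env)

  # Fisher-scoring polish to drive the gradient to machine-level zero
  ptab <- param_table(pattern)
  for (it in 1:60) {
    if (!st$ok || max(abs(st$grad)) < 1e-9) break
    stf <- c(st, list(V = env$V))
    info <- tryCatch(usem_information(stf, ptab), error = function(e) NULL)
    if (is.null(info)) break
    J <- c(rep(1, nA + nP), st$psi)      # raw -> log-psi Jacobian
    Dopt <- t(J * info$D) * J
    step <- tryCatch(solve(Dopt + diag(1e-10, nrow(Dopt)), st$grad),
                     error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    for (h in 0:20) {
      cand <- theta - step / 2^h
      stc <- usem_objective(cand, env)
      if (stc$ok && stc$F <= st$F + 1e-12) {
        theta <- cand; st <- stc; improved <- TRUE; break
      }
    }
    if (!improved) break
  }

  converged <- st$ok && max(abs(st$grad)) < grad_tol
  stf <- c(st, list(V = env$V))
  info <- tryCatch(usem_information(stf, ptab), error = function(e) NULL)
  seA <- matrix(NA_real_, p, p); sePhi <- matrix(NA_real_, p, p)
  D <- NULL
  if (!is.null(info)) {
    D <- info$D
    covth <- tryCatch((2 / (sc$n_eff - 1)) * solve(D), error = function(e) NULL)
    if (!is.null(covth)) {
      se <- sqrt(pmax(diag(covth), 0))
      seA[env$idxA] <- se[env$posA]
      sePhi[env$idxPhi] <- se[env$posPhi]
    }
  }
  A <- st$A; Phi <- st$Phi
  zA <- A / seA; zPhi <- Phi / sePhi
  roi <- colnames(X)
  dimnames(A) <- dimnames(Phi) <- dimnames(seA) <- dimnames(sePhi) <-
    dimnames(zA) <- dimnames(zPhi) <- list(roi, roi)
  structure(list(
    A_hat = A, Phi_hat = Phi, psi_hat = st$psi,
    se_A = seA, se_Phi = sePhi, z_A = zA, z_Phi = zPhi,
    F_ML = st$F, n_eff = sc$n_eff, p = p, converged = converged,
    pattern = pattern, S = sc$S, V = env$V,
    state = stf, ptab = ptab, D = D,
    subject_id = if (inherits(ts, "roi_timeseries")) ts$subject_id else NA),
    class = "fitted_usem")
}

#' @export
print.fitted_usem <- function(x, ...) {
  cat("fitted_usem: p =", x$p, "| F_ML =", format(x$F_ML, digits = 6),
      "| n_eff =", x$n_eff,
      if (x$converged) "| converged" else "| NOT converged", "\n")
  invisible(x)
}
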