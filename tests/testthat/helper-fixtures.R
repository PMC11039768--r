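# Shared fixtures and independent oracles for the test suite.

# direct reduced-form VAR simulator, written independently of the package's
# generator (used as data source for engine tests)
sim_var <- function(A, Phi, T_len, seed, burn = 200, noise_sd = 1) {
  p <- nrow(A)
  set.seed(seed)
  B <- solve(diag(p) - A)
  ntot <- T_len + burn
  eta <- matrix(0, ntot, p)
  for (t in 2:ntot)
    eta[t, ] <- B %*% (Phi %*% eta[t - 1, ] +
                         rnorm(p, 0, noise_sd))
  eta[(burn + 1):ntot, , drop = FALSE]
}

# a 3-ROI system with one contemporaneous and one lagged cross path
fixture3 <- function(T_len = 600, seed = 101) {
  A <- matrix(0, 3, 3); Phi <- matrix(0, 3, 3)
  A[2, 1] <- 0.4
  diag(Phi) <- c(0.3, 0.45, 0.25)
  Phi[3, 2] <- 0.3
  list(A = A, Phi = Phi, X = sim_var(A, Phi, T_len, seed),
       pattern = path_pattern(A != 0, Phi != 0 | diag(TRUE, 3)))
}

# Brute-force oracle: minimize the same ML discrepancy with an independent
# Sigma construction (built from the structural equations element by element)
# and a derivative-free/numeric-gradient optimizer.
oracle_fml <- function(X, free_A, free_Phi, standardize = FALSE) {
  p <- ncol(X)
  if (standardize) X <- scale(X)
  T_ <- nrow(X)
  Z <- cbind(X[1:(T_ - 1), ], X[2:T_, ])
  S <- cov(Z)
  V <- S[1:p, 1:p]
  iA <- which(free_A); iP <- which(free_Phi)
  build_sigma <- function(th) {
    A <- matrix(0, p, p); Phi <- matrix(0, p, p)
    A[iA] <- th[seq_along(iA)]
    Phi[iP] <- th[length(iA) + seq_along(iP)]
    psi <- exp(th[length(iA) + length(iP) + 1:p])
    Binv <- diag(p) - A
    # reduced form: eta_t = M eta_{t-1} + u_t
    M <- solve(Binv, Phi)
    U <- solve(Binv) %*% diag(psi, p) %*% t(solve(Binv))
    cross <- M %*% V                      # Cov(eta_t, eta_{t-1})
    cur <- M %*% V %*% t(M) + U           # Cov(eta_t)
    rbind(cbind(V, t(cross)), cbind(cross, cur))
  }
  fml <- function(th) {
    Sig <- build_sigma(th)
    out <- tryCatch({
      log(det(Sig)) + sum(diag(solve(Sig) %*% S)) - log(det(S)) - 2 * p
    }, error = function(e) 1e9)
    if (!is.finite(out)) 1e9 else out
  }
  th0 <- c(rep(0.05, length(iA)), rep(0.05, length(iP)), rep(0, p))
  o <- optim(th0, fml, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  o2 <- optim(o$par, fml, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-15))
  list(F = min(o$value, o2$value), par = if (o2$value < o$value) o2$par
       else o$par)
}

# small cached end-to-end run shared by io / gimme tests
cached_small_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    atlas <- default_atlas()
    prm <- simulation_params(n_subjects = 5L, T_len = 250L,
                             subgroup_sizes = c(3L, 2L),
                             subgroup_extra = c(2L, 2L),
                             individual_rate = 1, seed = 17L)
    str <- make_true_structure(atlas, prm)
    coh <- simulate_cohort(str, prm)
    res <- run_gimme(coh, search_config())
    cache <<- list(atlas = atlas, params = prm, structure = str,
                   cohort = coh, result = res)
    cache
  }
})

path_keys <- function(df) paste(df$lag, df$source, df$target)
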