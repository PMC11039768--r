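#' Default outcome-coupling coefficients
#'
#' Signs follow the reported directions: more positive within-SN density means
#' more slips, more positive DMN-FPN density fewer slips; more negative DMN-SN
#' density means less craving during treatment, more positive SN-FPN density
#' more craving. Magnitudes are on the density scale (densities live in
#' roughly 0-0.35), chosen so effects are reliably recoverable at n in the
#' low hundreds.
#'
#' @return Nested list of coefficients for the three outcomes.
#' @export
default_outcome_coeffs <- function() {
  list(
    slips = list(b0 = 1.0, snsn_pos = 20, dmnfpn_pos = -20,
                 age = 0.0, sex = 0.2, ftnd = 0.1, treatment = -0.2,
                 theta = 2),
    craving = list(b0 = 1.0, dmnsn_neg = -10, snfpn_pos = 10,
                   age = 0.0, sex = 0.1, ftnd = 0.05, treatment = -0.1,
                   sigma = 0.3),
    cue = list(b0 = 0.57, snfpn_neg = 5,
               age = 0.0, sex = 0.0, ftnd = 0.0, treatment = 0.0,
               sigma = 1.32))
}

#' Default covariate-generating distributions
#'
#' Emulates the cohort description: age ~ N(28.35, 6.36) truncated to 18-45,
#' 57 percent male, Fagerstrom score ~ N(4.49, 1.86) clipped to 0-10,
#' 29 of 49 in the patch+e-cigarette arm, baseline cigarettes/day
#' ~ N(11.62, 5.34) clipped below at 1.
#'
#' @return List of sampling functions, each taking n.
#' @export
default_covariate_dists <- function() {
  list(
    age = function(n) pmin(pmax(stats::rnorm(n, 28.35, 6.36), 18), 45),
    sex = function(n) stats::rbinom(n, 1, 28 / 49),
    ftnd = function(n) pmin(pmax(round(stats::rnorm(n, 4.49, 1.86)), 0), 10),
    treatment = function(n) stats::rbinom(n, 1, 29 / 49),
    baseline_cpd = function(n) pmax(round(stats::rnorm(n, 11.62, 5.34)), 1))
}

#' Simulate clinical outcomes coupled to true density metrics
#'
#' Slips are drawn from a negative binomial with log mean linear in the true
#' positive SN-SN and positive DMN-FPN densities plus covariates
#' (variance = mu + mu^2/theta). Craving during treatment is log-normal with
#' log mean linear in negative DMN-SN and positive SN-FPN densities; cue-
#' induced craving is Gaussian on its raw (difference) scale with a weak
#' negative SN-FPN coupling.
#'
#' @param density_profiles list of `density_profile` objects computed from
#'   the TRUE subject graphs (see [subject_truth()]).
#' @param coeffs coefficient list, see [default_outcome_coeffs()].
#' @param covariate_dists list of sampling functions, see
#'   [default_covariate_dists()].
#' @param seed RNG seed.
#' @return An `outcome_table` (see [read_outcomes()]).
#' @export
simulate_outcomes <- function(density_profiles,
                              coeffs = default_outcome_coeffs(),
                              covariate_dists = default_covariate_dists(),
                              seed = 1L) {
  if (coeffs$slips$theta <= 0) stop("dispersion theta must be positive")
  tab <- density_table(density_profiles)
  n <- nrow(tab)
  set.seed(seed)
  cv <- lapply(covariate_dists, function(f) f(n))
  dens <- function(m) tab[[m]]
  covpart <- function(cc) cc$age * cv$age + cc$sex * cv$sex +
    cc$ftnd * cv$ftnd + cc$treatment * cv$treatment
  mu_slips <- exp(coeffs$slips$b0 +
                    coeffs$slips$snsn_pos * dens("SN-SN_pos") +
                    coeffs$slips$dmnfpn_pos * dens("DMN-FPN_pos") +
                    covpart(coeffs$slips))
  slips <- stats::rnbinom(n, size = coeffs$slips$theta, mu = mu_slips)
  craving <- exp(coeffs$craving$b0 +
                   coeffs$craving$dmnsn_neg * dens("DMN-SN_neg") +
                   coeffs$craving$snfpn_pos * dens("SN-FPN_pos") +
                   covpart(coeffs$craving) +
                   stats::rnorm(n, 0, coeffs$craving$sigma))
  cue <- coeffs$cue$b0 +
    coeffs$cue$snfpn_neg * dens("SN-FPN_neg") +
    covpart(coeffs$cue) +
    stats::rnorm(n, 0, coeffs$cue$sigma)
  as_outcome_table(data.frame(
    subject_id = tab$subject_id, slips = slips,
    craving_treatment = craving, cue_craving = cue,
    age = cv$age, sex = cv$sex, ftnd = cv$ftnd, treatment = cv$treatment,
    baseline_cpd = cv$baseline_cpd))
}
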