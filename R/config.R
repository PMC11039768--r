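#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults reflect
#' the study conditions the synthetic cohort emulates (49 subjects, 11 ROIs,
#' 500 volumes at TR = 0.72 s) and the search settings of the connectivity
#' model search.
#'
#' @param ... named overrides of the defaults, e.g. `run_config(alpha = 0.01)`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # cohort dimensions
    n_subjects = 49L,
    n_timepoints = 500L,
    tr_seconds = 0.72,
    burn_in = 200L,
    # search settings
    gamma_group = 0.75,
    gamma_sub = 0.50,
    alpha = 0.05,
    walktrap_steps = 4L,
    max_paths = 20L,
    ar_start = TRUE,
    allow_reciprocal = TRUE,
    standardize = TRUE,
    # fit thresholds (any 2 of 4)
    cfi_min = 0.95, nnfi_min = 0.95, rmsea_max = 0.05, srmr_max = 0.05,
    # density / eligibility
    density_mode = "possible",
    eligibility_threshold = 0.25,
    # stability validation
    stability_alphas = seq(0.01, 1, by = 0.01),
    stability_reps = 100L,
    reassign_fraction = 0.20,
    # covariate coding
    sex_coding = "0=female,1=male",
    treatment_coding = "0=patch_only,1=patch_plus_ecig")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$gamma_group >= 0.5, cfg$gamma_group <= 1,
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to a YAML file
#' @param cfg a [run_config()].
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path path to a YAML file written by [write_config()].
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Printed study descriptors
#'
#' Self-contained quantities describing the study design, computed from their
#' primitive inputs: scan volumes from duration and TR, cohort size from the
#' two treatment-arm sizes, percentage male from the sex counts, ROI count
#' from the per-network atlas sizes, cue-induced craving as the post- minus
#' pre-scan desire-to-smoke mean.
#'
#' @param scan_minutes resting-state scan duration in minutes.
#' @param tr_seconds repetition time in seconds.
#' @param arm_sizes integer vector of treatment-arm sizes.
#' @param n_male,n_female sex counts.
#' @param desire_pre,desire_post mean desire-to-smoke ratings (1-5 scale)
#'   before and after the scan.
#' @param atlas a [network_atlas()].
#' @return Named list of computed descriptors.
#' @export
study_descriptors <- function(scan_minutes = 6, tr_seconds = 0.72,
                              arm_sizes = c(patch = 20L, patch_ecig = 29L),
                              n_male = 28L, n_female = 21L,
                              desire_pre = 2.14, desire_post = 2.71,
                              atlas = default_atlas()) {
  n <- sum(arm_sizes)
  list(
    n_timepoints = floor(scan_minutes * 60 / tr_seconds),
    n_subjects = n,
    pct_male = 100 * n_male / (n_male + n_female),
    cue_craving_mean = desire_post - desire_pre,
    n_rois = length(atlas$roi_names))
}
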