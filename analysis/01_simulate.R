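#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Draws the ground-truth connectivity structure (group paths mirroring the
# reported group map, two subgroups of 39/10 with 6/18 extra paths,
# Poisson(2) individual paths), simulates 49 subjects x 11 ROIs x 500
# volumes from the uSEM truth, computes each subject's TRUE density profile
# and couples the clinical outcomes to it. Everything needed by later
# stages is written under results/cohort/.

suppressPackageStartupMessages(library(netgimme))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

dir <- "results/cohort"
dir.create(file.path(dir, "timeseries"), recursive = TRUE,
           showWarnings = FALSE)
atlas <- default_atlas()
prm <- simulation_params(seed = seed)
truth <- make_true_structure(atlas, prm)
cohort <- simulate_cohort(truth, prm)
cat("Simulated", length(cohort), "subjects,",
    nrow(cohort[[1]]$data), "volumes x", ncol(cohort[[1]]$data), "ROIs\n")

for (ts in cohort)
  write_roi_timeseries(ts, file.path(dir, "timeseries",
                                     paste0(ts$subject_id, ".csv")))
file.copy(system.file("extdata", "atlas_dmn_sn_fpn.csv",
                      package = "netgimme"),
          file.path(dir, "atlas.csv"), overwrite = TRUE)

# the truth, for later recovery scoring
truth_edges <- do.call(rbind, lapply(names(truth$subgroup_assignment),
  function(id) cbind(subject_id = id, subject_truth(truth, id)$edges)))
write.csv(truth_edges, file.path(dir, "truth_edges.csv"), row.names = FALSE)
write.csv(data.frame(subject_id = names(truth$subgroup_assignment),
                     subgroup = unname(truth$subgroup_assignment)),
          file.path(dir, "truth_subgroups.csv"), row.names = FALSE)

true_profs <- lapply(names(truth$subgroup_assignment), function(id)
  compute_density_profile(subject_truth(truth, id)$edges, atlas,
                          "possible", subject_id = id))
outcomes <- simulate_outcomes(true_profs, seed = seed + 23)
write.csv(as.data.frame(outcomes)[
  c("subject_id", "slips", "craving_treatment", "cue_craving", "age",
    "sex", "ftnd", "treatment", "baseline_cpd")],
  file.path(dir, "outcomes.csv"), row.names = FALSE)
write_config(run_config(seed = seed), file.path(dir, "config.yml"))
cat("Cohort written to", dir, "\n")
cat("Mean slips:", round(mean(outcomes$slips), 2),
    "| mean craving:", round(mean(outcomes$craving_treatment), 2),
    "| mean cue-craving difference:", round(mean(outcomes$cue_craving), 2),
    "\n")
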