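#!/usr/bin/env Rscript
# Stage 4: sign-split within/between-network density metrics.
#
# Converts each subject's final directed graph into the 12 density metrics,
# writes the subjects x metrics table, the cohort descriptive summary
# (nonzero N, mean, SD, range) and the 25%-of-sample eligibility flags.

suppressPackageStartupMessages(library(netgimme))
res <- readRDS("results/gimme/result.rds")
atlas <- read_atlas("results/cohort/atlas.csv")

profs <- result_density_profiles(res, atlas, mode = "possible")
tab <- density_table(profs)
summ <- density_summary(profs)
el <- eligible_metrics(profs, threshold = 0.25)
dir.create("results/density", showWarnings = FALSE, recursive = TRUE)
write.csv(tab, "results/density/metrics.csv", row.names = FALSE)
summ$eligible <- el$included[summ$metric]
write.csv(summ, "results/density/summary.csv", row.names = FALSE)

cat("Density summary (eligibility rule: nonzero in >=", el$min_n,
    "of", el$N, "subjects):\n")
print(summ, digits = 3)
cat(sum(el$included), "of 12 metrics eligible for outcome models\n")
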