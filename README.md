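# netgimme

Person-specific directed functional-connectivity analysis for ROI fMRI
time series, with a fully synthetic, ground-truthed study cohort.

## The problem

Group-average resting-state connectivity analyses can fail to describe any
individual. This package implements, as tested R code, a complete
data-driven pipeline for parsing that heterogeneity in a cohort of
nicotine-dependent adults undergoing a two-week smoking-cessation attempt:

1. **uSEM fitting.** Each subject's p ROI signals follow a unified
   structural equation model — a structural VAR(1) with contemporaneous
   directed effects `A`, lag-1 effects `Φ` (diagonal = autoregressive) and
   diagonal Gaussian innovations:
   `η_t = A η_t + Φ η_{t−1} + ζ_t`. The maximum-likelihood discrepancy
   `F = log|Σ(θ)| + tr(SΣ(θ)⁻¹) − log|S| − 2p` is minimized over the free
   paths against the stacked covariance of `(η_{t−1}, η_t)`, with
   chi-square, CFI/NNFI/RMSEA/SRMR fit indices, expected-information Wald
   tests, and modification indices (1-df score tests).
2. **Three-stage model search (GIMME-style).** Group-level paths are added
   while a candidate's modification index is significant for ≥ 75% of
   subjects; subjects are then clustered by Walktrap community detection on
   a sign-aware shared-feature count matrix; subgroup-level paths are added
   at a ≥ 50% within-subgroup majority; individual-level paths are added
   until 2 of the 4 fit indices reach their excellent-fit cutoffs.
   Non-significant paths are pruned at each stage (AR and higher-level
   paths protected).
3. **Cluster-stability validation.** The similarity graph is rewired at
   increasing fractions and re-clustered; the subgrouping is *stable* only
   if ≥ 20% of edges must be perturbed before the partition differs as much
   as one with 20% of subjects randomly reassigned (variation of
   information, in bits). Unstable solutions halt subgroup-outcome
   analyses.
4. **Network density metrics.** Each final graph is summarized as 12
   sign-split within/between-network edge proportions over the DMN, SN and
   FPN; a metric enters regressions only if nonzero for ≥ 25% of the
   sample.
5. **Outcome regressions.** Negative-binomial regression of slips
   (cigarettes smoked during the attempt) and OLS on log-transformed
   craving outcomes, on the eligible density metrics plus age, sex,
   nicotine-dependence score and treatment arm, Bonferroni-corrected
   across the six models (p < 0.05/6).

Because raw study data are not public, the package ships a first-class
synthetic-cohort generator (`make_true_structure()`, `simulate_cohort()`,
`simulate_outcomes()`) whose defaults emulate the study conditions —
49 subjects × 11 ROIs × 500 volumes, group/subgroup/individual path
structure, outcomes coupled to the true densities — so that every stage is
exercised against a recoverable ground truth.

## Worked example

```r
library(netgimme)

prm    <- simulation_params(seed = 1)            # study-scale defaults
truth  <- make_true_structure(default_atlas(), prm)
cohort <- simulate_cohort(truth, prm)
res    <- run_gimme(cohort, search_config())
print(res)
#> gimme_result: 49 subjects | 19 group paths | 2 subgroups
#> mean fit: CFI 0.9805 NNFI 0.9688 RMSEA 0.0330 SRMR 0.0359
```

All 13 true group paths were recovered (the extra found paths are the
larger subgroup's shared paths, which exceed the 75% criterion because
that subgroup holds 39 of 49 subjects), and the mean fit indices show
every subject reaching excellent fit. Subgrouping and stability:

```r
compare_partitions(truth$subgroup_assignment, res$subgroups$assignment)$ari
#> [1] 1
stab <- assess_stability(res$similarity, res$subgroups,
                         alphas = seq(0.05, 1, 0.05), n_reps = 20, seed = 18)
print(stab)
#> stability: alpha* = 0.55 | benchmark VI = 0.929 bits | stable = TRUE
```

The planted 39/10 partition is recovered exactly and declared stable: 55%
of similarity edges must be rewired before the clustering degrades as much
as the 20%-reassignment benchmark. Densities and outcomes:

```r
profs <- result_density_profiles(res, default_atlas())
el <- eligible_metrics(profs)          # >= ceiling(0.25 * 49) = 13 subjects
mods <- fit_outcome_models(density_table(profs),
                           simulate_outcomes(lapply(
                             names(truth$subgroup_assignment), function(id)
                               compute_density_profile(
                                 subject_truth(truth, id)$edges,
                                 default_atlas(), subject_id = id)),
                             seed = 24),
                           eligibility = el)
mods$bonferroni$threshold
#> [1] 0.008333333
```

At n = 49 the per-coefficient estimates are noisy (as in any single cohort
of this size); the parameter-recovery behavior of the outcome models is
demonstrated at n = 200 in the tests and the acceptance script.

The full study-scale workflow is scripted under `analysis/`
(`01_simulate.R` … `05_outcomes.R`), each stage writing its tables under
`results/`.

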