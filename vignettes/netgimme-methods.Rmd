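---
title: "Methods: person-specific directed connectivity search and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: person-specific directed connectivity search and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Each subject's ROI signals $\eta_t \in \mathbb{R}^p$ follow a unified
structural equation model (uSEM), a structural VAR(1) with both
contemporaneous and lag-1 directed effects:

$$\eta_t = A\,\eta_t + \Phi\,\eta_{t-1} + \zeta_t,\qquad
\zeta_t \sim \mathcal{N}(0,\,\mathrm{diag}(\psi)),$$

where $A$ holds contemporaneous paths (no self-loops) and $\Phi$ lag-1
paths; the diagonal of $\Phi$ is the autoregressive (AR) effects. Our
convention throughout: an edge *source → target* means the target is
regressed on the source; lag 0 is contemporaneous, lag 1 is $t{-}1$.

Fitting works on the stacked $2p$-vector $(\eta_{t-1}, \eta_t)$ over the
$T-1$ usable pairs. With the covariance of the lagged block saturated, the
maximum-likelihood discrepancy

$$F_{\mathrm{ML}} = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1})
 - \log|S| - 2p$$

is minimized over the free entries of $A$, $\Phi$ and the innovation
variances. Because the likelihood factorizes into a marginal for the lagged
block and a conditional for the current block, the saturated block is
profiled out at the sample value exactly. Optimization is quasi-Newton
(BFGS) from zero starts (AR paths at 0.3), followed by Fisher-scoring
polish steps until the gradient max-norm falls below $10^{-6}$ (the
`converged` flag) — in practice far below. Standard errors come from the
inverse expected information; $\chi^2 = (n_\mathrm{eff}-1)F_{\mathrm{ML}}$
with $n_\mathrm{eff} = T-1$. We use the $n_\mathrm{eff}-1$ multiplier
throughout (the alternative $n_\mathrm{eff}$ differs negligibly at
$T = 500$) and the sample covariance with the $n-1$ denominator.

Series are z-scored per ROI before fitting by default
(`standardize = TRUE`): it makes path coefficients comparable across
subjects and stabilizes the optimization; a raw-scale mode is available.

## Fit indices and model search

Fit indices (CFI, NNFI, RMSEA, SRMR) are computed on the stacked
covariance against the usual independence baseline; "excellent fit" means
at least two of CFI ≥ 0.95, NNFI ≥ 0.95, RMSEA ≤ 0.05, SRMR ≤ 0.05
(inclusive at the threshold). Modification indices are one-df expected-
information score tests with the estimated parameters partialled out; the
expected parameter change (EPC) supplies the sign used by the subject
similarity. A slow exact-refit reference is exercised in the tests, where
each MI is checked against the refit $\Delta\chi^2$.

The three-stage search:

1. **Group level.** Start from the AR-only pattern and repeatedly add the
   candidate whose MI is significant ($p < \alpha$, default $\alpha=0.05$,
   unadjusted) for the largest number of subjects, provided that count
   reaches `gamma_group` (default 0.75) of the cohort; ties break by larger
   summed MI, then by a fixed (lag, target, source) order, making the
   search deterministic and independent of subject order. Added paths that
   end up Wald-significant for fewer than `gamma_group` of subjects are
   pruned (AR protected). A final *direction-revision* pass then
   re-examines orientation: paths picked early can point the wrong way
   because the model was still misspecified when they were chosen, and a
   contemporaneous and a lagged path on the same node pair tend to flip
   together. For each unordered node pair, the orientation combinations of
   its added paths are refit and the one with the lowest total discrepancy
   across subjects is kept; the pass is deterministic and subject-order
   invariant. It removes most — not all — orientation errors: when the
   rest of the model has already absorbed compensating paths, a wrong
   orientation can remain the local optimum, an inherent property of
   greedy stepwise search at these effect sizes. Starting at AR-only
   rather than a literally empty
   network is the established default for this family of searches — the
   final group model reports AR effects for every ROI either way; an
   `ar_start = FALSE` flag gives the literal empty start.
2. **Subgroups.** Each subject's feature set is the group paths tagged by
   the sign of that subject's estimate plus every significant non-group
   candidate tagged by its EPC sign; the similarity of two subjects is the
   count of shared (path, sign) features. Walktrap community detection
   (4-step random walks, weights = counts) on this graph yields the
   subgroups. Within each subgroup of size ≥ 2 the same add/prune loop runs
   with threshold `gamma_sub` (default 0.50, a strict majority for "most
   members"; the threshold is not pinned down by convention, so it is
   exposed as configuration).
3. **Individual level.** Per subject, the largest significant-MI candidate
   is added and the model refit until excellent fit is reached, no
   candidate remains, or `max_paths` (20) additions; individual paths are
   then pruned at $\alpha$ with group/subgroup/AR protected.

Reciprocal contemporaneous pairs are admissible during search
(`allow_reciprocal = TRUE`); subjects that fail to converge at some stage
keep their last converged model, are flagged, and still count in
denominators.

## Stability of the subgrouping

The subgrouping is validated by perturbation: for each fraction
$\alpha \in \{0.01, \dots, 1\}$ (step 0.01, 100 replicates by default;
desk-scale runs use step 0.05 with 20 replicates), $\lceil\alpha m\rceil$
of the $m$ nonzero dyads have their weights swapped with uniformly chosen
other dyads — conserving the weight multiset, symmetry, and zero diagonal —
and Walktrap is re-run. Dissimilarity to the original partition is measured
by variation of information (VI, in bits; ARI is reported alongside). The
benchmark is the mean VI against copies of the original partition with a
random 20% of subjects moved to different subgroups. The solution is
*stable* when the smallest $\alpha$ whose mean VI reaches the benchmark is
at least 0.20 (or the benchmark is never reached). The exact rewiring
variant of the published procedure is not fully specified, so the
symmetric weight-swap scheme used here is documented and seedable; a grid
that stops short of $\alpha = 0.20$ cannot evaluate the rule and is
flagged not-assessable. The unstable branch matters: when the solution is
not stable the pipeline skips subgroup-outcome analyses, exactly as the
motivating application had to.

## Density metrics and eligibility

Each non-AR edge of a subject's final graph belongs to the unordered pair
of networks of its endpoints — within DMN/SN/FPN or between DMN-SN,
SN-FPN, DMN-FPN — split by the sign of its estimate: 12 metrics. AR edges
are excluded: every subject has all of them by construction, so they carry
no between-subject information. The default denominator (mode
`"possible"`) is the number of admissible directed non-AR paths in the
category: $2n(n-1)$ within a network of size $n$ (contemporaneous plus
lagged, both directions), $4n_1n_2$ between networks. A shared-total
denominator (mode `"total"`, values summing to 1) is also shipped. The
per-category reading is the only one consistent with published descriptive
tables of this kind, whose 12 values sum to well above 1; this remains an
inference, and both modes are logged. A metric enters the regressions only
when at least $\lceil 0.25N \rceil$ subjects have a nonzero value
($\lceil 0.25 \cdot 49\rceil = 13$, so a 13-subject metric is included).

## Outcome models

Six primary models: {within, between} density families × {slips, craving
during treatment, cue-induced craving}. Slips (a count over the two-week
cessation attempt) use ML negative-binomial regression with log link
(dispersion $\theta$ estimated jointly; variance $\mu + \mu^2/\theta$),
with a likelihood-ratio $\chi^2$ against the covariate-only null as the
model-level test. The craving outcomes are log-transformed and fit by OLS;
because the cue-craving difference can be ≤ 0, the shifted transform
$\log(y - \min(y) + 1)$ is applied whenever any value is nonpositive
(plain $\log y$ otherwise) — the shift convention is recorded with the
results. Standardized $\beta = b\,\mathrm{sd}(x)/\mathrm{sd}(\log y)$.
Covariates: age, sex (0/1), nicotine-dependence score, treatment arm
(0/1), optionally baseline cigarettes/day. Missing outcomes are flagged at
read time and handled by listwise deletion (`n_used` reported — with one
incomplete subject, a 6-predictor/4-covariate model at $N=49$ yields
$F(10, 37)$). Model-level p-values (LR $\chi^2$ p for counts, overall F p
for linear models) are Bonferroni-corrected across the six models:
$p < 0.05/6 = 0.0083$.

# The synthetic cohort

The generator is the pipeline's ground truth, not a convenience fixture.
Defaults emulate the study conditions: 49 subjects, 11 ROIs (DMN = 2,
SN = 5, FPN = 4), 500 volumes at TR = 0.72 s, with a 200-sample burn-in
discarded from each simulated series. The group-level truth mirrors the
reported group map — contemporaneous paths within SN (2), FPN (4), DMN (1)
and between SN-FPN (1), SN-DMN (2); lagged within FPN (2) and DMN (1); AR
everywhere — with two subgroups of 39/10 subjects carrying 6 and 18 extra
paths and Poisson(2) individual paths per subject. Only path *counts* are
reported for the original cohort, never magnitudes, so magnitudes are a
stated convention: AR ~ U(0.2, 0.6), other paths ±U(0.2, 0.4) with a 30%
negative-sign share — strong enough to be reliably recoverable at T = 500,
weak enough to keep every subject stationary. Structures are
rejection-resampled until every subject's reduced-form transition matrix
$(I-A)^{-1}\Phi$ has spectral radius below 1. The truth never contains
both directions of the same contemporaneous pair: such reciprocal pairs
are weakly identified and would make "recovery" ill-posed regardless of
the search.

Series are generated by the reduced form
$\eta_t = (I-A)^{-1}(\Phi\eta_{t-1} + \zeta_t)$ with diagonal Gaussian
noise (the model's own assumption). Sample covariances converge to the
closed-form discrete-Lyapunov solution, which the tests verify at
$T = 20{,}000$ within 2%.

Outcomes are coupled to the *true* density profiles with the reported
effect directions: slips ~ NB with log-mean linear in +SN-SN and +DMN-FPN
density (signs +/−), craving log-linear in −DMN-SN (negative coefficient)
and +SN-FPN (positive), cue-craving weakly coupled to −SN-FPN; dispersion
$\theta = 2$ emulates over-dispersed counts. Covariates are drawn to match
the cohort description (age ~ N(28.35, 6.36) truncated to 18–45, 57%
male, FTND ~ N(4.49, 1.86) clipped to 0–10, 29/49 in the e-cigarette arm).
Coefficient magnitudes (±20 on the density scale for slips, ±10 for
craving) were chosen once so that effects are recoverable at $n$ in the
low hundreds, and are *not* estimates of the original effects.

What the generator does **not** emulate: hemodynamic smoothing and
autocorrelated scanner noise, motion artifacts, non-Gaussian innovations,
inter-subject variation in AR strength beyond the drawn range, or any
misspecification of the network assignment. Passing recovery tests
therefore shows the estimator and search are correct *under the model's
own assumptions* at the study's dimensions; it does not certify behavior
on real BOLD data.

# Numerical choices and edge cases

* Optimization: BFGS (`reltol` $10^{-14}$, ≤ 500 iterations) plus scoring
  polish; non-convergence yields a flagged result, never an exception.
* A singular stacked covariance (e.g. collinear ROIs) is an error advising
  a longer series; candidates whose adjusted information is singular are
  skipped with a warning.
* `df = 0` models take CFI = 1, RMSEA = 0 by convention.
* Tie-breaks in the search are fully deterministic (count, then summed MI,
  then lexicographic path order), so identical inputs give identical
  results; all stochastic stages (generator, rewiring, benchmarks) are
  seeded, with per-subject/per-replicate seeds derived from the master
  seed.
* An all-zero similarity matrix yields singleton subgroups, flagged
  degenerate; a single-subgroup solution makes the stability benchmark
  undefined and is reported not-assessable.
* Edges with an exactly zero estimate have no sign and are rejected when
  computing densities.
* Zero-variance density predictors are dropped from regressions with a
  warning; a constant outcome after transformation is an error.

# Problem sizes used by the shipped checks

The test suite exercises the engine oracles on 3–4-ROI systems
($T \le 20{,}000$), search recovery on cohorts of 5–20 subjects
($T = 250$–500), and the full 49 × 11 × 500 condition through the
acceptance checks with 2 replicates; stability checks use the desk-scale
grid (step 0.05, 20 replicates). The `analysis/` drivers run the complete
study-scale pipeline once end to end. Replicate counts in the tests are
deliberately modest; the invariants they check (oracle agreement,
conservation laws, determinism) do not depend on replicate count.

# Known limitations

Direction of contemporaneous paths is only weakly identified at moderate
$T$; occasional direction flips against the planted truth are expected and
observed. Subgroup paths shared by a subgroup comprising more than
`gamma_group` of the cohort are correctly (by the algorithm's definition)
promoted to group level. No latent-variable extension, higher-order lags,
non-Gaussian likelihoods, or missing-data estimation; inputs begin at
extracted ROI time series, never voxel data.
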