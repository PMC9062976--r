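# dsadyn

Unsupervised classification of early post-transplant donor-specific
antibody (DSA) dynamics, and the association of the resulting
dynamic-response groups with acute rejection and five-year graft
failure.

After HLA-incompatible kidney transplantation, the total DSA level
(tDSA, the per-day sum of single-antigen-bead MFI values across a
case's DSA specificities) follows one of a small number of dynamic
patterns in the first 50 days: no response, fast modulation, slow
modulation, rise to sustained, and sustained. `dsadyn` recovers these
groups from raw MFI time series with a four-stage pipeline:

1. **Gate** cases whose maximum post-transplant tDSA stays below
   τ = 1500 MFI into a no-response group 0.
2. **Interpolate** tDSA linearly onto a daily grid (days 0–50, no
   extrapolation; cases observed for fewer than 21 days are excluded),
   **scale** each responder by its own maximum, and **split** by length
   (reaching day 50 vs 20–50 days).
3. **Cluster** the full-length scaled series with dynamic time warping
   (DTW) under agglomerative clustering whose linkage replaces the two
   joined series by their pointwise mean, recomputing DTW distances at
   every merge. The number of clusters k is selected by the gap
   statistic — within-cluster dispersion `W_k = Σ_r D_r / (2 n_r)` on
   the log scale against B = 100 block-bootstrap reference sets
   (surrogates stitched from random 10-point segments of the observed
   series) — with the one-standard-error rule: the smallest k with
   `gap_k ≥ gap_{k+1} − s_{k+1}`.
4. **Classify** the shorter series into the learned clusters by
   nearest path-length-normalised DTW.

Downstream statistics: 2×2 odds ratios with Wald CIs, Fisher exact and
Wilcoxon rank-sum tests, stepwise logistic regression with deviance
F tests (enter p < 0.05, remove p > 0.1) reporting ROC-AUC and PR-AUC
with baseline ratios, and Kaplan–Meier / log-rank comparison of
modulation (groups 1–2) versus sustained (groups 3–4) arms.

Because the underlying patient data are not deposited, the package
includes a synthetic-cohort generator (`make_cohort`) reproducing the
five trajectory archetypes, the early-dense sampling schedule, and the
covariate/outcome structure, with truth labels retained for recovery
experiments. See the vignette (`vignettes/dsa-dynamics.Rmd`) for the
model details and design decisions.

## Worked example

```r
library(dsadyn)

res <- run_pipeline(pipeline_config(seed = 11, B = 100))
res$summary[c("n_input", "n_gated", "n_full", "n_short", "selected_k")]
#> $n_input
#> [1] 88
#> $n_gated
#> [1] 18
#> $n_full
#> [1] 44
#> $n_short
#> [1] 26
#> $selected_k
#> [1] 4

res$stats$rates
#>          arm  n rejection_rate    gf_rate
#> 1 modulation 35      0.5714286 0.02857143
#> 2  sustained 35      0.3714286 0.22857143

res$stats$gf_or$or        # odds of 5-year graft failure, sustained arm
#> [1] 10.07407
res$stats$km$logrank_p
#> [1] 0.01267574
```

An 88-case synthetic cohort is simulated (group sizes 18/15/23/16/16):
18 cases fall below the 1500-MFI gate, 44 responders reach day 50 and
are clustered (the gap statistic selects k = 4), and the remaining 26
shorter responders are classified into those clusters by nearest DTW.
The association table shows the characteristic dissociation: the
modulation arm has the higher early-rejection rate but the far lower
five-year graft-failure rate (odds ratio ~10 for the sustained arm,
log-rank p = 0.013).

Lower-level entry points: `make_cohort()`, `preprocess_cohort()`,
`dtw_distance()` / `dtw_matrix()`, `agglomerate()` / `cut_clusters()` /
`classify_short()`, `gap_curve()` / `select_k()`, `odds_ratio()`,
`stepwise_lr()`, `kaplan_meier()`.

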