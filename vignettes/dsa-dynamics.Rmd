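---
title: "Classifying early post-transplant DSA dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying early post-transplant DSA dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsadyn)
```

## The problem

After HLA-incompatible kidney transplantation, donor-specific antibody
(DSA) levels — measured as single-antigen-bead MFI — can rise sharply,
fall again, or stay persistently high during the first weeks. These
dynamic patterns, rather than any single time-point value, carry
prognostic information: early *modulation* (a rise followed by a fall)
is associated with frequent early acute rejection but good five-year
graft survival, while a *sustained* response is associated with worse
long-term outcome. `dsadyn` implements an unsupervised pipeline that
classifies per-case total-DSA (tDSA) time series into five
dynamic-response groups and links the groups to outcomes:

0. **no response** — tDSA stays below 1500 MFI throughout;
1. **fast modulation** — quiescence for about 5 days, a sharp rise
   peaking near day 13, a short (3–4 day) peak, then a sharp fall (decay
   half-life on the order of 5 days) back to the pre-peak level;
2. **slow modulation** — the same early rise, then a gradual, oscillating
   decline to roughly 30% of peak by day 50 (consistent with the ~23-day
   half-life of IgG1);
3. **rise to sustained** — a slower rise from a higher baseline, peaking
   near day 21, then persistently high levels;
4. **sustained** — persistently above 1500 MFI with no substantial rise
   or fall.

Because the underlying patient-level data are not publicly deposited,
the package ships a synthetic-cohort generator that reproduces these
archetypes together with the sampling and covariate structure the
analysis assumes, so that every stage of the pipeline is testable.

## The pipeline

**Stage 1 — gating.** Per case, individual DSA MFIs are summed per day
into tDSA. Cases whose maximum post-transplant tDSA is strictly below
1500 MFI form group 0 and are excluded from clustering: once scaled,
near-noise-floor series would contribute spurious shape information,
and MFI values in this range are dominated by assay uncertainty.

**Stage 2 — interpolation, scaling, length split.** tDSA is linearly
interpolated onto an integer daily grid between the first and last
observed post-transplant day, capped at day 50; there is no
extrapolation. Cases whose last observation is before day 20 are
excluded (the 21-day inclusion rule: days 0–20 span 21 daily points).
Responders are scaled by their own maximum, so shapes rather than
levels are compared. Cases reaching day 50 form the clustering set;
cases with 20–50 days are held out for classification. The clustered
vector is days 1–50 (50 points): day 0, the transplant day itself,
informs the gate and the interpolation but is not part of the
clustered window. Fifty points also divide evenly into the
10-point bootstrap blocks used below.

**Stage 3 — DTW mean-linkage clustering with gap-statistic model
selection.** The distance between two scaled series is classic dynamic
time warping: absolute-difference local cost, steps
{(1,0), (0,1), (1,1)}, no window (50-point series are cheap to align
exactly), unnormalised for the equal-length clustering set. The
agglomeration is deliberately non-standard: at each iteration the two
closest active nodes merge and are *replaced by the pointwise mean of
their two representative series*, after which DTW distances from the
new representative to all remaining nodes are recomputed. This
"mean of the joining series" linkage is taken literally — the new
representative averages the two merged representatives, not all member
series; the member-mean alternative is available via
`agglomerate(..., member_mean = TRUE)` for sensitivity analysis.
Because representatives are recomputed, merge heights need not be
monotone and nothing in the implementation assumes an ultrametric.

The number of clusters is chosen with the gap statistic. Within-cluster
dispersion is the pooled pairwise form
\(W_k = \sum_r D_r / (2 n_r)\) with \(D_r\) the sum of all pairwise DTW
distances inside cluster \(r\), compared on the log scale against
reference sets: each of \(B = 100\) reference sets contains as many
surrogate series as the data (47 in the canonical configuration), each
surrogate stitched from five randomly chosen 10-point blocks of
randomly chosen observed series (block bootstrap, preserving
short-range autocorrelation while destroying group structure). Blocks
are drawn with replacement, with start positions uniform over all valid
positions; surrogate sets are re-clustered with the *identical* DTW
mean-linkage pipeline, holding the method fixed. With
\(\mathrm{gap}_k = \overline{\log W^*_k} - \log W_k\) and
\(s_k = \mathrm{sd}(\log W^*_k)\sqrt{1 + 1/B}\), the selected \(k\) is
the smallest with \(\mathrm{gap}_k \ge \mathrm{gap}_{k+1} - s_{k+1}\) —
the first point at which the data-versus-reference dispersion
difference stops increasing.

**Stage 4 — classification of shorter series.** Held-out 20–50-day
series (scaled by their own maxima) are assigned to the cluster whose
mean representative is nearest under *path-length-normalised* DTW;
normalisation makes distances comparable across unequal lengths. Ties
go to the lower-numbered cluster.

**Association statistics.** Clusters are labelled by their nearest
archetype skeleton and collapsed into modulation (groups 1–2) versus
sustained (groups 3–4) arms. The package then provides: 2×2 odds
ratios with Wald intervals (any zero cell is reported as inestimable),
the Fisher two-tailed exact test, the Wilcoxon rank-sum test (exact
null for combined n ≤ 20 without ties), forward–backward stepwise
logistic regression using a deviance F test (enter at p < 0.05, remove
at p > 0.1 — mirroring the stepwise GLM tools common in clinical
work), ROC-AUC by the rank formulation, PR-AUC by step interpolation
(average precision, avoiding the optimism of trapezoidal PR
interpolation), both with baseline ratios (0.5 and prevalence), and
Kaplan–Meier curves with the log-rank test via the survival package.

## The synthetic generator

`make_cohort()` draws, per case: an archetype (with the requested group
sizes), a sampling schedule, a trajectory, covariates and outcomes.

* **Skeletons.** The rise is logistic, reaching 95% of the
  baseline-to-peak span at the peak day, with midpoint halfway between
  the end of quiescence and the peak. Post-peak decay is exponential.
  The archetype-level constants are: quiescence 5 days; peak day 13
  (groups 1–2) or 21 (group 3); peak duration 3–4 days (group 1);
  decay half-life 5 days (group 1); a day-50 plateau at 30% of peak
  (group 2). For group 2 the plateau fraction fixes the decay rate
  exactly (it implies a half-life of ~21 days, consistent with — and
  taking precedence over — the nominal 23-day IgG1 half-life, since
  the 30%-at-day-50 value is the directly observed quantity).
  Group-2 oscillations are sinusoidal with period 7 days and default
  amplitude 0.15 of the current level, applied post-peak.
* **Quiescent baselines.** Groups 1–2 default to 1200 MFI — below the
  1500-MFI gate, reflecting that these cases are described as
  "inactive" before the rise; their gate passage comes from the peak.
  Group 3 starts higher (3500 MFI); group 4 sits at 9000 MFI
  throughout.
* **Noise.** Measurement noise is multiplicative log-normal with unit
  mean and configurable coefficient of variation (default 0.1),
  reflecting positive, heteroscedastic MFI readouts. Group-0
  realisations are truncated just below the gate and group-4
  realisations just above it, so the archetypes' gate semantics hold
  for every draw.
* **Per-case heterogeneity.** With `param_jitter = TRUE` (the default)
  baselines, peak levels, peak days and decay rates vary between cases
  around the defaults. The jitter ranges are deliberately narrow enough
  to preserve each archetype's identity — e.g. group 1 keeps a
  peak/baseline ratio of at least 8 and a decay half-life within
  roughly ±30% of 5 days, and group 2's plateau fraction stays in
  [0.20, 0.45] — because wider ranges would create boundary cases that
  are genuinely members of a neighbouring archetype (a "slow" group-1
  case with a high settling level is indistinguishable in principle
  from a fast group-2 case once DTW has warped away timing).
  `param_jitter = FALSE` draws every case from the exact defaults.
* **Sampling.** Observation days emulate clinical monitoring: day 0 is
  always sampled, days 1–20 are sampled with probability 0.6/day, later
  days with 0.15/day, and each case has a last-observation day that is
  day 50 with probability 2/3 and otherwise uniform on 21–49 (so about
  two thirds of responders are full length, matching a 47/23 split at
  cohort scale). Under these defaults more than 80% of cases have ten
  or more sampled days in the first 20 days.
* **Specificities.** Only the tDSA sum is modelled mechanistically; it
  is partitioned across 1–7 per-case DSA specificities by a Dirichlet
  split, because downstream analysis only consumes the sum.
* **Covariates and outcomes.** Per-group probabilities follow the
  direction of the observed group differences: early-rejection
  probabilities of (0.17, 0.80, 0.57, 0.56, 0.19) for groups 0–4 and
  five-year graft-failure probabilities of (0.11, 0.07, 0.04, 0.31,
  0.25), plus group-dependent gender, age, previous-transplant and
  crossmatch distributions. Graft-failure times are uniform over the
  five-year window; everyone else is censored at five years. The
  constructor rejects parameterisations that invert the
  modulation-versus-sustained outcome directions.
* **Truth labels** are retained in a separate `true_group` column so
  recovery experiments need no extra bookkeeping.

What the generator does *not* emulate: per-specificity immunology
(class I versus II kinetics), prozone/saturation artefacts at high MFI,
treatment effects on trajectories, or autocorrelated biological
variation beyond the archetype skeletons (noise is independent across
sampled days). Passing tests therefore demonstrate that the pipeline
recovers structure of the kind the archetypes describe under assay-like
noise — not that it would perform identically on any real cohort.

## Numerical choices and edge cases

* Seeds: every stochastic function takes a seed; one global seed fans
  out to child seeds via `seed + 1000003 * index (mod 2^31 - 1)`, so
  stages are independently re-runnable and cohorts are bit-for-bit
  reproducible.
* The 1500-MFI gate is strict (`< 1500` is no-response), and gating
  before or after interpolation is equivalent because linear
  interpolation attains its maximum at an observed day (asserted by a
  property test rather than assumed).
* DTW ties between predecessor cells are resolved diagonal-first, and
  path-length normalisation uses the number of cells on the optimal
  path found under that rule.
* Merge ties take the lexicographically smallest node-id pair; cluster
  numbering after a cut is by decreasing size with ties by smallest
  contained case index. Both make builds deterministic.
* `select_k` falls back to `k_max` with a warning when the gap keeps
  increasing; `gap_curve` refuses degenerate inputs whose
  within-cluster dispersion is zero (identical series), since the log
  comparison is undefined there.
* Stepwise logistic regression flags candidates that produce complete
  separation and excludes them with a warning instead of reporting
  unbounded odds ratios.
* ROC baseline is fixed at 0.5 and PR baseline at prevalence; both
  ratios are reported alongside the raw AUCs.

## Problem sizes used in the test suite

The canonical recovery experiment — 47 responder series drawn from the
four non-trivial archetypes in roughly equal numbers, B = 100 reference
sets, k up to 10 — runs in well under a minute per cohort and is
exercised on five seeds in the validation suite. Its input is the
daily-sampled 50-day trajectories themselves (every day observed): with
the sparse late clinical schedule, samples arrive roughly every seven
days after day 20, and daily linear interpolation then aliases group
2's 7-day oscillation to almost nothing, erasing one of the separators
between fast and slow modulation. The subsampled-schedule variant is
exercised by the end-to-end pipeline tests instead, where exact
cluster-count recovery is not the property under test. Unit tests use
scaled-down configurations (10–20 series, B = 2–20, shorter grids)
chosen so each property is still informative; the single-archetype
no-spurious-structure check, for example, uses 15 series and B = 20.
Simulation-based calibration tests (stepwise selection, log-rank type-I
error, Wilcoxon power) use 300–600 replicates, enough for the
tolerances they assert.

## Known limitations

* With realistic per-case heterogeneity, the fast/slow-modulation
  boundary is intrinsically fuzzy: DTW discounts timing differences, so
  the two groups are separated mainly by their settling level and by
  group 2's oscillations. Cohort draws that happen to contain boundary
  cases can merge the two groups one level too early in the tree, in
  which case the gap statistic honestly reports three clusters.
  Relatedly, max-scaling a flat noisy series places different sustained
  cases at different sub-1 levels (the scaled level is the reciprocal
  of the case's maximum noise excursion), a level offset DTW cannot
  warp away; this inflates the sustained group's internal spread.
* The merge tree is rebuilt from scratch for every reference set; no
  distances are cached across merges beyond what the algorithm
  specifies. This is O(n^2) DTW alignments per clustering and is the
  dominant cost of the gap curve.
* The stepwise F-test variant follows the deviance-F convention of
  common stepwise-GLM tools; likelihood-ratio chi-square stepping would
  give slightly different entry orders in borderline cases.
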