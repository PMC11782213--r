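---
title: "Modelling the Down-syndrome AD biomarker cascade: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Down-syndrome AD biomarker cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscascade)
```

## The scientific problem

Adults with Down syndrome (DS) carry the amyloid precursor protein gene in
triplicate and develop Alzheimer's disease (AD) pathology on a compressed
timeline: amyloid plaques accumulate from the mid-30s and tau tangles follow
within a few years, rather than the decade seen in sporadic AD. Plasma glial
fibrillary acidic protein (GFAP) indexes astrogliosis, and a central
mechanistic question is whether astrocyte activation sits *between* amyloid
and tau on the causal path — i.e. whether amyloid stimulates astrocytes,
which in turn promote tau phosphorylation and deposition.

`dscascade` implements the three statistical stages that question requires,
over a cross-sectional cohort of DS participants and sibling controls:

1. **Pathology-group comparisons.** Participants are classified A+/A− by
   amyloid-PET Centiloid > 18 and T+/T− by a Braak-I/III/IV tau-PET summary
   SUVR > 1.3 (strict inequalities; missing values give an explicit
   `unknown`). Plasma GFAP and pTau-217 are compared across
   control / A−/T− / A+/T− / A+/T+ with a Kruskal–Wallis omnibus test and
   pairwise Wilcoxon rank-sum tests, Bonferroni-corrected over the six-pair
   family, each pair summarized by a Hodges–Lehmann shift with a rank-sum
   inversion CI.
2. **Trajectory divergence.** Each biomarker is regressed on age with a
   penalized cubic regression spline per group, and a participant-level
   bootstrap estimates the earliest age at which the DS curve sustainably
   exceeds the control curve, plus pairwise comparisons of divergence timing
   between biomarkers on shared replicates.
3. **Causal mediation.** A covariate-adjusted product-of-coefficients
   mediation analysis quantifies the share of the amyloid → tau (PET or
   plasma pTau-217) association carried by plasma GFAP, with a
   case-resampling bootstrap for CIs and p-values.

Because the underlying cohort data are available only on application, the
package ships a synthetic-cohort generator with a known
amyloid → GFAP → tau causal structure; every stage is exercised against
ground truth.

## EYO convention

Estimated years to symptom onset is `EYO = AAO − age` with AAO = 52.5
years. EYO therefore **counts down** toward onset: positive before expected
onset, 0 at it, negative afterwards. Some familial-AD studies use the
opposite sign; all internal code uses this convention and
`estimate_divergence_age(..., axis = "eyo")` merely relabels the age axis.

## The synthetic cohort

`generate_cohort()` draws, per participant: group, age (truncated normal
within 25–65 y; means/SDs 44.93 [9.7] for DS and 43.57 [12.5] for controls,
matching the observed cohort), sex (78.6 % / 45.1 % female in controls/DS —
the real groups are sex-imbalanced), APOE ε4 carriage (23.4 %), and an
inter-measurement latency uniform on 0–540 days (some PET was acquired at
an 18-month follow-up).

Biomarkers follow the causal triangle:

* **Amyloid (Centiloid)**: controls are age-flat at the floor; DS means
  follow a four-parameter logistic in EYO,
  `floor + amplitude / (1 + exp(−rate · (midpoint_eyo − eyo)))`.
* **GFAP (mediator)**: `floor + a·(amyloid − floor) + covariates + noise`
  in DS; age-flat in controls. GFAP is generated **once** and shared by
  both outcomes, so the two mediation structures must agree on `a` and the
  mediator noise SD (validated).
* **Tau-PET SUVR and plasma pTau-217 (outcomes)**:
  `floor + c′·(amyloid − floor) + b·(GFAP − floor) + covariates + noise`.

Noise is additive Gaussian on the measurement scale, truncated at zero for
concentrations; the truncation is identical across groups, so zeroing
amplitudes and paths leaves DS and controls identical in law (the null
configuration). Missingness is completely at random per modality, at the
observed availability rates (39.4 % amyloid PET, 54.6 % tau PET, 13.2 %
per plasma assay missing); complete-case analyses are unbiased under MCAR,
which is all the pipeline claims. Every generated cohort carries a
ground-truth sidecar (all parameters, the seed, and the implied proportion
mediated per outcome).

Default effect scales were chosen once for realism: `a = 2` pg/mL GFAP per
Centiloid with 40 pg/mL noise reproduces group shifts of tens of pg/mL; the
outcome paths put the true proportion mediated at 15.3 % (tau PET) and
42.1 % (pTau-217), the regime the mediation stage is meant to resolve; and
the amyloid trajectory (floor 5, amplitude 80 CL, midpoint EYO 2,
rate 0.45/y, noise 12 CL) yields roughly 45 % amyloid-positivity and 20 %
tau-positivity among measured DS participants, with the familiar stair-step
group pattern. What the generator does **not** emulate: longitudinal
within-person correlation, heavy-tailed assay noise, informative
missingness, and site effects — so green tests certify the estimators under
a clean cross-sectional MCAR world, not robustness to those features.

## Penalized splines

`fit_penalized_spline()` minimizes `||y − Bβ||² + λ βᵀPβ` with a cubic
regression spline basis (knots at empirical quantiles of `x`, basis
dimension `k = 10` by default) and the second-derivative penalty, both
taken from `mgcv::smoothCon()`; the penalized solve, GCV search and SE
machinery are the package's own so that bootstrap refits reduce to
indexing precomputed basis rows and solving k×k systems. The penalty
nullspace holds constants and lines, so the effective degrees of freedom
(trace of the smoother matrix) run from 2 (`λ → ∞`, the OLS line) to `k`
(`λ = 0`). `λ = "gcv"` minimizes `n·RSS/(n − edf)²` over a 41-point
logarithmic grid scaled by `tr(XᵀX)/tr(P)`; tests confirm agreement with
`mgcv::gam` fits on the same data.

## Divergence ages

"When does the DS curve leave the control curve?" is operationalized as
**sustained exceedance**. Participants are resampled with replacement
within group (knots fixed at the original quantiles); each replicate
records the DS − control difference on a 0.1-year age grid.

* **Point estimate**: the smallest grid age at which the pointwise
  bootstrap percentile interval (level `1 − α`, default 95 %) of the
  difference lies strictly above zero there *and at every older grid age*.
* **Per-replicate ages** (for the CI, the detection fraction, and timing
  comparisons): the first grid age where that replicate's difference
  exceeds `z₁₋α/₂` model-based standard errors of the difference, sustained
  to the end of the grid. A bare "difference > 0" rule would flag ~half of
  all null replicates (a random curve ends positive half the time); the
  SE-scaled rule is calibrated near the α level under the null, which the
  test suite verifies.
* When fewer than half the replicates detect a divergence the estimate is
  reported as *none* together with the detection fraction.

Two numerical choices matter. First, the evaluation grid is restricted to
ages supported by at least 5 observations per group (or the trimmed
2.5 %–97.5 % range if that is narrower): spline fits are boundary-unstable
where data are sparse, and since the rule reads the band out to the oldest
grid age, an unsupported edge can veto an otherwise clear divergence.
Second, the point estimate (an ensemble-band functional) and the CI (a
percentile of per-replicate ages) are different functionals; the CI is
widened, when necessary, to bracket the point estimate.

Timing comparisons use per-replicate age differences. Two biomarkers
analysed from the same cohort with the same seed share resampling indices,
so the differences are paired; replicates lacking a detection for either
biomarker are dropped with their fraction reported, and the two-sided
p-value `2·min(P(d ≤ 0), P(d ≥ 0))` is floored at `1/B`. Both spline and
flat (group-mean) control fits are available, since a flat control
reference is equally defensible for age-stable markers.

The divergence age is a *detectability* quantity: it moves later as noise
grows and earlier as samples grow. The recovery benchmark therefore uses an
abrupt-onset amyloid scenario (rate 3/y — a lift-off spanning ~2 years)
in which the estimand is nearly insensitive to sample size, making a
large-n run of the same estimator (n = 20,000/2,000) a valid oracle for the
study-scale estimator (n = 348/42).

## Mediation

With mediator model `M ~ T + Z` (path `a`) and outcome model
`Y ~ T + M + Z` (paths `b`, `c′`), the average causal mediation effect is
`a·b`, the direct effect `c′`, and their sum equals the treatment
coefficient of `Y ~ T + Z` *exactly* — an algebraic identity of least
squares that the tests assert to 1e−10. This equals the counterfactual
ACME under linearity, no treatment–mediator interaction, and the usual
no-unmeasured-confounding assumptions; none of these are testable here and
the package makes no claim beyond them. Sex and APOE ε4 enter as binary
indicators, latency in days as continuous.

Uncertainty comes from a seeded case-resampling bootstrap (percentile CIs;
two-sided p-values floored at `1/B`; 5,000 replicates by default). The
proportion mediated `ACME / TE` is reported raw — it may legitimately fall
outside [0, 1] when paths oppose — alongside a [0, 1]-truncated convenience
value; replicates with `|TE|` below 1 % of the point estimate's total
effect are dropped from the proportion's distribution, and a stability flag
is set when more than 1 % drop. One calibration subtlety: when *both*
`a = 0` and `b = 0` the product statistic is degenerate and its bootstrap
p-value is conservative (this is intrinsic to product-of-coefficients
tests, not a defect of the bootstrap); the null-calibration checks
therefore use `a = 0` with `b ≠ 0`, where the ACME is asymptotically
normal and its p-values are uniform.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Centiloid threshold | 18 | CL | amyloid positivity (strict `>`) |
| tau SUVR threshold | 1.3 | SUVR | tau positivity (strict `>`) |
| AAO | 52.5 | years | DS population average onset |
| spline basis `k` | 10 | – | standard GAM practice; GCV shrinks unused df |
| smoothing `λ` | GCV | – | no hyperparameter stated for the model family |
| divergence grid step | 0.1 | years | below reporting resolution |
| divergence α | 0.05 | – | two-sided 95 % band |
| trajectory bootstrap | 10,000 | replicates | default; stable to ~0.3 y at 500 |
| mediation bootstrap | 5,000 | replicates | default |
| minimum mediation n | 30 | rows | guards the linear fits |

## Analysis sizes

The shipped analyses and checks run at desk scale, chosen once: module
tests use 100–500 bootstrap replicates and cohorts of 40–500 per group;
the end-to-end checks use 20 seeds × 1,000 mediation replicates, 20 seeds
× 500 trajectory replicates against a 200-replicate n = 22,000 oracle, and
200-seed null calibrations. A bootstrap-stability test confirms that 200
vs 1,000 trajectory replicates move the divergence age by less than 0.3
years on a strong-effect cohort, so the scaled sizes do not alter the
conclusions the defaults would give.

## Known limitations

* Cross-sectional only: no within-person slopes; the divergence age is a
  population-curve property, not an individual onset age.
* Rank-based group comparisons are unadjusted; covariates enter only the
  mediation and (optionally, via pre-residualization) the trajectories.
* Percentile (not BCa) bootstrap intervals; pointwise (not simultaneous)
  divergence bands.
* The Wilcoxon exact/normal agreement bound of 0.02 holds for groups of
  ~8–10 per arm (the top of the exact range); at n ≈ 4 the doubling rule
  and the continuity-corrected normal can differ by ~0.03.
* With heavy ties the rank-inversion CI uses the tie-free null
  distribution and is conservative; a seeded bootstrap CI is provided as
  the alternative.
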