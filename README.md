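# dscascade

Ordering the Alzheimer's disease biomarker cascade in Down syndrome (DS),
and asking whether astrogliosis links amyloid to tau.

Adults with DS develop AD pathology on a compressed timeline. `dscascade`
implements the three statistical stages needed to place plasma GFAP
(astrogliosis) and plasma pTau-217 on that timeline relative to amyloid and
tau PET, for a cross-sectional cohort of DS participants and sibling
controls:

* **A/T pathology-group comparisons** — amyloid positivity at
  Centiloid > 18, tau positivity at Braak-I/III/IV summary SUVR > 1.3;
  Kruskal–Wallis omnibus plus pairwise Wilcoxon rank-sum tests with
  Bonferroni correction, Hodges–Lehmann shifts with rank-inversion CIs.
* **Trajectory divergence** — penalized cubic-regression-spline fits of
  each biomarker against age per group (GCV-smoothed), with a
  participant-level bootstrap locating the earliest age of sustained
  DS-over-control exceedance, and paired comparisons of divergence timing
  between biomarkers.
* **Causal mediation** — product-of-coefficients mediation (`ACME = a·b`,
  `ADE = c′`, `TE = c′ + a·b` exactly) of the amyloid → tau-PET and
  amyloid → pTau-217 relationships through GFAP, adjusted for
  inter-measurement latency, sex and APOE ε4, with case-resampling
  bootstrap CIs and p-values.

Because the motivating cohort data are available only on application, the
package includes a seeded synthetic-cohort generator with a known
amyloid → GFAP → tau causal structure (sigmoidal amyloid accumulation
against estimated years to onset, EYO = 52.5 − age; Table-1-like covariate
mix and per-modality missingness). Every estimator is tested against that
generator's ground truth. See `vignettes/biomarker-cascade.Rmd` for the
full methods account.

## Worked example

```r
library(dscascade)

sim <- generate_cohort(cohort_config(seed = 11))   # 348 DS + 42 controls
at  <- build_analysis_table(sim$cohort)
table(at$table$combined_label)
#>   A-/T-   A+/T-   A+/T+ control unknown
#>      49      33      22      42     244

cc <- compare_by_pathology_group(at, "gfap")
cc$pairwise[, c("group_a", "group_b", "adjusted_p", "hl_shift")]
#>   group_a group_b   adjusted_p   hl_shift
#> 1 control   A-/T- 8.2e-01         12.2
#> 2 control   A+/T- 1.5e-05        -55.7
#> 3 control   A+/T+ 8.1e-09       -150.9
#> 4   A-/T-   A+/T- 2.6e-08        -70.0
#> 5   A-/T-   A+/T+ 1.5e-09       -162.6
#> 6   A+/T-   A+/T+ 2.8e-06        -91.6
```

The stair-step is the substantive pattern: GFAP is *not* elevated in DS
without amyloid (control vs A−/T−, adjusted p = 0.82), rises by ~56 pg/mL
in A+/T− (HL shift, sign relative to the first group), and further in
A+/T+. Divergence ages and mediation follow the same interface:

```r
d <- estimate_divergence_age(at$table, "centiloid", n_bootstrap = 1000, seed = 7)
d
#> divergence_result: centiloid on age axis
#>   divergence at 44.0 (95% CI 43.1-47.3), detection 99.7%

m <- bootstrap_mediation(mediation_spec(outcome = "ptau217", seed = 7),
                         subset(at$table, group == "DS"))
m
#> mediation_result (n = 177, 5000 bootstrap replicates)
#>   acme                  0.001754  [0.0009645, 0.002563]  p = 0.0002
#>   ade                   0.003929  [0.003106, 0.004762]  p = 0.0002
#>   total_effect          0.005684  [0.005246, 0.006126]  p = 0.0002
#>   proportion_mediated     0.3087  [0.1709, 0.4444]  p = 0.0002
```

Here GFAP carries ~31 % of the amyloid → pTau-217 association on this
single cohort draw, whose generating truth is 42.1 % (recorded in
`sim$truth`); across seeds the estimator is unbiased, which the recovery
tests check directly.

The numbered scripts under `analysis/` run the full narrative —
simulate → preprocess → group comparisons → trajectories → mediation —
writing tables under `results/`; `run_pipeline()` does the same in one
call from a config list or YAML file.

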