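# comorbnet

Phenotype-stratified multimorbidity network analysis for binary comorbidity
cohorts.

Clinicians studying a heterogeneous index disease (the motivating case is
COPD) want to know whether the *web* of a patient's other chronic conditions —
not just their count — differs between clinical phenotypes such as chronic
bronchitis (CB+/CB−) or a history of severe exacerbations (Ex+/Ex−).
`comorbnet` is for epidemiologists and biostatisticians running that analysis:
diseases are nodes, and links are pairwise associations validated by a
within-stratum bootstrap.

## The model

For each disease pair the pairwise-complete 2×2 table
(n₁₁, n₁₀, n₀₁, n₀₀) gives

* the **phi coefficient**
  φ = (n₁₁n₀₀ − n₁₀n₀₁) / √(r₁r₀c₁c₀) — the Pearson correlation of the two
  binary indicators, range [−1, 1];
* the **co-occurrence relative risk** RRᵢⱼ = (Cᵢⱼ·N)/(Pᵢ·Pⱼ), the observed
  joint count over its independence expectation, with a delta-method CI;
* a chi-square test (no continuity correction, so X² = N·φ² exactly) or
  Fisher's exact test when any expected count is below 5.

Diseases are retained when their prevalence (over non-missing entries —
denominators are per-variable) reaches 3.5 % in at least one phenotype
subgroup; the filter is joint across subgroups so all networks share one node
set. Each stratum is then resampled with replacement at fixed size (defaults:
800 for CB strata, 400 for Ex strata; B = 10 000 resamples). A pair becomes a
drawn edge when the 2.5th percentile of its bootstrap φ distribution exceeds
0; **network density** is the mean φ over all candidate pairs and **node
connectivity** the mean φ over a disease's incident pairs, with per-node
bootstrap-interval overlap used to compare strata.

Because real cohort tables are rarely shareable, the package includes a
latent-Gaussian synthetic-cohort generator (`cohort_spec()`,
`generate_cohort()`) with exact marginal prevalences and direct pairwise φ
targeting via the bivariate-normal orthant equation; `copd_cohort_spec()`
reproduces the scale of a 1726-patient multicentre COPD cohort with planted
stratum densities.

## Worked example

```r
library(comorbnet)

cohort <- generate_cohort(copd_cohort_spec(seed = 7))
fit <- multimorbidity_networks(cohort, n_resamples = 1000, seed = 7,
                               keep_p = FALSE, verbose = FALSE)
summary(fit)
#> Stratified multimorbidity networks: 14 diseases retained, 91 candidate pairs
#>   CB-  n=820   density 0.0914  edges 55
#>   CB+  n=906   density 0.0578  edges 28
#>   Ex-  n=1296  density 0.0763  edges 10
#>   Ex+  n=430   density 0.0680  edges 16
#>
#> CB: density CB− = 0.0914 vs CB+ = 0.0578 (difference 0.0335)
#>   nodes with non-overlapping connectivity intervals: 1/14
#>
#> Ex: density Ex− = 0.0763 vs Ex+ = 0.0680 (difference 0.0083)
#>   nodes with non-overlapping connectivity intervals: 0/14
```

Two rare candidates fall below the 3.5 % retention threshold, leaving 14
diseases and 91 candidate pairs. The CB− network is denser than CB+ (mean φ
0.091 vs 0.058) with many more validated edges, while the Ex strata differ
only marginally — the per-node connectivity intervals overlap for every
disease. Individual pairs work the same way at the console:

```r
t <- pair_counts(cohort, "AHT", "HF")
phi_coefficient(t)
#> [1] 0.04082069
relative_risk(t)
#>       rr    lower    upper
#> 1.111367 0.968398 1.275444
prevalence_ci(235, 1726)   # Clopper-Pearson
#>  estimate     lower     upper
#> 0.1361530 0.1203129 0.1532409
```

`plot(fit)` draws the four networks (node size ∝ prevalence, edge width ∝
φ²); `export_network()` writes GraphML, edge-list CSV or schema-validated
JSON; `report_json(fit)` serialises the whole run deterministically.

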