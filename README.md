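# strokemr

Two-sample Mendelian randomization (MR) from GWAS summary statistics, built
around a complete, reproducible analysis of whether four stroke phenotypes
— any stroke (AS), any ischemic stroke (AIS), large-artery atherosclerotic
stroke (LAS), and cardio-embolic stroke (CES) — causally influence
Alzheimer's disease (AD) risk.

Two-sample MR uses genetic variants as instrumental variables: for each
instrument *j* with exposure association β̂<sub>Xj</sub> (SE σ<sub>Xj</sub>)
and outcome association β̂<sub>Yj</sub> (SE σ<sub>Yj</sub>) estimated in
separate cohorts, the Wald ratio θ̂<sub>j</sub> = β̂<sub>Yj</sub>/β̂<sub>Xj</sub>
estimates the causal effect. The package implements:

* **summary IO** — validated summary-statistic datasets, delimited-table
  reading/writing with configurable column schemas, odds-ratio and
  confidence-interval conversions (β = ln OR,
  SE = (ln CI<sub>u</sub> − ln CI<sub>l</sub>)/(2·1.96)), and the published
  stroke/AD instrument tables as packaged fixtures;
* **harmonization** — allele alignment (orientation, strand complement,
  palindromic ambiguity windows), declared LD-proxy substitution, and the
  fixed instrument-selection pipeline (exposure p < 5×10⁻⁸ strict, outcome
  p ≥ 0.05, explicit exclusions), every drop logged with its rule;
* **estimators** — IVW with weights (β̂<sub>Xj</sub>/σ<sub>Yj</sub>)² under
  fixed / multiplicative random-effects / J-dependent default variance
  models, percentile-interpolation weighted median with seeded
  parametric-bootstrap SE, MR-Egger regression with pleiotropy intercept,
  and Cochran's Q;
* **Steiger directionality** — r² from p and n, the Fisher-z directionality
  test, and instrument filtering;
* **sensitivity** — leave-one-out re-estimation, single-SNP Wald scans, and
  a Bonferroni-corrected pleiotropy screen over SNP × trait p-value
  matrices;
* **synthetic data** — a seeded generator of paired exposure/outcome
  summary statistics with known causal effect and configurable pleiotropy,
  plus Monte-Carlo calibration (type-I error, bias, power) of every
  estimator;
* **study runner** — configuration objects, an end-to-end `run_analysis()`,
  a `run_all_fixture_analyses()` suite that checks every published number
  at printed precision, and a CLI (`inst/cli/mr_study.R`) with
  `run` / `reproduce` / `simulate` verbs.

## Worked example

```r
library(strokemr)
rep <- run_analysis(analysis_config("AS", "AS", seed = 42))
print(rep)
```

```
MR analysis 'AS': 11 instrument(s), 0 dropped
 analysis          method n_snps    beta     se pvalue     or ci_lower ci_upper       q q_df q_pvalue
       AS             ivw     11 -0.0388 0.1216 0.7497 0.9619   0.7579   1.2209 15.8637   10   0.1036
       AS weighted_median     11 -0.1562 0.1460 0.2846 0.8554   0.6425   1.1387      NA   NA       NA
       AS           egger     11 -1.3122 0.7939 0.0984 0.2692   0.0568   1.2761 12.2806    9   0.1979
       AS egger_intercept     11  0.0711 0.0439 0.1051 1.0737   0.9852   1.1702      NA   NA       NA
```

All 11 genome-wide-significant AS instruments survive selection against the
AD dataset. The IVW causal estimate is β = −0.039 (OR 0.962, p = 0.750):
no evidence that liability to stroke raises AD risk. The weighted median
(−0.156, p ≈ 0.28) and the Egger slope (−1.312, p = 0.098) agree in
direction, and the Egger intercept (0.071, p = 0.105) shows no significant
average directional pleiotropy. Cochran's Q = 15.8637 on 10 df (p = 0.1036)
indicates acceptable heterogeneity across instruments; because J ≥ 4 the
default variance model applied the multiplicative random-effects scaling.
These match the published values for this analysis digit for digit, as do
the AIS/LAS/CES arms, the Steiger-filtered re-runs, the leave-one-out
table, and the single-SNP scans:

```r
suite <- run_all_fixture_analyses(seed = 1)
all(suite$comparison$pass)
#> [1] TRUE
```

Synthetic-data calibration with known truth:

```r
cfg <- scenario_config(n_snps = 50, theta = 0, seed = 7)
evaluate_calibration(cfg, n_reps = 200, methods = "ivw")$summary
#>   method rejection_rate   mean_bias empirical_se truth
#> 1    ivw           0.03 0.003085181     0.051482     0
```

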