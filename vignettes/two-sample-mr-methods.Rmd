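---
title: "Methods: two-sample Mendelian randomization in strokemr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in strokemr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemr)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone. For each genetic
instrument $j$ we observe the per-allele association with the exposure,
$\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$, and with the outcome,
$\hat\beta_{Yj}$ with standard error $\sigma_{Yj}$, estimated in
non-overlapping cohorts. Under the instrumental-variable assumptions
(relevance, independence from confounders, and exclusion restriction) every
valid instrument identifies the same causal effect $\theta$ through its
Wald ratio

$$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj},
  \qquad \mathrm{se}(\hat\theta_j) \approx \sigma_{Yj}/|\hat\beta_{Xj}|,$$

where the standard error is the first-order delta approximation that
ignores exposure-side sampling error (the no-measurement-error, "NOME",
convention; exposure instruments here reach genome-wide significance, so
the neglected term is small).

`strokemr` ships the published instrument tables for four stroke phenotypes
— any stroke (AS), any ischemic stroke (AIS), large-artery atherosclerotic
stroke (LAS), and cardio-embolic stroke (CES), 521,612 subjects — paired
with Alzheimer's disease (AD) associations from a 54,162-subject
case-control meta-analysis, as `load_fixture()` datasets, and reproduces
the full analysis between them. Everything also runs on user-supplied
tables via `read_summary_table()`.

## Estimators

**IVW.** The inverse-variance weighted estimate pools the ratios with
weights $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$:
$\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$, equivalent to
zero-intercept weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with weights $\sigma_{Yj}^{-2}$ (the test suite asserts
this equivalence to 1e-10 against an independent `lm()` oracle).
Heterogeneity is Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ on $J-1$ degrees of freedom.

Two variance models are provided. The *fixed-effect* standard error is
$(\sum_j w_j)^{-1/2}$; the *multiplicative random-effects* model inflates
it by $\max\{1, \sqrt{Q/(J-1)}\}$, flooring under-dispersion at 1. The
`"default"` model applies fixed effects below four instruments and the
floored random-effects model from four instruments up. This single rule
reproduces all four published primary IVW p-values at once: the AS arm
(J = 11, overdispersed) needs the random scaling, the AIS arm (J = 9,
underdispersed) needs the floor, and the two J = 3 arms need fixed
effects. P-values are two-sided normal.

**Weighted median.** Ratios are sorted ascending with normalized weights
$w'_j$; cumulative percentiles are $p_j = (S_j - w'_j/2)/S_J$ with $S_j$
the running weight sum, and the estimate interpolates $\hat\theta$
linearly at $p = 1/2$ (an exact hit returns that ratio; ties in
$\hat\theta_j$ are broken by a stable sort on rsID for determinism). The
estimator is consistent while valid instruments carry more than half the
weight — the simulation tests demonstrate both the robustness below 50%
invalid weight and the breakdown above it. The point estimate is
deterministic. Its standard error has no closed form; following the
published estimator's procedure we use a parametric bootstrap (default
1000 resamples) drawing both beta vectors from normals centred on the
observations, with a mandatory seed, and a two-sided normal p-value. Two
weight conventions are available: `"first_order"`
($w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$, the default) and `"delta"`, the
full delta-method ratio variance
$1/(\sigma_{Yj}^2/\hat\beta_{Xj}^2 +
\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4)$. The packaged primary
analyses reproduce under the first convention and the Steiger-arm runs
under the second — the two MR software packages used in the source
analyses differ exactly this way.

**MR-Egger.** Weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ *with* intercept, weights $\sigma_{Yj}^{-2}$, after
reorienting every instrument so exposure betas are non-negative (Egger
regression is not orientation-invariant; the packaged tables already
satisfy the convention, so they are unaffected). The slope is the
pleiotropy-adjusted causal estimate under the InSIDE assumption; the
intercept estimates average directional pleiotropy. Residual
heterogeneity $Q'$ on $J-2$ df inflates both coefficient standard errors
by $\max\{1, \sqrt{Q'/(J-2)}\}$. Normal p-values by default; `t_dist =
TRUE` switches to $t_{J-2}$ tails.

### Why two p-value conventions coexist

The source analyses were run through two different MR packages, and their
printed p-values are not mutually consistent under any single convention:
the primary arms require normal tails with the J-dependent default
variance model, while the Steiger-arm re-runs require the floored
random-effects model at *any* J (their J = 3 LAS IVW p is 0.6320, not the
fixed-effect 0.568) and $t_{J-2}$ Egger tails. Rather than pick one,
`strokemr` exposes `variance_model`, `egger_t_dist` and `ratio_weights`
and documents which combination corresponds to which software;
`run_all_fixture_analyses()` uses the first convention for the primary
arms and the second for the Steiger arms, and reproduces every printed
beta, Q, and deterministic p-value at printed precision.

## Harmonization and instrument selection

`select_instruments()` applies a fixed, fully logged pipeline: (1) keep
exposure SNPs with $p < 5\times10^{-8}$ (strict — a SNP at
$6.44\times10^{-8}$ is excluded); (2) substitute declared LD proxies for
instruments missing from the outcome (statistics taken verbatim; proxy
discovery against reference panels is out of scope); (3) drop instruments
absent from the outcome; (4) drop instruments nominally associated with
the outcome ($p < 0.05$) — such a SNP is a plausible direct risk factor,
violating exclusion; (5) drop explicit exclusions; (6) optionally drop
ambiguous palindromic SNPs; (7) align alleles. Alignment passes effects
through when orientations match, negates the outcome beta (and reflects
its frequency) when the allele pair is swapped, and resolves strand flips
by complementing — for non-palindromic pairs only, since a complemented
A/T or C/G pair is indistinguishable from a swap.

Palindromic handling deserves a note. A palindromic SNP can only be
oriented through its allele frequency, and only when that frequency is far
from 0.5. The ambiguity window defaults to [0.42, 0.58], and a palindromic
SNP whose frequency is *missing* on either side is treated as ambiguous.
That choice is what reproduces the published Steiger-arm instrument set:
the two palindromic AS instruments were removed there as "intermediate
frequency" even though their exposure-side frequencies (0.34, 0.60) fall
outside any conventional window — the outcome dataset simply carries no
frequency column, so the ambiguity cannot be resolved. An explicit
palindromic-exclusion list is honoured as well. For the primary arms
palindromic dropping is off (both SNPs were retained there); Steiger-mode
runs switch it on.

## Steiger directionality filtering

A valid instrument should explain more variance in the exposure than in
the outcome; the reverse pattern suggests reverse causation. From each
SNP's association p-value and study sample size, the implied variance
explained is $r^2 = t^2/(t^2 + n - 2)$ with $t^2$ the upper chi-square(1)
quantile at $p$. The directionality test Fisher-z-transforms the implied
correlations (positive root; effect direction is irrelevant to a variance
comparison) and compares them with
$z = (\mathrm{atanh}\,r_X - \mathrm{atanh}\,r_Y)\big/
\sqrt{1/(n_X-3) + 1/(n_Y-3)}$. `steiger_filter()` keeps instruments with
$r^2_X > r^2_Y$ and logs every per-SNP result. Per-SNP sample sizes are
not published for these cohorts, so the dataset totals (521,612 and
54,162) are used throughout; total n rather than effective case-control n
$4/(1/n_{\mathrm{cases}} + 1/n_{\mathrm{controls}})$ is the default
because the source analysis gives no indication of using the latter, and
the choice is recorded in the run log. On the packaged data the filter
removes nothing beyond the palindromic pair — every exposure p is at most
$3.4\times10^{-8}$ against outcome p of 0.07 or larger, so the
directionality is never in doubt; the filter earns its keep on data where
it is.

## Sensitivity analyses

`leave_one_out()` re-runs IVW, weighted median, and Egger after excluding
each instrument in turn (J >= 4 so Egger stays estimable), reseeding the
bootstrap deterministically per row. `single_snp_scan()` reports each
instrument's Wald ratio. `screen_pleiotropy()` implements the staged
confounder screen: a SNP x trait matrix of association p-values (built
from database lookups outside this package) is thresholded at the
Bonferroni-corrected level $\alpha/J$ — 0.05/11 = 0.004545 for the
11-instrument arm — with absent lookups never flagged. The Egger intercept
(stage 4 of the published procedure) is deliberately not duplicated in the
screen; it is read from the estimator output, keeping one source of truth.

## The synthetic-data generator

`simulate_pair()` emits paired summary datasets from a stated world:
true exposure effects $\gamma_j \sim N(0.06, 0.015^2)$ truncated at
$|\gamma_j| \ge 0.02$ (weak-instrument degeneracy of the Wald ratio is
not the phenomenon under study), per-SNP standard errors uniform on
0.008–0.016 (exposure) and 0.015–0.035 (outcome), and outcome betas
$N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ where the direct effects
$\alpha_j$ are zero for valid instruments, mean-zero for balanced
pleiotropy, and mean `alpha_mean` for directional pleiotropy. The defaults
mirror the scale of the packaged stroke/AD tables: genome-wide-significant
instruments from a ~5e5-subject exposure GWAS against an outcome GWAS a
tenth that size. By default the observed exposure beta *is* $\gamma_j$
(NOME, matching the estimators); `exposure_noise = TRUE` adds
$N(0, \sigma_{Xj}^2)$ sampling error for robustness experiments. Either
convention is defensible for a generator; the no-noise default was chosen
because it matches the estimators' working assumption, and the switch
preserves the alternative. Alleles are drawn
non-palindromic and pre-aligned, and frequencies are uniform on
0.05–0.95 — the generator does not emulate strand ambiguity, LD between
instruments, sample overlap between the two GWAS, or case-control
ascertainment, so a green calibration test establishes correctness of the
estimators under clean conditions, not robustness to those artefacts.

`evaluate_calibration()` wraps the replicate loop (replicate $r$ reseeds
at `seed + r`) and reports rejection rate, mean bias, and empirical SE per
method. Under the null the default-model IVW rejects at ~4% — slightly
conservative, as expected from flooring the dispersion estimate — which
sits inside the binomial acceptance band around the nominal 5%.

## Numerical choices and degenerate inputs

* P-values are reported on (0, 1]; simulated p-values are floored at
  1e-300, and the loose beta/se-consistency check on input tables (warn
  past 3 decades on log10 p; printed meta-analysis p-values legitimately
  differ from plain Wald tails by one to two decades) exempts floored
  values.
* Scientific notation is parsed case-insensitively with Unicode dashes
  (en dash, minus) normalized, since published tables mix glyphs.
* `se_from_ci()` uses the printed constant 2 x 1.96, not
  `2 * qnorm(0.975)`; the two differ in the fifth decimal.
* A single instrument reduces IVW to the Wald ratio (no heterogeneity
  reported); weighted median and Egger require J >= 3; leave-one-out
  requires J >= 4; an empty selection raises a typed `no_instruments`
  error.
* Weighted-median ties are resolved by stable sort on rsID; duplicated
  cumulative percentiles (possible with zero-weight degeneracies) are
  perturbed by 1e-12 before interpolation.
* All bootstraps and simulations run under `with_seed()`, which restores
  the caller's RNG state, so library calls never perturb a session's
  random stream.

## Reverse-direction analyses

The AD-to-stroke reverse analysis is supported as configuration, not as a
fixture: its instrument table lives in supplementary material that cannot
be transcribed digit-for-digit here, so the package ships only the column
template (`inst/extdata/reverse_mr_template.tsv`) and the documented
proxy/OR-conversion conventions (`beta_from_or()`, `se_from_ci()`,
`proxy_map`). Users who transcribe the table run it through
`run_analysis()` like any other pair of files.

## Known limitations

* No LD clumping or reference-panel queries: instrument independence is
  taken from the declared selection (distinct loci), and proxies must be
  declared, not discovered.
* No mode-based estimators, MR-PRESSO, or multivariable MR.
* Dataset-level sample sizes stand in for per-SNP n in Steiger filtering.
* The weighted-median p-value rests on a bootstrap-normal approximation;
  only its point estimate is treated as exact in regression tests.
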