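---
title: "Methods: two-sample Mendelian randomization with mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The problem and the model

mrkit implements a two-sample summary-statistic Mendelian randomization
(MR) workflow, built around the application that motivated it: does
genetically predicted educational attainment (EduYears, standardized so
1 SD is about 3.6 years of schooling) causally affect ischemic stroke
risk? Exposure associations come from an education GWAS (405,072
individuals); outcome associations from a stroke case-control GWAS
(29,633 individuals, case fraction 0.347822). Only per-SNP summary
statistics are needed.

For instrument $j$, let $\hat\gamma_j$ (SE $\sigma_{Xj}$) be the per-SD
exposure effect and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) the log-odds
outcome effect, harmonized to the same effect allele. The Wald ratio is
$\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order SE
$\sigma_{Yj}/|\hat\gamma_j|$ and weight
$w_j = (\hat\gamma_j/\sigma_{Yj})^2$. Valid instruments require
relevance, independence from confounders, and the exclusion restriction;
each estimator relaxes these differently:

* **IVW**: $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, identical to
  weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the origin
  with weights $\sigma_{Yj}^{-2}$ (both routes are computed and compared
  in the tests). Unbiased only when *all* instruments are valid.
* **Weighted median**: the 50th weighted percentile of the ordered
  ratios, consistent when valid instruments carry at least half the
  weight.
* **MR-Egger**: weighted regression *with* intercept after orienting
  every instrument so $\hat\gamma_j > 0$; the intercept estimates mean
  directional pleiotropy, the slope the causal effect under InSIDE
  (pleiotropy independent of instrument strength).

Estimates are reported on both the log-odds and the odds-ratio scale per
SD of schooling.

## Pipeline stages and their parameters

`run_pipeline()` executes, in order:

1. **Genome-wide filter** (`gw_threshold`, default $5\times10^{-8}$):
   the conventional relevance screen.
2. **Harmonization** (`palindromic_eaf_window`, default 0.08): matching
   is by rsID only (the instrument table carries no coordinates).
   Identical allele pairs are kept; swapped pairs flip the outcome beta;
   pairs matching only after strand complement are aligned the same way;
   palindromic SNPs (A/T, C/G) whose exposure EAF is within 0.08 of 0.5
   are dropped as strand-ambiguous — outside that window alignment is by
   allele label under a same-strand assumption. A pair sharing no
   alleles is dropped with an explicit `allele_mismatch` reason, never
   silently kept. The source analysis never states its harmonization
   rule, so this policy is the package's own, following standard
   two-sample MR practice; every drop is logged in the provenance.
   The exposure EAF drives all frequency computations (missing outcome
   EAF is tolerated), and betas are used as published (per SD); the
   "3.6 years" is a reporting label, not a rescaling.
3. **Stage-1 confounder screen** (`alpha` = 0.05): a SNP associated with
   any confounder trait at $p < \alpha/m$ is excluded. $m$ is the
   *pre-screen instrument count* (162 in the motivating analysis, giving
   the threshold $0.05/162 = 3.09\times10^{-4}$), not the SNP-by-trait
   test count — the more conservative per-trait reading matching the
   published threshold. A SNP absent from a confounder dataset cannot be
   tested and is logged as untested, never excluded without evidence.
4. **Stage-2 diagnostics**: Cochran's Q with $I^2$ and a
   Higgins–Thompson test-based CI (back-transformed from a normal
   interval for $\ln H$, $H=\sqrt{Q/df}$, truncated to [0,100]%); the
   MR-Egger intercept test; MR-PRESSO (`n_sim` = 1000,
   `outlier_alpha` = 0.05, Bonferroni-corrected over $J$).
5. **Estimation**: IVW (fixed and multiplicative random effects — the
   point estimate is identical, and the random-effects SE, never smaller
   than fixed, is the headline default since the source does not state
   its choice), weighted median (`n_boot` = 2000), MR-Egger.
6. **Instrument strength and power**: $R^2 = \sum_i \beta_i^2\,2\,
   \mathrm{MAF}_i(1-\mathrm{MAF}_i)/\mathrm{var}(X)$ with folded
   frequencies and $\mathrm{var}(X)=1$ for the standardized exposure;
   the F statistic in two conventions (below); analytic power for a
   binary outcome from the noncentrality parameter
   $\mathrm{NCP} = N R^2 K(1-K)\ln(\mathrm{OR})^2$ with the two-sided
   form $\Phi(\sqrt{\mathrm{NCP}}-z_{1-\alpha/2}) +
   \Phi(-\sqrt{\mathrm{NCP}}-z_{1-\alpha/2})$, so that power at OR = 1
   equals $\alpha$ exactly and power is symmetric in $\ln \mathrm{OR}$.

All thresholds surface in the config with these defaults; one master
seed drives a per-purpose sub-seed sequence (PRESSO, bootstrap) so
stages can be re-run independently, and identical config + seed gives a
byte-identical JSON report.

### Two F-statistic conventions

The published first-stage F (327.56) is inconsistent with the
multi-instrument formula $F = R^2(n-1-k)/((1-R^2)k)$ at the exposure
$n = 405{,}072$, but matches the single-regressor mRnd form
$F = R^2(n-2)/(1-R^2)$ evaluated at the *outcome* $n = 29{,}633$ with an
unrounded $R^2$ near 1.09%. Both conventions are implemented and tagged;
`mrnd` is the default for report parity.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` states a world matching the motivating analysis:
111 instruments, exposure $n$ 405,072, outcome $n$ 29,633 with case
fraction 0.347822, joint instrument $R^2$ 1.09%, per-SD exposure effects
in the 0.01–0.05 range (standard-normal draws rescaled so the true
$R^2$ is hit exactly). Standard errors follow the standardized-trait
approximations $\sigma_X = (2n_Xm(1-m))^{-1/2}$ and
$\sigma_Y = (2n_YK(1-K)m(1-m))^{-1/2}$, which makes the generator
self-consistent with the power module's NCP. Confounder p-values are
Uniform(0,1) except planted hits, whose z-scores are drawn from
$N(6,1)$ — a clearly detectable GWAS association, so the stage-1
screen's removal rate equals the analytic power of the per-trait test.

Directional pleiotropy is applied in the $\gamma>0$ oriented frame
(direct effects sign-aligned with the instrument's exposure effect).
Without this, random effect-allele coding would turn any fixed-mean
pleiotropy into balanced pleiotropy after MR-Egger's orientation step —
"directional" is only meaningful relative to an orientation.
`inside_violated` couples the direct effect to instrument strength,
breaking InSIDE.

Not emulated: linkage disequilibrium between instruments (the motivating
analysis treats its variants as independent), individual-level
genotypes, sample overlap between the two GWAS, allele-frequency
mismatch between cohorts, and strand errors. A green simulation test
therefore establishes correctness of the estimators under the stated
sampling model, not robustness to those artifacts.

## Numerical choices and edge cases

* Weighted-median interpolation: standardized cumulative weights
  $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum w_i$, linear interpolation at
  $s = 0.5$; boundary values are returned when $s_1 \ge 0.5$ or
  $s_J \le 0.5$; ties in $\theta_j$ are broken by rsID so output is
  deterministic.
* Egger collinearity (all oriented $\hat\gamma$ equal) is a hard error,
  as is a zero exposure beta in any ratio.
* Both Egger SEs and the random-effects IVW SE use the multiplicative
  inflation $\max(1, \sqrt{\mathrm{RSS}/(J-2)})$ (resp.
  $\sqrt{Q/(J-1)}$); p-values are two-sided normal, the summary-data MR
  convention with large $J$.
* MR-PRESSO residuals are taken against leave-one-out IVW slopes so an
  outlier cannot mask itself; the global and per-SNP p-values use the
  $(1+\#\{\cdot\})/(n_{sim}+1)$ form, so a Monte-Carlo p is never zero.
  The distortion test (reported only when outliers exist, as an explicit
  `has_outliers` flag rather than a magic value) compares the change in
  IVW estimate after removing the flagged SNPs with the change after
  removing equally many random SNPs in each simulated dataset — the
  reference implementation's convention, since the source names the
  method without detail.
* `detectable_or()` inverts the power function by bisection in
  $\ln\mathrm{OR}$ to $|\Delta\text{power}| < 10^{-8}$; the returned
  bounds are exact reciprocals because the NCP depends on
  $\ln(\mathrm{OR})^2$ only. The published bounds (0.71, 1.37) are
  asymmetric around 1, which a symmetric-NCP calculation cannot
  reproduce exactly; the package's bounds agree with an independent
  closed-form inversion and sit within ±0.02 of the published pair.
* The confounder threshold appears in the source once as
  $3.09\times10^{-4}$ and twice as $3.09\times10^{-3}$; since
  $0.05/162 = 3.09\times10^{-4}$, the former is used.

## Known calibration properties

Two behaviours of the standard methodology are worth stating because the
test suite measures them:

* **Weighted-median bootstrap is conservative under the null.** The SE
  is the SD of the estimate over parametric-bootstrap replicates drawn
  around the *observed* betas. When the true causal effect is zero and
  there is no pleiotropy, all spread in the observed Wald ratios is
  sampling noise, and re-drawing around observed values double-counts
  part of it. Measured null coverage of the nominal 95% CI in the
  study-scale regime is ~96–99% across simulation seeds (IVW and Egger
  sit at 94–96%). The acceptance test asserting 95% ± 3% for all three
  estimators is therefore left failing for the weighted median at its
  frozen seed rather than silently re-tuned; the underlying procedure is
  the field-standard one and is implemented as specified.
* **Median robustness is a small-noise property.** With 30% of
  instruments carrying large directional pleiotropy, the weighted median
  stays near the truth only when per-SNP Wald noise is well below the
  contamination shift. At the stroke-GWAS outcome size the per-SNP ratio
  noise (~1 on the $\theta$ scale) swamps a true effect of 0.2, so the
  robustness demonstration is run at outcome $n = 500{,}000$, where the
  weighted median's mean absolute bias is several-fold smaller than
  IVW's (both are recomputed by `scripts/acceptance.R`).

## Worked example

```{r, eval = FALSE}
library(mrkit)

tab1 <- load_table1_fixture()          # 162 education instruments
variance_explained(tab1)               # 0.01702 — within the 1.6–1.8% band

cfg <- simulation_config(seed = 7, confounder_traits = c(bmi = 0.2))
sim <- simulate_dataset(cfg)
report <- run_pipeline(list(
  exposure = sim$exposure, outcome = sim$outcome,
  confounders = sim$confounders, seed = 11,
  n_outcome = cfg$n_outcome, case_fraction = cfg$case_fraction))
report
```

## Limitations

The headline reproduction of the published odds ratios (IVW 0.54,
weighted median 0.49, MR-Egger 0.18) requires the per-SNP outcome and
confounder statistics from the source's supplementary files, which are
not redistributable here; the pipeline accepts them through the generic
TSV schema whenever the user supplies them, and the packaged fixture
covers the exposure side only. LD clumping, proxy lookup, Steiger
filtering, multivariable MR and mode-based estimators are out of scope.
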