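---
title: "Models and methods behind patox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

patox analyses longitudinal photoacoustic tomography (PAT) studies of tumor
treatment response. This vignette explains the models the package implements,
the assumptions behind them, what the synthetic-data generators do and do not
emulate, and the design decisions taken where more than one reasonable choice
existed.

## From multispectral stacks to oximetry records

A PAT acquisition yields, per imaging day and tumor, one 2-D reconstructed
slice at several wavelengths (`MultispectralStack`). Hemoglobin dominates
tissue absorption in the 700–900 nm window, so the per-pixel signal is modeled
as a linear mixture of the oxy- and deoxyhemoglobin extinction spectra,

$$ s(\lambda, x) \;=\; \Phi(\lambda, x)\,\big[\varepsilon_{HbO_2}(\lambda)\,
c_{HbO_2}(x) + \varepsilon_{Hb}(\lambda)\, c_{Hb}(x)\big] + \epsilon, $$

and `unmixPixels()` solves the per-pixel unconstrained least-squares problem
against the bundled extinction table, restricted to 700–900 nm by
`selectWavelengths()`. Key points:

* **The fluence $\Phi$ is not corrected.** Oxygenation derived this way is an
  *apparent* metric: it equals the true saturation only when the fluence is
  spectrally flat across the ROI. The phantom generator's
  `fluence = "exponential"` option attenuates the illumination with depth at a
  rate proportional to the background absorption spectrum (spectral
  coloring), and the test suite demonstrates the resulting bias; under
  constant fluence the noiseless round-trip is exact to numerical precision.
* **ROI-mean-then-ratio, not ratio-then-mean.** `computeOximetry()` defines
  SO2 as the ratio of ROI means, mean HbO2 / (mean HbO2 + mean Hb), matching
  the extraction order of standard PAT workflows; `so2Map()` provides
  per-pixel ratios for display only.
* **Clamping.** Unconstrained weights can go negative under noise. The
  default policy clamps negative ROI means to zero before ratios, confining
  SO2 to [0, 1]; a tumor THb that is non-positive after clamping flags the
  record invalid instead of silently reporting 0. Exact two-component
  nonnegative least squares is available via `nonnegative = TRUE`.
* **Reference normalization.** Total hemoglobin (THb = HbO2 + Hb, arbitrary
  units) is normalized by the same quantity in a reference vessel ROI
  (aorta/vena cava), removing global system drift; both SO2 and normalized
  THb are invariant to a global rescaling of the stack.
* **Extinction table.** The bundled CSV is a smooth synthetic table of
  literature magnitude (2 nm grid, 650–1100 nm), labelled synthetic in its
  filename and header. Phantom simulation and unmixing share it, a deliberate
  inverse crime: the round-trip tests validate the solver, not the spectra.

## Growth modeling and responder allocation

Tumor volumes are analysed on the cube-root scale, where power-law growth is
linear in time and the growth rate has units mm/day. Two classifiers assign
treated units (mice, or individual tumors) to responder/nonresponder classes:

1. **Threshold rule** (`thresholdClassify`): responder iff the OLS cube-root
   slope is strictly below 0.05 mm/day. A variant
   (`significanceClassify`) instead flags units falling below the one-sided
   95% lower confidence bound of the control mean slope; because that bound
   tightens toward the control mean as controls accumulate, its
   misclassification rate *increases* with control sample size
   (`evaluateClassifier()` exposes this curve). The fixed threshold is
   scale-dependent: re-expressing volumes in cm³ divides slopes by 10, so the
   cut must be rescaled with the units.
2. **Hard EM** (`emAllocate`): classification expectation-maximization over
   the joint linear mixed model
   $y_{ijt} = \beta_0 + \beta_1 t + \gamma_0\,r_i + \gamma_1\, r_i t +
   b_{0i} + b_{1i} t + u_{ij} + \epsilon_{ijt}$
   on cube-root volumes, with mouse random intercept and slope, tumor random
   intercept, and $r_i$ the responder indicator. Control units are fixed to
   the nonresponder class (the two are statistically indistinguishable in
   growth). The M-step maximizes the full ML likelihood given labels
   (`lme4::lmer`, ML rather than REML so objectives are comparable across
   label configurations); the E-step reassigns each treated unit to the class
   maximizing its exact marginal Gaussian likelihood under the current
   parameters, with ties going to nonresponder and units visited in
   ascending id order — which makes converged labels invariant to row
   permutations. At the mouse level units are independent, so the
   −2 log-likelihood objective is non-increasing and the iteration terminates
   at a label fixed point. At the tumor level the E-step evaluates each
   tumor's marginal likelihood ignoring the coupling to its sibling tumor
   through the shared mouse effects; monotonicity is then only approximate.
   An emptied responder class is a valid fixed point, not an error.

**Known limitation — spurious splits under a null cohort.** Hard EM maximizes
a likelihood that always improves when a slow-growing tail is split off, so
in a cohort with *no* true responders it will sometimes carve one out (and
never un-assign it: the marginal-likelihood E-step is absorbing around such a
split). `emAllocate` therefore reports `delta_bic`, the BIC margin of the
converged allocation over the single-class fit (penalty $2\log n$ for the two
class fixed effects), and `split_support = (delta_bic < 0)`. In simulations
with no responder subgroup, most spurious splits lack BIC support; in small
genuinely-mixed cohorts (6 treated mice) BIC is conservative and a true split
may also lack "support" — the flag is evidence to weigh, not a gate, and the
allocation itself is never altered by it.

The boundary-stress configuration (`boundaryStressConfig()`) — responder
mouse slopes Normal(0.03, 0.01), nonresponder/control slopes
Normal(0.08, 0.02), residual SD 0.05, weekly observations over 6 weeks, 6
treated + 8 control mice, 2 tumors each, half the treated arm responding —
realizes a small average growth-rate difference between classes. Under it the
EM classifier's pooled sensitivity exceeds 95% with specificity near 90%
(`scripts/acceptance.R` recomputes both); intuitively, with class-symmetric
slope spread the EM decision boundary sits near the midpoint of the class
means (~0.055), far from the responder mean in responder-SD units but only
~1.25 nonresponder-SDs below the nonresponder mean.

## Longitudinal mixed models

`fitLmm()` fits hierarchical linear mixed models with mice and
tumors-within-mice as random intercepts (REML by default, via `lme4`):

* **Growth**: cube-root volume ~ day × group (three analysis groups:
  control, nonresponder, responder).
* **Oximetry (piecewise)**: SO2 or normalized THb with a hinge design —
  intercept, one slope on day shared by every group, and per-group columns
  $\max(0, \text{day} - \text{knot})$. The shared pre-knot slope encodes
  "same trajectory for all groups early on"; the hinge keeps every group's
  mean trajectory continuous at the knot. The knot defaults to day 21
  (3 weeks from enrollment) and is a parameter; `compareModels()` (AIC/BIC)
  supports scanning it or comparing piecewise against single-slope fits
  (ML required when fixed effects differ).

Sensitivity variants mirror common robustness checks: mouse-level random
slopes (`random = "slope"`), tumor-level labels, and a heteroscedastic
residual model $\mathrm{SD}(day) = \sigma (day+1)^{\delta}$ — a simple
monotone one-parameter family — fitted with `nlme::lme` and `varPower`.
Inference on fixed effects is Wald with normal reference distribution
(`testSlopeChange()` for post-knot slope contrasts);
denominator-degrees-of-freedom corrections are deliberately out of scope, a
small-sample caveat that the type-I simulation in the test suite bounds at
the design sizes used. `predictGroupTrajectories()` returns population-mean
trajectories with delta-method 95% pointwise bounds and flags extrapolation
beyond the observed day range.

## Endpoint and planning statistics

* `ttestAuto()`: unpaired comparisons use Student's t unless a two-sided
  F-ratio pretest at α = 0.05 rejects equal variances, then Welch; paired
  comparisons bypass the pretest. Degenerate constant-and-equal groups return
  p = 1 by convention. No familywise adjustment is applied by default.
* `pearsonTest()`, `logrankTest()`: standard Pearson correlation and
  log-rank/Kaplan–Meier (via `survival`), for biomarker–histology
  correlations and survival comparisons.
* `mcPower()`: Monte Carlo power for the clustered two-group design. Tumor
  values decompose into a mouse effect (variance $\rho\sigma^2$) and
  tumor-level noise ($(1-\rho)\sigma^2$), inducing within-mouse correlation
  $\rho$; each replicate aggregates tumors to mouse means and applies the
  variance-pretest t rule. At $\rho = 0$ and one tumor per mouse this
  reproduces the closed-form two-sample power. With the endpoint oxygenation
  effect sizes (0.58 ± 0.03 vs 0.31 ± 0.07), $\rho = 0.3$ and 6 mice
  (12 tumors) per group, the detection probability at α = 0.05 exceeds 0.8
  by a wide margin (recomputed by `scripts/acceptance.R`).

## What the generators emulate — and what they do not

`simulateGrowthCohort()` draws cube-root-linear growth with independent
Gaussian random effects at the mouse and tumor level; enrollment is at
500 mm³ (intercept 500^(1/3) mm), observations weekly over 6 weeks, 8
control/11 treated mice with 2 tumors each, control and nonresponder slope
0.08 mm/day, responder slope 0.01, responder fraction 3/11 — a typical
antiangiogenic xenograft study arm. The responder count in the treated arm is
deterministic (`round(fraction × n)`), so classifier operating
characteristics are estimated on stable class sizes. Negative cube-root
values are floored at zero volume. Mouse-level slope SDs may be class
specific (the boundary-stress configuration needs responder 0.01 vs
nonresponder 0.02).

`simulateOximetryTrajectories()` draws the piecewise-linear SO2/THb mean
structure (baseline 0.45, +0.003/day pre-knot for all groups; post-knot
+0.003 control/nonresponder and −0.010 responder, reaching ≈0.58 vs ≈0.31 at
day 42) with mouse/tumor random intercepts; SO2 is clamped to [0, 1].
`simulateSurvival()` turns growth curves into endpoint times at the
sphere-equivalent volume of a 1.5 cm diameter, (4/3)π·7.5³ ≈ 1767 mm³,
interpolating crossings linearly on the cube-root scale and censoring at 180
days.

Real data differ in ways these generators do not attempt: measurement
dropout and attrition, non-Gaussian calliper error, drifting reference-vessel
physiology, vascular-structure image texture (phantom regions are piecewise
constant), 3-D tumor geometry and slice selection (the unmixing module takes
the caller's single largest-area slice), and group sizes unbalanced by
endpoint losses. Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not robustness to every artifact of real
acquisitions.

## Numerical choices and problem sizes

Cube-root/cubing round-trips are exact to 1e-12 relative; noiseless
constant-fluence phantom round-trips to better than 1e-8. EM convergence uses
a label fixed point or an objective change below 1e-6 within 30 iterations;
`lme4` fits in the EM loop disable derivative checks for speed and treat
singular fits as flagged boundary estimates, not errors. Likelihood
evaluations in the E-step use Cholesky factorizations of the exact per-unit
marginal covariance. Monte Carlo sizes follow the quantities they estimate:
2,500 replicates for power, 200 cohorts for classifier operating
characteristics, 100 replicates for CI coverage and transform-selection
checks, 400 for type-I error of the slope-change test; tests use fixed seeds
throughout.
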