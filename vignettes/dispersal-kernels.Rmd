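---
title: "Modelling wind dispersal of auto-gyrating fruit from wing morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wind dispersal of auto-gyrating fruit from wing morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyrokernels)
```

## The problem

Dipterocarp trees dominate South-East Asian lowland rain forests. Their
single-seeded fruits carry zero to five sepal-derived wings and auto-gyrate
(helicopter) when abscised, which slows descent and lets lateral wind carry
them away from the mother tree. How far they travel sets the template for
density-dependent survival, regeneration, and the resilience of fragmented
populations — yet measured dispersal kernels exist for very few species.

The premise of this package is that a single morphological index predicts
dispersal across the family: **inverse wing loading** (IWL), the ratio of a
fruit's "long" wing area (cm²) to its air-dried mass (g). More wing per gram
means more lift, slower descent, longer flight. Working with IWL instead of
classical wing loading (weight per wing area) makes zero a legitimate value
for wingless fruit rather than a division by zero, and orients the index so
that bigger means farther.

`gyrokernels` implements the full analysis chain around that idea:
morphometrics, a mixed model of release-experiment data, bootstrap
inference, simulated dispersal kernels over an IWL × wind grid, a ballistic
comparison model — and a synthetic release-experiment generator, because the
raw field data of the 13-species canopy-tower study the packaged reference
tables come from were never deposited.

## Morphometrics

Wing area follows a genus rule. Two-winged genera (*Dipterocarpus*, *Hopea*):
the summed length × width rectangles of both wings. *Shorea* (three long
wings, two short): the longest and shortest long wing are measured, their
summed rectangular area is multiplied by 1.5 for the unmeasured middle long
wing; short wings are ignored as contributing negligible lift. No planform
shape factor is applied — areas are deliberately crude rectangles, consistent
with the calibration data.

```{r}
compute_wing_area("shorea_five_winged", c(10, 8), c(3, 2.5))  # cm^2
compute_iwl(75, 3)                                            # cm^2/g
```

For comparison with the descent-rate literature, IWL converts to square-root
wing loading by treating mass as a weight: 1 g weighs 980665 millidynes
(standard gravity, 980.665 cm/s²), so WL = 980665 / IWL and the package
maintains the exact identity `iwl * wing_loading == 980665`. For wingless
fruit the conversion is flagged undefined (`NA`), not zero: wing loading
diverges as wing area vanishes, and propagating a fabricated 0 would poison
the ballistic comparison silently.

One caveat the package documents rather than resolves: published per-species
√WL values are averages of per-fruit conversions, not conversions of the
mean IWL (the transform is convex, so the two differ — 326.37 vs 324.93 for
the highest-mass species in the packaged table). Where published √WL values
exist they are used as inputs; otherwise the closed-form transform of mean
IWL is the fallback.

## The dispersal mixed model

Release experiments measure, per fruit: IWL, the maximum and mean wind speed
over its flight, and horizontal distance. The model is a Gaussian
random-intercept linear mixed model on the log scale,

$$\log d_{ij} = \beta_0 + \beta_1 \log(\mathrm{IWL}_{ij}+1)
  + \beta_2 \log(U_{ij}+1)
  + \beta_3 \log(\mathrm{IWL}_{ij}+1)\log(U_{ij}+1)
  + b_i + \varepsilon_{ij},$$

with species intercepts $b_i \sim N(0, \sigma_s^2)$ and residuals
$\varepsilon_{ij} \sim N(0, \sigma_e^2)$. The +1 offsets accommodate the
zeros (wingless fruit, calm releases); natural logarithms are used
throughout — the choice of base cancels out of every back-transformed
prediction, but fixing it makes coefficients reproducible. The interaction
regressor is the product of the two logged terms, the standard expansion of
a crossed formula. Maximum wind speed is the default covariate; the mean
wind over a flight is retained in the data schema so the AIC comparison
(`compare_wind_covariates()`, fitted by ML since the fixed effects differ)
can re-derive that choice. Residuals are homoscedastic; a
variance-increasing-with-mean alternative is deliberately out of scope, as
it does not improve on the homoscedastic fit for data of this kind.

### Fitting: profiled REML

`fit_lmm()` is self-contained and exact for this model class. For a fixed
variance ratio $\lambda = \sigma_s^2/\sigma_e^2$ the marginal correlation
matrix is $I + \lambda ZZ^\top$, block diagonal with an explicit inverse per
species ($I - \tfrac{\lambda}{1+\lambda n_j}\mathbf{1}\mathbf{1}^\top$), so
the GLS fixed effects and the profiled $\hat\sigma_e^2$ are closed form from
per-species sufficient statistics. What remains is a one-dimensional
maximisation of the profiled (RE)ML criterion over $\log\lambda \in
[-12, 12]$ (Brent search, tolerance 1e-10), with the boundary $\lambda = 0$
evaluated explicitly — important because for data with no between-species
signal the optimum genuinely sits on the boundary and the fit must collapse
to ordinary least squares exactly. The test suite verifies the whole path
against a deliberately naive dense-matrix maximisation over
$(\sigma_s, \sigma_e)$, and against lme4 on full-size data.

Nested random terms beyond species (mother tree, genus) are handled through
`variance_decomposition()`: any random term explaining less than 0.1% of
total variance is flagged droppable, which is the model-reduction rule that
leads to the species-only model the rest of the package assumes.

```{r}
sim <- generate_releases(default_generator_config(rng_seed = 1))
fit <- fit_lmm(sim$dataset)
fit
variance_decomposition(fit)
```

### Bootstrap inference

Wald intervals are unreliable for variance parameters and for small numbers
of groups, so inference is by parametric bootstrap (`bootstrap_lmm()`):
simulate fresh species intercepts and residuals from the fitted model, refit,
repeat B times (default B = 1000; per-replicate seeds derive deterministically
from one base seed). Intervals are plain percentile intervals (type-7
quantiles); the approximate two-sided p-value for a coefficient is the
tail-count rule $p = \max\{2\min(\#\{\theta^* \le 0\}, \#\{\theta^* \ge
0\})/B,\ 1/B\}$, capped at 1. The floor matters: a bootstrap cannot certify
a p-value below the resolution of its draw count, which is why well-behaved
coefficients at B = 1000 report p = 0.001, never 0. Refit failures are
counted and dropped rather than retried — transparent and unbiased within
the replicate budget.

## Dispersal kernels

Conditional on parameters and a (IWL, wind) condition, distance is
log-normal: location $\mu$ from the fixed effects, log-scale variance
$\sigma_e^2$, plus $\sigma_s^2$ when predicting for an unobserved species
(`include_species_effect = TRUE`, the default — for named, observed species
one may prefer the conditional kernel, and both are exposed because the
choice is genuinely open). `kernel_closed_form()` evaluates density, cdf and
quantiles analytically; `kernel_monte_carlo()` simulates (and converges to
the closed form, a Glivenko–Cantelli check in the tests);
`kernel_bands()` propagates bootstrap parameter uncertainty into pointwise
95% envelopes. `kernel_grid()` sweeps IWL 1–50 by wind 1–10 m/s, the range
covering three quarters of Bornean dipterocarps.

Numerical conventions, fixed for reproducibility: type-7 quantile
interpolation everywhere; the default density grid is 512 geometric points
from 0.05 m to 1.5× the 99.9% quantile; a zero-variance kernel degenerates
to a point mass with a step cdf. One property worth stating because it is
easy to misread from kernel plots: $q_{90}/q_{50} = \exp(1.2816\,s)$ is
constant in IWL — high-IWL species have *absolutely*, not relatively, longer
tails and wider bands.

```{r}
kernel_grid(reference_parameters(), iwl_values = c(1, 25, 50),
            wind_values = c(1.72, 5))
```

## The ballistic comparison

The classical mechanistic alternative: a fruit falls at terminal velocity
$V_t$ from height $H$ while a constant lateral wind $U$ carries it, so
$d = UH/V_t$, and for gyrating fruit $V_t = a + b\sqrt{\mathrm{WL}}$. The
regression coefficients behind the packaged comparison table were published
only as fitted values, so `calibrate_from_anchors()` recovers $(a, b)$ from
any two species' published √WL and ballistic distance (exact solve; least
squares for more anchors). Calibrating from the two extreme-√WL species
reproduces the other ten published ballistic distances to within 0.02 m,
which also validates the recovered line
($a \approx -0.2166$, $b \approx 0.007873$).

The ballistic model assumes the release-point wind acts over the whole fall
— defensible in open landscapes, wildly optimistic under a forest canopy
where wind decays rapidly with depth. Its predictions exceed the mixed-model
medians several-fold for every winged species; `comparison_table()` puts the
two side by side (wingless species get `NA` in the ballistic column, where
wing loading diverges).

## The synthetic generator

`default_generator_config()` encodes the reference study design: 13 species,
728 fruits with the published per-species counts, release height 30 m.
Per-fruit IWL is normal truncated at zero (redraw, not folding — folding
would inflate the mean for low-IWL species); the per-fruit SD is
reconstructed from published standard errors as SE·√n, the only consistent
reconstruction available. Mass is log-normal with the published mean as
median and a CV reconstructed the same way. Wing rectangles are back-solved
from drawn IWL and mass so the morphometrics round-trip is exact to 1e-9.
Maximum wind is gamma with mean 1.72 m/s truncated at 10.5 m/s; the shape
(1.2) is the one free choice, set once for a heavy right tail that produces
occasional releases near the recorded 10.5 m/s maximum in a 728-release
experiment while keeping most releases below ~2 m/s. Mean wind is the
maximum times a uniform (0.3, 1) fraction — generated although unused by the
default model, so covariate selection has a genuine competitor. Distances
come from the mixed model at the packaged estimates.

What the generator does *not* emulate: measurement error in distances,
temporal autocorrelation of wind, fruit entanglement in understory
vegetation (only recovered fruit are emitted), turbulence and updrafts, and
any secondary dispersal. Passing tests therefore demonstrate that the
estimation machinery is correct and calibrated for data that follow the
assumed model — not that the model captures every feature of real releases.

## What the checks do and do not reproduce

Simulation sizes were chosen to keep the full suite within a few minutes:
parameter recovery uses 500 replicate experiments at the full 728-fruit
design; interval coverage uses 50 replicates at B = 200; the type-I-error
check 200 replicates at B = 200; Monte-Carlo/closed-form agreement uses
10^5 draws.

Two documented non-reproductions remain, both traceable to the unavailable
raw data:

* **Species-SD bias.** Across 500 replicate experiments the mean REML
  estimate of $\sigma_s$ is ≈ 0.149 against a generating 0.154 — a −3%
  Jensen bias from reporting the square root of a variance estimated from
  only 13 species (the variance itself is recovered without bias; lme4
  returns the identical estimator). With Monte-Carlo standard errors of
  ~0.002 this is a detectable, real property of the design, not an
  implementation defect.
* **Published per-species medians.** The packaged table of per-species
  "mixed model" medians was produced from the authors' bootstrap over their
  raw data, plausibly conditioning on fitted species intercepts. The
  marginal closed-form back-transform `predict_median_distance()` lands
  within ±18% of it for 12 of 13 species but 36% high for *Shorea gibbosa*
  — the species whose empirical median sits farthest below its IWL-marginal
  prediction, exactly the signature of a negative fitted species intercept
  that cannot be reconstructed without the raw data. Both conventions
  (marginal point prediction, bootstrap quantiles) are exposed; the
  discrepancy is documented rather than papered over.

## Reproducible pipeline

`run_pipeline()` chains simulate → fit → bootstrap → kernels → ballistic
with explicit seeds per stochastic stage, writes every artifact as CSV/JSON,
and records MD5 digests in a manifest; identical configuration and seeds
give identical digests. Unknown configuration keys are rejected by name.
The packaged reference tables load through `load_fixtures()`, which verifies
their checksums.
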