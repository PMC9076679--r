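---
title: "Covariate-driven CTCRW models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-driven CTCRW models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crwlink)
```

## The movement model

crwlink fits a continuous-time correlated random walk (CTCRW) to
irregularly timed, error-prone telemetry. Per planar axis the velocity is
an Ornstein–Uhlenbeck process, `dv = -beta v dt + sigma dW`, and position
is integrated velocity. Two parameters carry the behavioural signal:

* **beta** (h⁻¹): the decay rate of velocity autocorrelation. We report it
  as persistence `p = 3 / beta`, roughly the time separation at which
  locations and speeds decorrelate. Small beta (large p) is directed
  transit; large beta is tortuous movement.
* **sigma** (km h^-3/2): the diffusion scale of the velocity process; the
  stationary velocity standard deviation is `sigma / sqrt(2 beta)`.

Slow *and* unpersistent movement — the lowest quartiles of both `p_t` and
`sigma_t` — is the proxy for area-restricted search (ARS), the behaviour
associated with foraging.

Both parameters vary along the track through log-linear links in
standardized covariates, with optional group-deviation intercepts and
slopes (`G = 1` for mothers under sex grouping, or for the second tagging
period under period grouping):

```
log sigma_t = (A0 + a0 G) + (A1 + a1 G) X_1t + ... + (An + an G) X_nt
log beta_t  = (B0 + b0 G) + (B1 + b1 G) X_1t + ... + (Bn + bn G) X_nt
```

The formulation in which `log sigma_t` and `log beta_t` are latent
Gaussian variables centred on these linear predictors, with standard
deviations eps1 = eps2 fixed at 0.001, is implemented as its
deterministic-link limit: at that scale the latent spread is orders of
magnitude below the sampling uncertainty of any coefficient, so an
integrated likelihood is numerically identical to the plug-in one. The
latent perturbation is available on the simulation side
(`linear_predictors(..., latent_sd = 0.001)`) for completeness; a separate
Laplace-integrated fitting path would be indistinguishable dead code, so
none is provided.

Parameters are piecewise constant per inter-fix interval and anchored at
the interval's **starting** fix — the causal choice: behaviour over the
next interval responds to conditions where the animal is now.

## Likelihood, filtering, and numerics

Conditional on the per-interval `(sigma_i, beta_i)`, the model is
linear-Gaussian, and the exact transition of the `(position, velocity)`
state over an interval of length `delta` has closed-form moments
(`transition_moments()`); the marginal likelihood of the observed
locations follows from a Kalman filter over both axes independently
(`ctcrw_loglik()`, with the inner recursion in C++). Numerical choices:

* For `beta * delta < 1e-4` the closed forms cancel catastrophically and a
  series expansion (relative error below ~1e-12 at the switch point) is
  used instead.
* The initial state is diffuse in position — mean at the first observed
  location, variance 1e6 km², which makes the likelihood exactly
  translation invariant — with the stationary velocity prior of the first
  interval.
* Observation error is independent per axis, from the Argos error-ellipse
  decomposition (`ellipse_to_sd()`, a 1-sigma axis-splitting convention
  with a configurable scale for other conventions) or, for tags without
  ellipses, drawn from per-class gamma regressions of SD on latitude with
  log link; imputation is seeded per animal from a master seed.
* The linear predictors are clamped at ±25 with a quadratic penalty on the
  excess: the optimizer keeps gradient information without ever
  evaluating `exp()` in overflow territory.

Two independent oracles guard the engine in the test suite: a brute-force
joint-Gaussian likelihood built by composing transition moments (agreement
to 1e-8 on all tracks of up to 12 fixes), and an Euler–Maruyama
integration of the SDE pair (dt = 1e-3 h, 1e5 replicates, agreement within
3 Monte-Carlo SEs; at that step size the O(dt) discretization bias is an
order of magnitude below the Monte-Carlo noise).

Fitting is quasi-Newton (`nlminb`) on the pooled negative log-likelihood,
started from method-of-moments intercepts (empirical velocity variance and
lag-one velocity autocorrelation at the median gap) with zero slopes.
Standard errors come from the inverse numerical Hessian. A fit is flagged
converged when the optimizer reports success **and** the infinity-norm
gradient of the per-fix mean log-likelihood is below 1e-4 — the per-fix
scaling keeps the criterion meaningful across fleet sizes, and the
threshold sits safely above finite-difference noise for fleets of ~1e3–1e5
fixes. I-models drop covariates that are invariant for that animal (a
whale that never met sea ice carries no information about an ice
coefficient) with a warning.

Model selection enumerates all covariate subsets that avoid forbidden
pairs — pairs with pooled Pearson `|r| >= 0.5` and `p < 0.01`, the screen
that makes SST, CHL and DSB mutually exclusive on realistic fields — and
ranks them by `AIC = 2k - 2 logLik`, where `k` counts every estimated link
coefficient. Ties sort by model name for reproducibility.

## Data handling choices

* **Projection**: spherical azimuthal equidistant centred at (40°W, 45°S),
  km units; distance distortion is below 0.5% across the 15–65°S span of
  the migration corridor. Configurable.
* **Duplicate fixes**: same animal and timestamp keep the better Argos
  class (3 > 2 > 1 > 0 > A > B), then the first occurrence.
* **Speed filter**: fixes implying speeds above 5 m/s from the previous
  retained fix are removed one at a time, recomputing after each removal;
  the first fix is never removed. Only speed is checked (no turning-angle
  test).
* **Censoring**: fixes before the first exit from the continental-shelf
  polygon are dropped (breeding-ground residency is behaviourally
  indistinguishable from foraging ARS in location data); tracks that never
  reach 50°S are discarded, since their feeding behaviour was never
  observed. The shipped shelf polygon is a synthetic coarse proxy for the
  200 m isobath, adequate for simulated fleets.
* **Crossing dates** interpolate linearly in time between the fixes
  bracketing 50°S; durations are floored to whole days, matching how such
  tables are printed. Footer statistics use the sample (n-1) SD.
* **Ice binaries**: daily ice fractions for August (ICE08) and October
  (ICE10) of each animal's tagging year are reduced to presence on any of
  ten evenly spaced days — days 1, 4, ..., 28, the arithmetic sequence
  that fits ten samples into 28–31 days. Presence means fraction > 0
  (configurable). Sampling is at the fix location. The pipeline collapses
  the sampled days into a per-cell presence grid first; bilinear sampling
  of that grid is positive exactly when the day-by-day rule fires, and
  costs one lookup instead of ten.
* **Standardization** is pooled over all retained fixes of all animals, so
  individually fitted and pooled coefficients share one scale (and
  I-models reuse the pooled scaling rather than re-centring per animal).
  Ice binaries enter unstandardized, which keeps the ice-effect ratio
  formulas `exp(-(A_ice + a_ice G))` interpretable.
* **CHL gaps** (the only covariate with missing coverage) are
  forward-filled per animal; leading gaps take the first available value.
* **Group coding**: the reference group (G = 0) is males+ under sex
  grouping and the first tagging period under period grouping — the coding
  under which the published ratio `exp(-A5) = 1.08` belongs to males+.

## Behavioural and spatial summaries

Quartile classes for `p_t` and `sigma_t` are pooled across animals
(per-animal quartiles are available via precomputed breaks); ties fall to
the lower class, and degenerate all-equal input is all-Q1. The marginal
ARS flags (lowest quartile of each variable) are the default summary, with
the joint flag provided additionally. Speeds come from RTS-smoothed
velocities. The 95% minimum convex polygon drops the 5% of fixes farthest
from the planar centroid before taking the hull — the standard home-range
convention; the published MCP areas depend on unstated projection and
trimming details and are treated as real-data references, not targets.
Rank-sum comparisons use `stats::wilcox.test` (exact for small untied
samples, tie-corrected normal approximation otherwise).

Spatial prediction evaluates a fitted pooled model over covariate rasters
on a regular grid: raw covariates standardized with the *training* spec,
`sigma = exp(mu1)`, `p = 3 / exp(mu2)` per cell and group, multi-year
means and CVs (sample SD over mean) across years, quartile bins of the
mean fields, and the joint lowest-quartile mask. Cells outside the
training covariate range are flagged as extrapolation rather than masked,
since predictions deliberately cover areas the animals never visited.

## What the synthetic data emulate — and what they do not

`gen_covariate_fields()` builds analytic fields with smoothed sinusoidal
noise: SST linear in latitude, zero-mean SSTA patches, a depth ramp with a
mid-latitude ridge, sign-structured wind-stress curl, chlorophyll
constructed to correlate with SST above the screening threshold (so the
forbidden-pair rule is exercised), a masked chlorophyll longitude band (so
forward-filling is exercised), daily ice layers south of a wiggly,
year-varying boundary, and a zonal front polyline. `sim_fleet()` then
advances each animal with the exact CTCRW transition, reading covariates
at the current true position, and corrupts positions with
Argos-class-mixture ellipse errors; older-period tags can withhold their
ellipses so the gamma-imputation path runs.

The default migratory configuration echoes the published fleet: 22
retained whales (12 mothers, 10 males+ — the actual composition of the
tagged fleet), two tagging periods, ~1000 fixes per animal at a ~2 h
cadence, departure from the Brazilian shelf with ~5.5 km/h southward
initial velocity, and a link calibrated so that warm-water transit is
extremely persistent (beta ~ 3e-4 h⁻¹) while cold, ice-covered water
drives beta toward 0.1 h⁻¹ and lower sigma — producing Polar Front
crossings in roughly 25–85 days, a substantial fraction of animals that
never reach 50°S, and ice-zone exposure ranging from zero to ~70% of
fixes, the qualitative shape of the real deployment table. The regional
configuration (`migratory = FALSE`; 20 animals × 150 fixes at 3 h used
for the recovery experiments) scatters animals over the feeding grounds
under a compact SST + ICE08 link.

Limits worth keeping in mind: a mean-zero OU velocity has no taxis, so
directed migration is carried by initial velocity and extreme persistence
rather than by goal attraction — the synthetic fleet's speed profile is
somewhat slower than real migrating whales, and lateral wandering
occasionally walks a track out of the field (such tracks are truncated
and flagged). The fields are not statistically Southern Ocean-like (no
eddy spectrum, no seasonal cycle within a deployment), covariates are
sampled at true rather than observed positions when the generator emits
its design matrix, and Argos duty-cycling is reduced to a gamma gap
mixture. Passing recovery tests therefore demonstrates correctness of the
estimator under the model's own assumptions, not robustness to real-data
misspecification.

Problem sizes in the shipped tests were chosen to give each check power
while keeping a full run comfortable on one CPU: oracle comparisons on
tracks of 3–12 fixes, recovery on 20 replicate fleets of 20 × 150 fixes,
AIC selection on 20 replicate fleets of 8 × 80 fixes over a 3-covariate
pool, and Euler–Maruyama checks at 1e5 replicates.

## Known limitations

* No Bayesian or random-effects (partial pooling) machinery: the contrast
  is complete pooling vs independent individual fits, by design.
* No behavioural-state HMM; ARS is a quartile proxy, not a decoded state.
* The error model is Gaussian per axis; heavy-tailed Argos errors are
  handled only by the upstream speed filter.
* Raster support is a lightweight in-memory lon/lat grid with plain-text
  serialization — deliberately self-contained rather than a GDAL binding;
  anything that can be coerced to a matrix on a regular grid can be
  wrapped with `lonlat_grid()`.
* One printed reference value is knowingly irreproducible from its own
  table: the overall migratory-duration SD prints as 13.9 where the
  printed durations yield 11.6 (the tests assert the recomputed value);
  similarly the mothers' sigma ice ratio recomputes to 1.60 from the
  rounded coefficients where 1.61 is printed.
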