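---
title: "Segmented negative binomial models of seal occupancy on ice floes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented negative binomial models of seal occupancy on ice floes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floeseal)
```

## The model

Pack-ice seals haul out on free-floating ice floes, where they can be counted
in very-high-resolution satellite imagery. The number of seals on floe $i$ is
modelled as NB2,

$$y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\mathrm{Var}(y_i) = \mu_i + \mu_i^2/\theta,$$

with a log-linear mean that is *piecewise linear in floe area* $a_i$ (m$^2$):

$$\log \mu_i = \beta_0 + \beta_1 a_i + \delta_2\, h(a_i, \psi_1) +
  \delta_3\, h(a_i, \psi_2) + \beta_r r_i + \beta_s s_i + \beta_c d_i,$$

where $h(a, \psi) = \max(0, a - \psi)$ is the hinge basis, $r_i$ is
bathymetric roughness averaged in a 1000 m circle (m), $s_i$ sea-ice
concentration in a 750 m buffer (fraction in $[0,1]$), and $d_i$ distance to
the nearest penguin colony (m). The hinge coefficients $\delta_k$ are slope
*increments*: the slope of $\log\mu$ in area is $\beta_1$ below $\psi_1$,
$\beta_1 + \delta_2$ between the breakpoints, and
$\beta_1 + \delta_2 + \delta_3$ above $\psi_2$. This parameterization keeps
the predictor continuous in area by construction.

The package's reference parameter set (`seal_model()`) uses
$\beta_0 = -7.53$, $\beta_1 = 0.139$, $\delta_2 = -0.136$,
$\psi_1 = 49.84$, $\psi_2 = 481.32$, $\beta_r = 0.042$, $\beta_s = -0.72$,
$\beta_c = 6.19\times 10^{-7}$: seal numbers rise steeply with area up to
about 50 m$^2$, rise very slowly (slope $\approx 0.003$) up to about
480 m$^2$, and plateau beyond. Two of its values deserve comment:

* **Third-segment increment $\delta_3 = -0.003$.** The derived slope above
  $\psi_2$ is then $\approx 0$, i.e. a plateau. The alternative reading of a
  *positive* 0.003 slope continuing past $\psi_2$ is untenable: at
  5000 m$^2$ it implies $\log\mu \approx 14$, millions of seals on one floe.
  A plateau is also what the estimated occupancy pattern describes
  qualitatively (counts level off on the largest floes).
* **Dispersion $\theta = 0.5$.** No dispersion estimate accompanies the
  reference coefficients; $0.5$ encodes the strong overdispersion evident in
  group sizes from 1 up to the observed tens on occupied floes while most
  floes hold none. It is a documented stand-in and configurable.

## Breakpoint estimation

`segnb()` estimates $(\beta, \delta, \psi, \theta)$ jointly by iterative
linearization of the hinge. Around a current $\psi^{(t)}$,

$$h(a, \psi) \approx h(a, \psi^{(t)}) - (\psi - \psi^{(t)})\,1\{a > \psi^{(t)}\},$$

so each iteration fits an NB GLM with the working columns
$U_k = h(a, \psi_k^{(t)})$ and $V_k = -1\{a > \psi_k^{(t)}\}$ and updates
$\psi_k \leftarrow \psi_k + \hat\gamma_k / \hat\delta_k$, where
$\hat\gamma_k$ is the $V_k$ coefficient. The inner NB fit alternates
iteratively reweighted least squares for the coefficients with Newton
maximum-likelihood steps for $\theta$ (the standard alternation for NB2).
Numerical safeguards, all tunable through `segnb_control()`:

* **Search window.** Breakpoints are constrained to the 5th–95th percentile
  of the observed segmented covariate, preventing boundary degeneracy.
* **Backtracking.** A proposed $\psi$ move is accepted only if the profile
  log-likelihood (hinge-only refit) does not decrease; otherwise the step is
  halved, up to 5 times. Accepted iterations therefore have monotone
  log-likelihood.
* **Convergence.** Iteration stops when the largest $\psi$ move falls below
  $10^{-6}$ of the covariate range, or when the profile log-likelihood
  stalls (relative change below $10^{-9}$) — the $\psi$ update can
  oscillate at a scale far below any scientifically meaningful resolution.
* **Multi-start.** With no starting values, candidate breakpoints on a
  quantile grid are screened by profile log-likelihood and the iteration is
  run from the best few (`n_keep`). On data sets beyond `screen_n` rows the
  screening fits use a deterministic x-stratified subsample; start selection
  needs only the coarse shape of the profile.
* **Discrete polish.** The profile log-likelihood is piecewise-smooth with
  kinks at every observed covariate value; on small samples the
  linearization can settle one basin short of the discrete optimum. After
  convergence the profile is re-evaluated at the candidate midpoints nearest
  each $\hat\psi_k$ (window of 10 on each side, repeated until no
  improvement) and the best is kept. With more than 5000 distinct covariate
  values the profile is effectively smooth and this step is skipped.
* **Separation.** Two breakpoints closer than 2% of the search window are
  treated as collapsed and reported as an error suggesting fewer
  breakpoints.

Standard errors for $\hat\psi_k$ use the delta method on the ratio
$\hat\gamma_k/\hat\delta_k$ at convergence, the standard result for this
estimator. Coefficient covariance comes from the Fisher information at the
MLE; $\theta$'s standard error from the observed information of its profile
likelihood (the two blocks are orthogonal for NB2). Wald p-values are
reported for the unsegmented terms only; for the hinge (slope-change) terms
they are shown as `NA`, because under "no breakpoint" the breakpoint
location is unidentified and the usual test is invalid without a
Davies-type correction, which this package intentionally omits. The model's
AIC counts $\theta$ and each estimated breakpoint as parameters.

```{r fit-example}
d <- sim_floe_table(8000, seed = 1)
fit <- segnb(seal_count ~ area + rough_1000 + sic_750 + colony_dist,
             data = d, seg = "area", npsi = 2)
summary(fit)
```

## What the synthetic generator emulates — and what it does not

The licensed source imagery (and hence the real floe tables) cannot be
redistributed, so every stage is exercised on synthetic scenes built by
`gen_floe_field()`, `gen_bathymetry()` and `sim_floe_table()`. Choices, made
once and fixed:

* **Floe areas**: log-normal, `meanlog = 4.0`, `sdlog = 1.5`, truncated to
  $[1, 5000]$ m$^2$. This emulates a *training sample already flattened by
  stratified size-bin selection*, not the raw floe-size population (which is
  far more extremely skewed toward 1-m$^2$ fragments). The truncation bound
  and the spread put both reference breakpoints well inside the 5th–95th
  percentile search window, which any recoverable design must do.
* **Covariates**: `sic_750 ~ Beta(5, 2)` (dense pack ice, mean 0.71; the
  other radii are correlated, nested jitters), `rough_1000 ~ Gamma(2, 5)` m
  with slope/TRI co-varying, `colony_dist ~ Uniform(5, 500)` km in meters.
* **Geometry**: floes are non-overlapping circles (a polygonal perimeter
  factor perturbs recorded perimeters); bathymetry is a spectrally
  synthesized Gaussian random field with Gaussian correlation of the
  requested length, normalized to the requested standard deviation in
  expectation.
* **Seeding**: every generator is a pure function of (spec, seed); one
  master seed derives fixed sub-streams per generator.

Passing the recovery tests therefore shows the *estimator* is correct and
well-calibrated at survey scale; it does not validate the covariate
distributions against real Antarctic scenes, nor does the generator emulate
image radiometry, floe fragmentation geometry, spatial clustering of seals
beyond what the covariates induce, or scene-to-scene heterogeneity.

## Covariate extraction conventions

Sea-ice concentration "around a floe" is computed in an annulus from the
floe boundary outward (excluding the focal floe's own pixels — a large floe
should not dominate its own neighbourhood covariate), at radii 150, 250,
500, 750, 1000 m. Terrain metrics use 3×3 focal windows: slope is the
central-difference gradient magnitude, TRI the mean absolute difference
from the centre cell, roughness the window max minus min; each is averaged
over pixels whose centres fall in a 1000 m circle. Floes within 1000 m of
the scene edge are removed before extraction so no buffer ever reads
outside the rasters. All coordinates are planar scene meters (origin at the
raster's top-left, y downward); any monotone variant of these focal
definitions would merely rescale the roughness coefficient, so one
convention is fixed package-wide, identically in the generator and the
extractor.

Where a simulation study needs covariates but not rasters,
`sim_covariates()` draws them directly from the distributions above — the
fast path used by the survey-scale recovery experiments.

## Model selection and importance

Candidate screening uses a regression forest plus conditional permutation
feature importance (CPFI): for each predictor, observations are stratified
into cells by the quantile grid (4 bins per conditioner, shrunk until every
cell holds at least 2 rows) of every other predictor with absolute Spearman
correlation above 0.2, and the predictor is permuted within cells. This
preserves the permuted predictor's joint distribution with its correlated
partners and so removes the importance a variable inherits merely by being
correlated with a truly informative one. The forest itself uses standard
variance-reduction splits — the conditioning lives in the importance
measure, not in the split tests; that is a deliberate simplification and is
what the package's calibration tests exercise. "Accuracy" for the count
response is reported as the round-to-integer exact-match rate of OOB
predictions; it is never used for selection.

Model search is all-subsets AIC (`dredge_aic()`, every subset of the
optional covariates on top of the segmented area term), followed by k-fold
or leave-one-scene-out cross-validation of the top candidates; the final
model rule is lowest mean held-out MAPE with RMSE as tie-break.

## Error metrics, intervals, diagnostics

Most floes hold zero seals, so per-floe percentage error is undefined.
MAPE is therefore computed on *size-bin aggregates*: observed and predicted
counts are summed within 20 log-spaced area bins (per scene), bins with
zero observed total are dropped, and MAPE is the mean absolute percentage
error of the bin totals. RMSE is per-floe. This aggregation rule is an
interpretation — reported prominently because other conventions give
different numbers.

Bootstrap intervals use nonparametric case resampling of floes with a full
refit per replicate. The CI for $\mu_i$ is the percentile interval of the
replicate $\hat\mu_i^b$; the PI draws one NB count per replicate at
$(\hat\mu_i^b, \hat\theta^b)$ and takes percentile bounds of the draws,
enveloped with the CI so the CI is always contained in the PI even where
the integer draws collapse to zero. Scene totals use the same construction
on the replicate sums; the point prediction for a scene is exactly the sum
of floe-level predictions.

Residual diagnostics follow the heteroscedasticity question "does residual
spread change with the predicted count": Pearson's correlation (with a
Fisher-z interval) between Pearson residuals and fitted values, and White's
test in its Lagrange-multiplier form with auxiliary regressors
$\{\hat\mu, \hat\mu^2\}$ — $nR^2$ against $\chi^2_2$.

## The candidate-distribution comparison and its limits

`compare_distributions()` fits Poisson, NB2, Gamma, Exponential and
Log-normal with a log-linear mean in area and ranks them by AIC, fitting
the continuous families on $y + 0.5$ since they are undefined at zero. That
half-count shift has a sharp consequence: AIC then compares count *pmfs*
against continuous *densities*, and when a single count value dominates
(say, 80% zeros), the density's Jacobian advantage at the point mass
($+\log 2$ per zero for the shifted log-normal) is enough to beat the true
NB model systematically. No information inequality protects a discrete
truth against a density on a different dominating measure. The comparison
is therefore informative only in moderate-count regimes (roughly, zero
fraction below ~0.2); the package's calibration tests run it there, and
users applying it to heavily zero-inflated floe tables should treat a
continuous-family "win" as an artifact of the convention, not evidence.

## Problem sizes used in the validation suite

The recovery experiment refits the 2-breakpoint model on 25 replicates of
60,000 floes — large enough that the weak second kink (slope change of
0.003 per m$^2$) is estimable, matching the order of the real training
sample. Bootstrap coverage uses 25 replicates of 500 floes with 500 refits
each; the five-family comparison 100 replicates of 5,000 floes; the
White-test size study 500 replicates of 1,000 observations; CPFI
calibration 100 replicate forests. These sizes were chosen so each check
estimates its rate with useful precision while the whole suite stays
comfortably runnable on a single CPU.

## Known limitations

* Breakpoint inference is conditional on the chosen number of breakpoints;
  no Davies-type existence test is provided.
* Quasi-separation is possible on small samples: if every floe below a
  candidate breakpoint has a zero count, the first-segment slope is
  unbounded in the likelihood and the fit reports enormous coefficients
  with non-finite standard errors. Sample more floes or drop to `npsi = 0`.
* The bootstrap treats floes as exchangeable; spatial correlation within
  scenes is not modelled.
* Scene-level observed-versus-predicted comparisons on the real imagery are
  out of reach without the licensed data; the package validates against
  simulation truth instead.
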