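# floeseal

Segmented negative binomial models of pack-ice seal occupancy on sea-ice
floes.

## The problem

Antarctic pack-ice seals (predominantly crabeater seals along the western
Antarctic Peninsula) haul out to rest on free-floating ice floes, where
very-high-resolution satellite imagery can count them. Turning such counts
into abundance estimates requires a model of *how many seals to expect on a
given floe*: occupancy rises steeply with floe area on small floes, then
much more slowly, and finally plateaus on the largest floes, and it also
responds to the surrounding sea-ice concentration, the roughness of the
seafloor below, and the distance to penguin colonies (a proxy for
competition for krill).

`floeseal` is for quantitative ecologists building that kind of
floe-resolved occupancy model: it provides the segmented count regression
at the core, the covariate-extraction conventions around it, and a
synthetic-scene generator so the whole pipeline can be exercised and
calibrated without access to licensed imagery.

## The model

Seal counts per floe are NB2,
`Var(y) = mu + mu^2/theta`, with a log-mean piecewise linear in floe area
`a` (m^2):

```
log mu = b0 + b1*a + d2*max(0, a - psi1) + d3*max(0, a - psi2)
         + br*rough_1000 + bs*sic_750 + bc*colony_dist
```

The breakpoints `psi1 < psi2` are estimated, not fixed: `segnb()` fits them
by iterative linearization of the hinge terms (working columns
`U = max(0, a - psi)` and `V = -1{a > psi}`, update `psi <- psi +
gamma/delta`), with quantile-window constraints, profile-likelihood
backtracking, multi-start, and a discrete polish on small samples.
Breakpoint standard errors come from the delta method on `gamma/delta`.
The reference parameter set (`seal_model()`) has breakpoints near 50 and
481 m^2: strong area dependence below ~50 m^2 (slope 0.139 per m^2), a
near-flat middle segment (0.003), and a plateau beyond ~481 m^2.

Around the core sit: per-floe covariate extraction from raster masks
(sea-ice concentration in metric ring buffers, 3x3 focal
slope/TRI/roughness averaged in a 1000 m circle, nearest-colony distance,
1000 m edge-buffer filtering, stratified size-bin sampling), a five-family
AIC comparison, conditional permutation feature importance on a regression
forest, all-subsets AIC ranking with cross-validation, bootstrap confidence
and prediction intervals, and Pearson/White residual diagnostics.

## A worked example

```r
library(floeseal)

# simulate a 8,000-floe survey from the reference occupancy model
d <- sim_floe_table(8000, seed = 1)

# refit the 2-breakpoint segmented NB GLM
fit <- segnb(seal_count ~ area + rough_1000 + sic_750 + colony_dist,
             data = d, seg = "area", npsi = 2)
summary(fit)
```

```
Coefficients:
              Estimate Std. Error z value Pr(>|z|)
(Intercept) -7.026e+00  3.046e-01 -23.065  < 2e-16 ***
area         1.260e-01  5.680e-03  22.191  < 2e-16 ***
rough_1000   4.694e-02  3.280e-03  14.312  < 2e-16 ***
sic_750     -7.694e-01  1.593e-01  -4.831 1.36e-06 ***
colony_dist  4.600e-07  1.803e-07   2.551   0.0107 *
U1.area     -1.225e-01  5.747e-03 -21.322       NA
U2.area     -3.353e-03  2.791e-04 -12.012       NA

Breakpoints:
     Estimate Std. Error
psi1  50.8369     1.0664
psi2 387.1812    34.7804

Derived per-segment slopes:
segment1 segment2 segment3
  0.1260   0.0035   0.0002

theta (NB2 dispersion): 0.5121  (SE 0.02226)
logLik: -6227.65   AIC: 12475.3   n: 8000
```

Reading this against the generating values (intercept -7.53, first-segment
slope 0.139, roughness 0.042, SIC -0.72, breakpoints 49.84 and 481.32,
theta 0.5): the first breakpoint, dispersion and all covariate effects are
recovered within one to two standard errors, the hinge-term p-values are
deliberately `NA` (their Wald tests are invalid without a Davies-type
correction), and the near-zero third-segment slope is the plateau on the
largest floes. The second breakpoint is the hard parameter — the slope
change there is only 0.003 per m^2, so at n = 8,000 its estimate (387, SE
35) still wanders; the survey-scale recovery experiment below shows it
centering on the truth at n = 60,000. Continue with, e.g.:

```r
compare_distributions(d$seal_count, d$area)   # five-family AIC table
dredge_aic(d, optional_terms = c("rough_1000", "sic_750", "colony_dist",
                                 "perimeter", "sic_1000", "slope_1000"))
bootstrap_intervals(d, function(dd)
  segnb(seal_count ~ area + rough_1000 + sic_750 + colony_dist, dd,
        npsi = 2), n_boot = 1000, seed = 1)
residual_diagnostics(fit)
```

or run a full synthetic scene end to end (floe field, rasters, covariate
extraction, fit, predictions, manifest) with `run_pipeline()`.

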