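---
title: "Virtual species, spatial sampling bias, and sex-ratio estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual species, spatial sampling bias, and sex-ratio estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`sdmbias` is a simulation laboratory for a specific methodological question
in presence-only species distribution modelling (SDM): when two subgroups of
a population — here the two sexes — prefer different habitat, what does
spatially biased sampling do to estimated habitat coefficients and to the
estimated sex ratio, and how well do two standard bias corrections repair
the damage? This vignette explains the model, the simulated observation
process, the estimators, the choices behind the package defaults, and what
the experiments do and do not demonstrate.

```{r setup}
library(sdmbias)
```

## The generating model

Each sex's sign density is an inhomogeneous Poisson point process at the
25 m cell resolution. With standardized environmental covariates $x_i(s)$
the log intensity in cell $s$ is linear,

$$\ln \lambda(s) = \beta_0 + \sum_{i=1}^{p} x_i(s)\,\beta_i,$$

and the realized number of signs per cell is an independent Poisson draw
with mean $\lambda(s)$. The two sexes have their own coefficient vectors.
The shipped reference parameterization (`reference_params()`) uses three
covariates named `slope`, `canopy` and `simpson` (terrain slope, canopy
density between 10 and 20 m, and a Simpson index of vegetation-height
diversity) with female slopes $(-0.9, -0.8, 1)$ and male slopes
$(-0.2, 0.9, -0.9)$: females prefer flat, open-canopy, structurally diverse
forest; males the converse. These opposed preferences are what makes biased
sampling consequential.

The male intercept is not a free parameter. `calibrate_male_intercept()`
solves in closed form for the intercept that makes the expected female
share of total intensity, $\sum_s \lambda_f / (\sum_s \lambda_f + \sum_s
\lambda_m)$, equal a target (0.5 by default) *exactly* on the landscape at
hand. A fixed intercept constant only balances the sexes on the one
landscape it was tuned for; the closed form transfers the design to any
synthetic landscape. (On the default landscape the calibrated value,
$\approx -3.54$, is nearly identical to the reference constant $-3.55$.)
The reference study notes intensities should stay roughly within 0 and 2
per cell; we treat that as a sanity diagnostic, not a constraint, since the
attained range depends on the covariate field's tails.

## The synthetic landscape

No real rasters are bundled; `generate_covariates()` emulates them.
Stationary Gaussian random fields with an exponential correlogram
$C(h)=\exp(-h/\rho)$ are simulated by circulant embedding (FFT on a
doubled torus; the embedding's few negative eigenvalues are clamped to
zero, a standard approximation). The independent fields are then centered,
empirically whitened with the Cholesky factor of their sample covariance,
and re-colored with the Cholesky factor of the target correlation matrix,
so the realized between-layer Pearson correlations equal the target to
machine precision while the spatial structure is preserved. Defaults: a
$145 \times 145$ grid of 25 m cells ($\approx 13\ \mathrm{km}^2$),
autocorrelation range $\rho = 200$ m, and pairwise correlations
0.21 (slope/canopy), 0.18 (slope/simpson) and 0.12 (canopy/simpson),
mirroring the weakly correlated LiDAR-derived variables the design is
modeled on. The correlogram family and range are exposed as configuration
because the original variables' autocorrelation structure is not
documented; the exponential family is a neutral stand-in.

```{r landscape}
stack <- generate_covariates(60, 60, 3, spatial_range = 200, seed = 1)
round(cor(stack_as_matrix(stack)), 3)
```

## The observation process

Three survey designs are simulated:

* **random** — 2,000 points uniform over the landscape; a cell is sampled
  if it contains a point, and every sign in a sampled cell is observed
  (detection 1 there, 0 elsewhere);
* **systematic** — parallel transects 400 m apart with a random offset
  (about 32 km of lines on the default extent);
* **subjective** — `generate_subjective_trajectory()` emulates
  opportunistic surveys: correlated random walks whose *start cells* and
  *step directions* are up-weighted by $\exp(b \cdot \text{preference})$,
  with the male habitat surface as the preference. Observers in the
  motivating system deliberately searched male-preferred, more open forest;
  biased starts reproduce the landscape-scale component of that behavior
  (choosing favorable areas), biased steps the local component.

For trajectory designs, a sign at distance $d$ from the nearest trajectory
is observed with probability $p(d) = g(d)/g(0)$, where $g$ is a
distance-decay density (`detection_model()`); observation is an independent
Bernoulli per sign, i.e. a per-cell binomial thinning of the Poisson
counts. Cells with zero observed signs disappear, and every observed sign
becomes one presence-only record at its cell center — duplicates are kept
deliberately, one row per sign. The decay family is configurable
(exponential, half-normal, or a log-spline density fitted to observed
distances by Poisson regression of binned counts on a natural-spline
basis) so the simulated decay and the decay assumed in a correction can be
matched or mismatched on purpose.

Default observation-process parameters were chosen once, to reproduce the
reference study conditions at their reported order of magnitude: an
exponential decay with mean detection distance 10 m (truncated at 300 m)
yields roughly 70 observations per sex under the systematic design and
roughly a hundred per sex under the random design, and a walker bias of
$b = 0.7$ split over 12 walks totalling 31.2 km yields a male-dominated
subjective sample (observed female share roughly 0.1–0.35 across
landscape realizations) together with a strong distortion of the sampled
covariate distribution. Short mean detection distances are realistic for
ground signs (feces, feathers) in closed forest.

## Fitting and the two corrections

`fit_sdm()` is a Maxent-equivalent presence-only fitter: a logistic
regression of presences (weight 1) against background points (large
weight), whose slope estimates converge to the maximum-likelihood slopes
of the Poisson point process as the background weight grows — the
"infinitely weighted logistic regression" equivalence. Features are linear
only, matching the generating model; no regularization is applied. The
default background weight is 1000, at which the slopes agree with an
independent down-weighted Poisson quadrature fit to a few times $10^{-4}$
(the tests assert $10^{-3}$); at weight 100 the residual gap can exceed
$10^{-3}$, which is why the default is higher. Background size defaults to
10,000 points, fixed across replicates within a scenario so replicate
variation reflects the observation process, not background resampling.

Sampling bias is addressed in three ways:

* **none** — uniform random background;
* **targeted background** — `targeted_background()` places background
  points along the survey trajectories with perpendicular offsets drawn
  from the *same* detection density $g$, so presences and background share
  the spatial observation bias and it cancels in the contrast;
* **distance covariate** — the cell's distance to the trajectories enters
  the model as one extra linear predictor (scaled internally to 100 m
  units for conditioning, reported per meter), with uniform background.

## Sex-ratio estimation

Relative abundance per cell is the normalized raw prediction
$\mu_j \propto \exp(\sum_i x_{ij}\hat\beta_i)$, $\sum_j \mu_j = 1$; for
distance-corrected fits the distance term is set to zero, giving the
habitat-only surface. Given $N_{obs}$ observed signs and a per-cell
detection probability $p_{obs,j}$, the expected total sign count under
complete sampling is

$$N_{tot} = \frac{N_{obs}}{\sum_j \mu_j\, p_{obs,j}},$$

the unique solution of $E[N_{obs}] = N_{tot} \sum_j \mu_j p_{obs,j}$; at
$p \equiv 1$ it reduces to $N_{obs}$, and $\sum_j \mu_j p_{obs,j} = 0$
(no detectable mass) is an error. The sign density map is
$\lambda_j = \mu_j N_{tot} / a_j$ in signs/ha. $p_{obs,j}$ comes from the
detection density ($g(d_j)/g(0)$, used for the uncorrected and
targeted-background models), from the fitted distance coefficient
($\exp(\hat\beta_d d_j)$, capped at 1 — a positive $\hat\beta_d$ is
flagged as a fitting problem), or is the binary sampled-cell indicator for
random designs. The sex ratio (female share) is then
$N_{tot,f}/(N_{tot,f}+N_{tot,m})$, or $N_{obs,f}/(N_{obs,f}+N_{obs,m})$
when estimated from raw observations. Any detection rescaling shared by
both sexes cancels in the ratio.

One estimator subtlety surfaced by the simulations: because the
uncorrected-model estimator *also* uses the detection density for
$p_{obs,j}$, knowing the true decay already absorbs most of the
detection-driven ratio bias, and on these synthetic landscapes the
uncorrected model-based ratio often lands near 0.5 even when the raw
observed ratio is badly biased; its residual bias (driven by differential
$\hat\mu$ bias between sexes) varies in sign across landscape
realizations. The experiment therefore treats the observation-based ratio
as the uncorrected baseline when ordering estimators, and reports the
uncorrected model-based ratio alongside.

## The replicated experiment

`run_experiment()` fixes one landscape, one set of survey designs and one
background set per scenario, then per replicate redraws the Poisson counts
and the thinning, fits female, male and pooled (generic) models for every
design/correction combination, and records habitat-coefficient bias
(signed, estimate minus truth; summaries also report magnitudes since sign
conventions vary), Spearman rank correlation between predicted
relative-abundance maps and each sex's true intensity surface,
cross-validated AUC against an independently drawn evaluation background
(fold mean and between-fold variance, no refitting — the cross-validated
AUC convention), and the sex-ratio estimates. One master seed spawns one
sub-seed per replicate; the whole object is reproducible from
`(config, seed)`. Scenario cells that fail (e.g. too few female presences
in an extreme replicate) are recorded and skipped, and the run continues.
Trajectory designs and all background sets are fixed across replicates
(the trajectories stand in for fixed real-world survey routes, and fixed
background locations are part of the emulated design); the random survey
points, by contrast, are redrawn each replicate, since each replicate
represents an independently collected survey — freezing them would add an
arbitrary persistent component to the replicate-mean coefficient bias.

Default problem sizes — a $145 \times 145$ landscape, 100 replicates,
10,000 background points — complete in a few minutes on one core and give
replicate-mean standard errors comfortably below the effect sizes of
interest. The package's own acceptance checks assert, at these defaults:
unbiased coefficient recovery under random sampling (|mean bias| ≤ 0.1);
that both corrections shrink the bias of the most-distorted covariate
under subjective sampling; Spearman ρ ≥ 0.95 for own-sex maps under random
sampling; and the ratio ordering described above. Replicate variance of
corrected estimates exceeds the uncorrected variance — the cost of bias
correction observed in the reference study — and can be read off the `sd`
columns of `summarize_experiment()`.

## Numerical choices and degenerate inputs

* Grids are stored bottom-up with the origin at the lower-left corner;
  cell centers at `origin + (index - 0.5) * cell_size`. Missing cells
  propagate through intensities and are excluded from sums.
* Standardization is idempotent, stores its constants for replay on
  prediction rasters, and rejects constant layers.
* Distance to trajectories is the exact point-to-segment minimum over all
  segments (no densification); it is invariant to vertex order and
  densification by construction.
* The spline detection fit normalizes by $g(0)$ evaluated at the boundary;
  `p(0) = 1` holds for every form. All-identical distances are rejected
  for the spline form; distances beyond the truncation are dropped with a
  warning.
* Relative-abundance maps subtract the maximum linear predictor before
  exponentiating (overflow-safe) and are invariant to intercept shifts.
* Complete separation or non-convergence in the logistic fit warns and
  reports diagnostics rather than failing silently; collinear covariates
  yield `NA` coefficients with a warning.

## Limitations

The generator emulates the *structure* of the motivating data, not the
data themselves: real LiDAR covariates have non-Gaussian marginals and
scale-dependent autocorrelation; real observer routes follow terrain and
access constraints no preference walk reproduces; detection in the field
varies among observers and with sign type, and sexing of signs is
imperfect (none of which is modeled). Passing experiments therefore
demonstrate the estimators' behavior under a faithful stylization of the
design — not performance guarantees on any particular field dataset.
Abundance here is sign abundance; converting sign totals to individuals is
out of scope, as are occupancy-style detection models, temporal dynamics,
and Maxent's hinge/product feature classes.
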