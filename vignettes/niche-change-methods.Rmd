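---
title: "Detecting niche change through time with aggregated presence/background GAMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting niche change through time with aggregated presence/background GAMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiocarbon-dated occurrences from the archaeological and paleontological
record are sparse and geographically biased, and the bias differs between
millennia. Fitting a separate species distribution model (SDM) to each
paleoclimate time slice therefore confounds genuine niche change with
sampling noise: a slice with few, clustered finds yields an artificially
narrow niche estimate. `paleoniche` implements the opposite strategy:
*all* dated occurrences enter one binomial generalized additive model
(GAM), and niche change is expressed as a smooth interaction between each
environmental variable and time. Whether the niche changed at all then
becomes a model-comparison question rather than a visual comparison of
per-slice maps.

## The model

Occurrences are presences; absence is never observed, so each presence is
contrasted against random *background* points describing the available
environment, drawn from the land, ice-free cells of the presence's own
time slice at a 50:1 ratio. With time-matched backgrounds the per-slice
prevalence is constant by construction, which is why the models need no
standalone time term — a pure time effect is unidentifiable by design,
and any time signal the model finds must come through the environment.

Two models are fitted to each background draw, with
$y_i \sim \mathrm{Bernoulli}(p_i)$ on the logit scale:

* **constant niche**:
  $\mathrm{logit}(p_i) = \beta_0 + \sum_v f_v(x_{iv})$, one thin-plate
  regression spline per variable;
* **changing niche**:
  $\mathrm{logit}(p_i) = \beta_0 + \sum_v g_v(x_{iv}, t_i)$, one
  tensor-product smooth per variable, each margin carrying its own
  wiggliness penalty, so the response curve can deform progressively
  through time. The tensor absorbs the variable's main effect.

The five variables are BIO5 (maximum temperature of the warmest month,
degrees C), BIO6 (minimum temperature of the coldest month, degrees C),
BIO12 (annual precipitation, mm/yr), NPP (net primary productivity) and
rugosity (topographic roughness, unitless). Basis dimensions default to
k = 16 for BIO6 and k = 10 for the others (per margin), with 5 basis
functions on the time margin; smoothing parameters are selected by REML
with the complexity multiplier gamma = 1.4 penalizing overly wiggly
smooths. Fitting goes through `mgcv`, using the extended Fellner–Schall
update for the REML optimum — the same criterion as the default Newton
optimizer, several-fold faster on tensor-heavy formulas (on a 15,000-row
repetition: roughly 25 s vs 90 s). Rows with identical response and
covariates (frequent, because background cells are drawn with replacement
from a finite grid) are aggregated into prior weights before fitting; the
replicated-Bernoulli likelihood is identical, so every reported score is
unchanged while fitting cost roughly halves.

Model support is summarized per repetition by
$\mathrm{AIC} = -2\ell + 2\,\mathrm{edf}$, with the effective degrees of
freedom taken as the trace of the influence matrix of the penalized fit
(we deliberately do not use the smoothing-uncertainty-corrected edf some
implementations substitute, so the reported AIC matches the stated
formula exactly). Deviance explained and Nagelkerke
$R^2 = \frac{1-\exp((D_1-D_0)/n)}{1-\exp(-D_0/n)}$ are reported
side-by-side. A difference is called "supported" only beyond the
conventional 2-unit AIC margin.

## Repetitions, validation, ensembling

Because background sampling is stochastic, the whole comparison is
repeated across 25 independent background draws (10 in the scaled-down
experiments the tests run; the count is a parameter). Each changing-niche
fit is validated with the **continuous Boyce index**: 101 overlapping
windows of width one tenth of the prediction range slide over the
available-cell predictions; per window the presence share is divided by
the available share, consecutive duplicate ratios are collapsed, and the
index is the Spearman rank correlation between the ratio and the window
midpoint. An index of 1 means suitability ranks presences perfectly; 0 is
random. (The index is defined as a rank correlation throughout — that is
the standard continuous formulation.) Fits with an index above 0.8 are
ensembled pointwise by mean and by median; whichever ensemble scores the
higher index is used for everything downstream.

**Variable importance** partitions deviance two ways per variable:
*total* (deviance explained by a model with only that variable, its time
tensor retained) and *unique* (loss in deviance explained when the
variable is dropped from the full model); the difference is variance
shared with other variables. With penalized fits the unique component can
dip a few hundredths below zero; differences within ±0.01 should not be
interpreted.

## Projection

The best ensemble is projected onto every slice's land, ice-free cells.
Probabilities are binarized at the **minimum-predicted-area** threshold:
the largest threshold that still covers 99% of the training presences
(pooled across slices, one threshold per species), so presence recovery
is guaranteed by construction. Binary maps are averaged within four
climatic periods — pre-LGM (47–27 kya), LGM (27–18), Late Glacial
(18–11.7), Holocene (11.7–7.5) — a slice on a shared boundary counting
toward the older period; each period mean is shown only on cells that are
land in *all* member slices, with the union of member ice masks carried
for display. Niche change itself is visualized as the centered partial
effect of each tensor smooth on a (time × variable) grid, averaged across
accepted repetitions, masked where no training data fall nearby
(default: within 10% of each axis range), and accompanied by the
presences and the availability density of the variable through time, so
preference can be read against what was actually available. Two
centerings are offered: the conventional global centering for display,
and a per-time-column centering (`center = "by_time"`) that removes each
tensor's arbitrary share of the (by design unidentifiable) pure time
effect — the right scale for asking *when* a preference changed sign.
When localizing a change point, we read the zero crossing from the mean
profile pooled over all flip rows rather than a single row; single-row
crossings scatter by a couple of thousand years under smoothing, and the
crossing position is in any case biased toward the young side because
the availability of the newly preferred conditions lags the niche change
itself.

## Diagnostics

* Pearson correlation screen on the model table (|r| < 0.7 passes).
* Concurvity: per smooth term, the share of its fitted component's
  variance reproducible by least-squares projection onto the other
  terms' column space (weight-aware); values below 0.8 pass. This equals
  the "observed" measure of `mgcv::concurvity` for unweighted fits.
* Simulation-based randomized-quantile residuals (250 simulations):
  Kolmogorov–Smirnov uniformity, a dispersion ratio against the
  simulated Pearson statistic, and an outlier count tested against its
  *exact* Bernoulli null probability (the mean over observations of
  $p(1-p)^S + (1-p)p^S$, with $S$ simulations) rather than the $2/(S+1)$
  rule used for
  continuous responses, which is badly mis-calibrated for binary data.
  Note that for independent binary observations the dispersion statistic
  is determined by the fitted means alone, so it has essentially no
  power against marginal misspecification or latent clustering; it is
  reported for completeness, and mean-structure misspecification is
  instead caught by the uniformity test.
* Moran's I on residuals with inverse great-circle (haversine) distance
  weights between points of the *same* slice (zero across slices),
  row-standardized, pairs at identical cell centers clamped to 1 km;
  significance by one-sided permutation (999 shuffles). The run passes
  if p ≥ 0.05 or |I| < 0.1. At pipeline scale the point set is capped at
  a seeded subsample of 2000 rows to keep the permutation test
  tractable.

## The synthetic world

The generator exists so the whole pipeline can be exercised with a known
truth and no downloads. It emulates the *structure* of the gridded
paleoclimate reconstructions the method targets — five variables on a
regular lon/lat grid, slices every 1000 years up to 22 kya and every
2000 years before, land and ice masks — without any claim of
climatological realism. Each variable is a baseline plus latitudinal and
longitudinal gradients, a smooth random spatial field (low-order cosine
basis, seeded), and a Gaussian-in-time glacial signal peaking at 21 kya
(width 9000 y) that cools temperatures, dries precipitation and pushes
the ice margin south; the coastline is a time-constant thresholded random
field (10% sea). Gradients and field amplitudes were chosen once so that
all pairwise correlations stay below the 0.7 screen (maximum ≈ 0.6 in
the default world); a `collinear = TRUE` switch duplicates the BIO5
field into NPP to exercise the screen's failure path.

The true niche is a product of Gaussian response curves per variable
(so suitability is automatically in [0, 1] and never exceeds any
marginal curve). The default constant world uses optima of 18 °C (BIO5),
−5 °C (BIO6) and 700 mm (BIO12), with NPP and rugosity inert — giving
the importance analysis known signal and known noise variables. The
change-point world shifts the BIO6 optimum from −20 °C (at and before
16 kya) to −5 °C afterwards, with a smaller BIO5 shift — a strong,
localized niche change whose fingerprint the tensor smooths should
recover as a sign flip in the cold-end BIO6 effect near 16 kya.
Presences are drawn per slice from land, ice-free cells with probability
proportional to suitability times an east–west logistic sampling-bias
ramp (mimicking uneven archaeological effort; the real sampling process
is unknown, and this bias model is an assumption for testing, not a
claim about the record). Ages are jittered uniformly within the slice's
half-spacing, so nearest-slice assignment provably round-trips; the
default sampling error column is 150 y. Because the generator has
bias but no date-calibration error model, no spatial autocorrelation in
the residual sense, and no biotic interactions, passing tests show the
*machinery* recovers planted signals under the stated assumptions — they
say nothing about whether real data meet those assumptions.

## Numerical and design choices

* **Time axis**: the 1000/2000-year spacing rule over the 7.5–47 kya
  window yields 27 slices (8–22 kya by 1, 24–46 kya by 2). Ages are
  assigned to the nearest slice, ties toward the older slice (fixed,
  documented; real data may interpolate instead, which we do not).
* **Cells** are half-open `[west, east) × [south, north)`, coordinates
  are cell centers, and the grid origin/resolution are explicit — no
  hard-coded 0.5°.
* **Window** [7500, 47000] is closed at both ends.
* **Collapse** to one record per species × cell × slice keeps the
  smallest dating error, remaining ties broken by record content (age,
  then coordinates) so the result is invariant to file order.
* **Ice** is treated as non-habitat everywhere: excluded from background
  sampling, availability densities and map denominators.
* **Background** draws cells uniformly *with replacement*; presence
  cells stay eligible (background is availability, not pseudo-absence).
* **Degenerate inputs**: constant covariates reduce k with a warning;
  all-sea slices error by name; empty periods warn and are skipped;
  an all-constant prediction vector makes the Boyce index undefined and
  errors rather than returning a number.
* **Problem sizes** in the shipped experiments — ~300 presences over 27
  slices, 10 repetitions, 50:1 background — were chosen as the smallest
  sizes at which the AIC selection experiment is decisive (observed
  delta AIC ≈ +90 to +107 under the change-point world, ≈ −10 under the
  constant world); the full-scale analysis simply raises `n_rep` and the
  occurrence count.
* **netCDF**: cubes are serialized as a plain-text bundle (`meta.json` +
  long CSV). The format is self-describing and round-trips exactly;
  adapters for binary raster formats can wrap `climate_cube()` directly.

## Limitations

Beyond the synthetic-world caveats above: the changing-niche formula
cannot separate a niche change from a change in sampling bias that is
correlated with the environment (the aggregated design mitigates but
does not remove geographic bias); concurvity between rugosity and
temperature-like variables is intrinsic to real topography and can blur
the attribution of importance; and AIC comparison across repetitions is
not a formal test — the per-repetition unanimity reported by
`select_model()` is descriptive, not an error rate.
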