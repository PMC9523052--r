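# paleoniche

Time-aggregated species distribution modelling for detecting ecological
niche change from radiocarbon-dated occurrences.

## The problem

Dated occurrences from the archaeological and paleontological record are
sparse and geographically biased, and the bias differs between
millennia. Fitting a separate species distribution model to every
paleoclimate time slice therefore confuses genuine niche change with
sampling noise. `paleoniche` takes the opposite route: all occurrences
from the study window (by default 7.5–47 thousand calibrated years BP)
enter a *single* presence/background binomial GAM, and niche change is
expressed as smooth environment-by-time interactions.

For each species two models are fitted and compared:

- **constant niche**: `logit p = β₀ + Σᵥ fᵥ(xᵥ)` — one thin-plate
  regression spline per environmental variable (BIO5, BIO6, BIO12, NPP,
  rugosity);
- **changing niche**: `logit p = β₀ + Σᵥ gᵥ(xᵥ, t)` — one
  tensor-product smooth per variable, letting its effect deform through
  time.

Each presence is matched by 50 random background points from the land,
ice-free cells of its own time slice; the whole comparison is repeated
over 25 independent background draws and summarized by AIC
(`−2ℓ + 2·edf`, with a 2-unit support margin). Changing-niche fits are
validated with the continuous Boyce index (presence-only; Spearman
correlation of predicted-to-expected ratios against suitability, gated
at 0.8), ensembled by mean and median, projected to per-slice
suitability maps, binarized at the minimum-predicted-area threshold
covering 99% of presences, and averaged over the four climatic periods
(pre-LGM 47–27, LGM 27–18, Late Glacial 18–11.7, Holocene 11.7–7.5 kya).
Deviance partitioning (total vs unique deviance explained per variable),
a 0.7 correlation screen, concurvity, simulation-based quantile-residual
checks and Moran's I on residuals round out the workflow. A synthetic
paleoclimate and occurrence generator with a known (optionally
change-point) niche makes everything testable without downloads.

## Worked example

```r
library(paleoniche)

# a synthetic world whose BIO6 optimum shifts from -20 to -5 degC at 16 kya
cfg  <- scenario_config_shift()
cube <- generate_climate_cube(cfg)
occ  <- sample_occurrences(cube, cfg$niche, cfg$sampling, seed = 2)

model <- paleo_sdm(occ, cube, n_rep = 2, seed = 5, verbose = FALSE)
model
#> Time-aggregated niche-change SDM
#>   presences: 299 collapsed records over 27 slices
#>   repetitions: 2 at ratio 50 :1
#> Model comparison over 2 repetitions: changing niche favored in 100%
#>   mean delta AIC (constant - changing) = 76.0
#>   accepted fits (BCI > 0.80): 1 of 2
#>   best ensemble: mean (BCI 0.852)

proj <- project_ensemble(model, cube)
proj$periods
#> Period summary at threshold 0.0022
#>   pre-LGM      10 slices, mean occupancy 0.414
#>   LGM          7 slices, mean occupancy 0.716
#>   Late Glacial 6 slices, mean occupancy 0.849
#>   Holocene     4 slices, mean occupancy 0.748
```

The mean ΔAIC of +76 says the changing-niche model is decisively better
supported on this world (on a constant-niche world it hovers around
zero); the ensemble's Boyce index of 0.85 clears the 0.8 acceptance
gate; and the period summary gives, per climatic period, the share of
slices in which each cell falls inside the binarized range at the
0.0022 minimum-predicted-area threshold (the largest threshold that
still recovers 99% of the presences). `plot(model, "surface",
variable = "BIO6")` draws the environment-by-time effect heatmap in
which the planted cold-to-warm shift appears as a sign flip near
16 kya.

With 25 repetitions (the default) a run like the above takes on the
order of 15 minutes on one core; `run_pipeline()` drives the same
workflow from a YAML/list config and writes every stage artifact plus a
hash manifest for reproducibility.

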