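# wavetrack

Do migrating herbivorous waterfowl time their spring arrivals on the
**green wave** — the northward-sweeping onset of vegetation growth — or on
the **seed wave**, the pulse of post-harvest agricultural seed that spring
snowmelt re-exposes on farmland? `wavetrack` implements the full analysis
pipeline for answering that question from GPS telemetry and gridded
remote-sensing time series, together with a synthetic-data generator with
known ground truth so every stage can be verified end to end. It is aimed
at movement ecologists working with waterfowl (or any migrant tracking
pulsed resources) and at methodologists studying temporal
resource-selection models.

## The model

For each residency site detected in a bird's track, the arrival day is a
*presence* and randomly drawn alternative days are *absences*. With
$m$ = candidate day − resource date at the site's pixel (the resource date
being the pixel's green-up day or one of the 25/50/75/100% snowmelt
dates), and a temporal lag $\ell$, the package fits the random-intercept
logistic resource selection function

$$\Pr(\text{presence}) = \mathrm{logit}^{-1}\big(\beta_0 +
\beta_2\,(m-\ell)^2 + u_{\text{track}}\big), \qquad u_{\text{track}} \sim
N(0,\sigma^2),$$

scans $\ell$ over an integer grid, selects the AIC-optimal lag, brackets
it with the ΔAIC = 2 likelihood range, validates with a track-blocked
k-fold Spearman score $r_s$, and chooses each cohort's cue: plant vs
snowmelt by comparing $r_s$ of the plant model against the mean $r_s$ of
the snow models, and (if snowmelt wins) the specific phase by the minimal
$|\ell^\*|$.

Upstream of the model: green-up dates come from the second-derivative
method on smoothed EVI series; melt phases from exhaustive-search
three-piece segmented regression of daily snow cover; residency sites from
centroid-radius clustering of fixes (≥ 2 days, < 50 km) with NOAA solar
day/night labelling; habitat use from daytime fixes on a seven-class
land-cover grid.

## Worked example

Simulate 50 bird-years whose stopover arrivals sit 2 ± 1 days after the
75% snowmelt date, then run the entire inference chain — segmentation,
phenology and snowmelt retrieval, lag-scanned RSF, cue choice:

```r
library(wavetrack)

spec <- landscape_spec(24, 20, 40, 40, 117,
                       list(farmland = 0.45, grassland = 0.2, wetland = 0.2,
                            water = 0.05, forest = 0.05, shrubland = 0.04,
                            other = 0.01), seed = 101)
grid <- gen_landscape(spec)
evi  <- gen_evi_series(evi_params(), grid, seed = 102)
snow <- gen_snow_series(snow_params(), grid, seed = 103)
truth <- resource_stack(attr(evi, "truth"), attr(snow, "truth"),
                        lat = evi$lat, lon = evi$lon)

scen <- bird_scenario(cue = "melt75", true_lag_days = 2, lag_noise_sd = 1,
                      n_tracks = 50, seed = 7)
sim   <- gen_tracks(scen, truth, grid)
sites <- segment_all_tracks(sim$tracks)

gs <- greenup_surfaces(evi)           # green-wave retrieval
ms <- snowmelt_surfaces(snow)         # seed-wave retrieval
retrieved <- resource_stack(gs$map, ms$maps, lat = gs$lat, lon = gs$lon)

des <- build_design(sites[sites$role == "stopover", ], retrieved, seed = 8)
res <- scan_all_cues(des, seed = 9)
res$melt75
choose_cue(res, region = "NCP_core", species = "synthetic goose")
```

```
<lag_scan> cue melt75: optimal lag +3 days (arrival after resource)
  dAIC=2 range [2.8, 3.5], difference 0.7; logLik -29.01
  k-fold rs: mean 0.677 over 50 fold scores
<cue_assignment> synthetic goose @ NCP_core: snowmelt (specific cue melt75)
  rs plant 0.605 vs snow mean 0.663; |lag| per snow cue: melt25=17, melt50=10, melt75=3, melt100=4
```

The scan recovers the generating cue (75% snowmelt) and a lag of +3 days
(true value 2, arrival-day noise sd 1): birds arrive ~3 days *after* 75%
of the snow has melted off their stopover pixels. The ΔAIC = 2 range
(width 0.7 days) is the likelihood-supported interval around that lag, and
`rs` is the track-blocked cross-validation score of each cue's best model.
`lagscan_table(res, ...)` collects the per-cue rows (cue, signed lag with
range, difference, log-likelihood, rs) into the conventional results-table
layout.

A command-line front-end over the same functions is installed at
`inst/scripts/wavetrack-cli.R` (subcommands `simulate`, `segment`,
`phenology`, `snowmelt`, `rsf`).

## Package layout

- `R/` — generators (`landscape`, `evi-sim`, `snow-sim`, `tracks-sim`),
  retrievals (`phenology`, `snowmelt`), track processing (`solar`,
  `trackproc`, `geo`), inference (`rsf`), habitat use (`habitat`).
- `tests/testthat/` — module tests, property-style invariants, and
  `test-acceptance.R` with the end-to-end recovery experiments.
- `vignettes/wavetrack-methods.Rmd` — the model, its assumptions, every
  tunable parameter, and known limitations.
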