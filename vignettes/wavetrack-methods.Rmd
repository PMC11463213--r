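---
title: "Tracking multiple resource waves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking multiple resource waves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavetrack)
```

## The scientific question

Migrating herbivorous waterfowl in East Asia exploit two pulsed food
resources in spring: newly emerging vegetation in natural habitat (the
*green wave*) and post-harvest agricultural seeds that become accessible as
snow melts off farmland (the *seed wave*). `wavetrack` asks, for a set of
GPS-tracked birds, which resource event best predicts the birds' arrival at
their stopover and breeding sites, and with what temporal lag.

The pipeline has five analysis stages plus a synthetic-data generator:

1. **Phenology retrieval**: per-pixel green-up day from 8-day
   vegetation-index (EVI) series, by the second-derivative method.
2. **Snowmelt phasing**: per-pixel three-piece segmented regression of
   daily snow-cover series, yielding the 25/50/75/100% melt dates used as
   relative seed-availability surrogates.
3. **Track processing**: day/night labelling by solar position,
   segmentation of fixes into residency sites (winter, stopovers,
   breeding), core-stopover filtering, migration summaries.
4. **Lag-scanned resource selection**: mixed-effects logistic RSF over
   candidate arrival days, scanned across integer temporal lags, with AIC
   model selection, a likelihood-based lag range, k-fold validation, and a
   cue-choice rule.
5. **Habitat use**: weekly daytime land-cover proportions, the
   habitat-switch week, and the farmland-to-natural foraging shift around
   local vegetation emergence (Welch's *t*).

## The selection model and the lag scan

For each site we build one presence row (the arrival day) and, by default,
10 absence rows (days drawn uniformly without replacement from Julian days
1–211, excluding the arrival day). Each row carries a mismatch
$m = \text{candidate day} - \text{resource date at the site's pixel}$ for
each of the five cues (green-up, d25, d50, d75, d100). For a lag $\ell$ and
$\Delta = m - \ell$ the model is

$$\Pr(\text{presence}) = \text{logit}^{-1}\!\left(\beta_0 + \beta_2
\Delta^2 + u_{\text{track}}\right),\qquad u_{\text{track}} \sim
N(0, \sigma^2),$$

fitted by Laplace approximation (`lme4::glmer`), falling back to the
fixed-effects fit when $\hat\sigma^2 < 10^{-8}$. The quadratic is concave
at any informative fit, so selection probability peaks at $\Delta = 0$,
i.e. at candidate days exactly $\ell$ days after the resource date.

**Why no linear term.** With a free linear term the quadratic
$\beta_0 + \beta_1\Delta + \beta_2\Delta^2$ can re-centre itself at any
lag: substituting $\Delta \mapsto \Delta - c$ only reparameterises
$(\beta_0,\beta_1,\beta_2)$, so the likelihood profile over lags is exactly
flat and the scan is unidentifiable (we verified this empirically before
pinning the peak). $\beta_0 + \beta_2\Delta^2$ is the minimal form that
makes the lag-scan procedure well-posed.

The scan grid spans the 10th–90th percentile of the presence-row
mismatches, padded by 5 days on each side; without the pad, a low-noise
cohort collapses the percentile interval to a point and the likelihood-drop
crossings could not be bracketed. The optimal lag minimises AIC (the
random-intercept variance counts as a parameter); the *range* is the pair
of linearly interpolated lags at which the log-likelihood falls 1 unit
below its maximum ($\Delta\text{AIC} = 2$), and the *difference* is the
range width.

**Sign conventions.** Internally a lag is "arrival day minus resource
date": positive means the bird arrives after the resource. Published
conventions differ (one common convention flips the sign so negative means
after); `lag_scan` objects therefore report `optimal_lag` (mismatch
scale), `lag_paper` (its negation) and `abs_lag`, and cue choice uses the
magnitude only.

## k-fold validation and cue choice

Validation folds split *tracks*, never rows, preserving the random-effect
structure. Held-out rows are scored on the fixed effects (a new track has
no estimated intercept, so validation refits are fixed-effects logistic
fits), scores are cut into 10 equal-width bins, and the per-bin
area-adjusted presence frequency (held-out presences in the bin divided by
all held-out rows in it, empty bins merged downwards) is rank-correlated
with bin order — a Boyce-style Spearman score $r_s$.

A single 5-fold split of this score is noisy: the binned frequencies are
coarse, and when a model is sharp, most presences land in the single top
bin so the score saturates. In simulation the expected $r_s$ does rank the
generating cue highest, but the margin over rival cues (≈0.03–0.06) is
smaller than the split-to-split standard deviation (≈0.07). `kfold_rs`
therefore averages 10 independent fold splits (repeated k-fold), which
leaves the expectation unchanged and shrinks the noise below the margin.
Even so, the *family* comparison below remains the least sharply
identified step of the pipeline, and we say so rather than overstating it.

`choose_cue` implements the two-step rule: the plant model wins if its
$r_s$ exceeds the mean $r_s$ of the four snowmelt models (uninformative
snow profiles excluded); if snowmelt wins, the specific cue is the phase
with the minimal $|\ell^*|$, ties broken towards the earlier phase. In
simulations the phase step is very reliable (the |lag| ordering separates
phases cleanly); the plant-vs-snow step operates on the thin $r_s$ margin
described above.

## Phenology retrieval

Green-up is the day maximising the discrete second derivative of the
smoothed daily EVI curve, restricted to the rising limb (start of series to
the day of the EVI maximum), with parabolic sub-day refinement of the
argmax; series with total range below 0.05 index units are flagged `flat`
(a noise-floor guard, exposed as a parameter). For a logistic rise with
midpoint $m$ and rate $b$ the continuous argmax is
$m - \ln(2+\sqrt{3})/b$, which is the closed-form oracle used throughout
the tests.

**Smoother choice.** The smoothing step is deliberately pluggable. The
default fits a rising four-parameter logistic by Levenberg–Marquardt and
evaluates it daily — the standard companion to curvature-based retrieval —
because generic filters cannot localise the curvature maximum of an
8-day-sampled spring rise to the ±2-day accuracy the rest of the pipeline
assumes: linear daily interpolation has curvature only at composite knots
(8-day resolution at best), and a 5-composite Savitzky–Golay window spans
33 days and shifts the curvature peak of a sharp rise by about −4 days. The
SG(5,2)+spline path is retained (`method = "sg"`) as a model-free fallback
for series that are not spring-rise shaped; it preserves constants and
reproduces quadratics exactly away from the reflected endpoints. With the
default smoother, noiseless detection is within 0.05 days of the closed
form and the mean absolute error over 500 pixels at noise sd 0.02 is about
1 day.

Retrieval runs only on *pure pixels* — cells whose herbaceous proportion
(wetland + grassland + shrubland) strictly exceeds 0.5.

## Snowmelt phasing

Each pixel's daily snow-cover series is fitted with a continuous
three-piece model: plateau $s_{\text{high}}$, linear decline on
$[t_1, t_2]$ (slope constrained ≤ 0), plateau $s_{\text{low}}$. Breakpoints
are found by exhaustive search over all integer day pairs $t_1 < t_2$;
conditional on the pair, the two remaining parameters are linear, so the
RSS is evaluated in closed form from cumulative sums (O(1) per pair —
about 22,000 pairs per pixel in milliseconds). Missing days are simply
omitted from the RSS; the outer segments are level plateaus (the
literature leaves this unstated; level plateaus are recorded in the fit
object). Series whose observed range is under 5 percent-points return a
`no_melt` sentinel. Ties in RSS break to the smallest $(t_1, t_2)$.

The phase dates follow from the fitted line: the day the curve has lost a
fraction $f$ of its melt range is $t_1 + f\,(t_2 - t_1)$, and $f = 1$
returns $t_2$ exactly; $s_{\text{low}}$ is not forced to zero, so "100%
melt" means reaching the low plateau. The fit is tested against an
independent brute-force enumeration (explicit basis construction + OLS per
pair); the two routes agree in argmin exactly and in RSS to $10^{-6}$
(they sum in different orders, so bit-identity is not a meaningful
target).

## Track segmentation

Sites are maximal runs of fixes that stay strictly within 50 km of the
run's incrementally updated centroid (a fix at exactly the radius closes
the run) and span at least 2 civil days *and* 24 h of elapsed time — the
elapsed-time condition stops a handful of midnight-straddling transit
fixes from counting as a 2-day stay. Civil dates use UTC+8 (the study
region; the time zone is not dictated by the data format). The first site
of the season is labelled winter, the last breeding. The published
analysis identified sites with a space-time scan statistic; this package
substitutes the centroid-radius rule because the operational criteria
(≥ 2 days, < 50 km) fully determine acceptance, and flags the method in
the output metadata. Core stopovers are those between 38.7° and 52° N
whose cumulative stay exceeds half the winter-departure-to-breeding-arrival
period. Migration distance is the haversine sum (R = 6371 km) over
consecutive site centroids.

## The synthetic generator and what it does (not) show

The generator is the package's ground-truth instrument, not a fixture: a
categorical landscape, EVI and snow raster series with recorded latent
truth, and migrating agents. The standard study conditions used by the
tests and the acceptance script are a 24 × 20 grid of 40-km pixels with
its south-west corner at 40° N 117° E (latitudes ≈40–48.7° N), default
curve parameters (EVI baseline 0.12, amplitude 0.4, spring midpoint day
100, rate 0.2 d⁻¹, noise sd 0.02; snow plateaus 95% → 0%, melt days 55–85,
noise sd 5%), a 3 d/° latitudinal delay on both waves, cohorts of 50
bird-year tracks, 2-h fixes, 0.5–1 km GPS jitter, 10 absence days per
site, and arrival-day noise of 0–1 days as each experiment states.

Two generator choices deserve emphasis:

* **Pixel-level phenological jitter** (sd 5 days on the EVI midpoint and
  independently on each snow breakpoint). Without idiosyncratic variation
  the five resource dates differ by pixel-constant offsets, every cue
  predicts arrivals equally well at a shifted lag, and cue identification
  is ill-posed for *any* method. Independent jitter on $t_1$ and $t_2$
  also decorrelates the four melt phases, which is what lets the
  minimal-|lag| rule find the exact generating phase.
* **Arrival semantics**: arrival day = cue date + lag + Gaussian noise,
  rounded half-up (daily resolution, matching migration-timing practice);
  the stopover stay extends until two travel days before breeding arrival;
  transit legs are interpolated but pulled back 60 km from each residency
  centroid so the 50-km residency radius never captures en-route fixes.

What passing on this generator does *not* show: robustness to cloud/QA
gaps and snow–cloud confusion in real imagery, to irregular fix schedules
and tag failure, to behavioural heterogeneity between individuals (the
random-intercept variance is essentially zero in simulation), or to
resource fields whose spatial structure is not latitude-plus-noise.
Real-data results additionally depend on land-cover accuracy, which the
generator idealises.

## Numerical choices and degenerate inputs

* Lag grids are integer days; percentile span padded ±5 days; profile
  crossings by linear interpolation, clamped to the grid edge when the
  profile never drops a full unit on one side (flagged `uninformative`
  when the whole profile spans < 0.5).
* Quasi-separated designs (zero lag noise) are expected: fits that reach
  the iteration limit are kept with a warning, since AIC ordering — not
  coefficient scale — drives the scan.
* `glmer` runs with `calc.derivs = FALSE` (the scan needs likelihoods,
  not Wald standard errors).
* Three-piece fits require ≥ 20 non-missing days; `welch_t` with two
  zero-variance samples returns t = 0 (equal means) or ±∞ (unequal) with
  pooled df.
* All generators are seeded and bit-reproducible; every recovery test
  reads truth only from the generator's truth table.

## Problem sizes

The test-suite and acceptance-script experiment sizes — 480-pixel rasters,
50-track cohorts, 10 replicates per generating cue, 50 calibration
replicates over true lags −10…10 — were chosen as the smallest sizes at
which the binomial/simulation bounds quoted in the tests are comfortably
stable.

## Known limitations

* The plant-vs-snowmelt family decision rests on a validation score with
  intrinsically weak signal when all candidate cues are spatially
  correlated; treat single-cohort family assignments as evidence, not
  verdicts.
* The RSF is temporal only: space enters through each site's pixel, and
  no step-selection or availability-field structure is modelled.
* One covariate family (resource mismatch) — no weather, photoperiod or
  density effects.
* The solar calculator implements the NOAA Fourier-series algorithm
  (minute-level accuracy), not an ephemeris.
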