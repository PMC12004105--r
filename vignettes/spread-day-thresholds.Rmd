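---
title: "Estimating fire-weather thresholds for wildfire spread days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fire-weather thresholds for wildfire spread days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadday)
```

## The problem

Wildfires burn most of their area on a handful of *spread days* — days of
severe fire weather on which a fire grows substantially. A practical
threshold separating spread-day weather from ordinary weather is valuable
for fire management, but fire growth occurs across a gradient of
conditions, so any crisp threshold must be defined statistically. The
definition implemented here: for each Canadian Fire Weather Index (FWI)
System variable, **the index value below which half of the total burned
area accumulated**. Because burned area along an index axis is roughly
bell-shaped, the 50% crossing of the cumulative area-burned curve sits at
the mode of that bell and is a natural spread-day identifier.

The pipeline has five stages, each usable on its own:

1. **FWI System engine** (`fwi_calc()`): the six daily indices — FFMC, DMC,
   DC (fuel-moisture codes) and ISI, BUI, FWI (behaviour indices) — from
   noon temperature, relative humidity, 10 m wind and 24 h precipitation.
2. **Daily growth delineation** (`map_daily_growth()`): the final fire
   perimeter is rasterized and every cell is dated from satellite hotspots.
3. **Weather pairing** (`pair_daily_growth()`): coarse gridded indices are
   downscaled to the growth footprint by regression kriging on elevation
   and aggregated (means; the median for FWI).
4. **Threshold estimation** (`threshold_at_half()`,
   `resample_thresholds()`): the 50% crossing of a spline-smoothed
   cumulative area-burned curve, resampled over years.
5. **Percentile and spread-day accounting**
   (`percentile_of_threshold()`, `area_above_percentiles()`,
   `count_psd()`/`count_rsd()`): how extreme the thresholds are, and what
   fraction of *potential* spread days (PSD: days whose weather exceeds the
   threshold) are *realized* (RSD: mapped growth days exceeding it).

## The threshold model

Let rows $(x_i, a_i)$ be paired growth days: index value $x_i$, burned
area $a_i$ (ha). The empirical cumulative area fraction is

$$F(x) = \frac{\sum_{i : x_i \le x} a_i}{\sum_i a_i}.$$

`cumulative_smooth()` fits a penalized regression spline (basis dimension
10, smoothness chosen by GCV, via **mgcv**) to the step heights of $F$,
projects the fit onto a monotone curve (isotonic regression over a
1000-point grid), and `threshold_at_half()` returns the smallest $x$ with
$\hat F(x) \ge 0.5$, linearly interpolated between grid points and clamped
to the observed range. Step heights are taken at the midpoint of each mass
step, so the degenerate two-point case (equal areas at 80 and 90) gives
85, matching the area-weighted median oracle `weighted_quantile()`.

Uncertainty follows the study design rather than an analytic formula:
each of 100 replicates pools 10 of the 21 available years (drawn uniformly
without replacement) and re-estimates the threshold; the mean and sample
(n−1) s.d. across replicates are reported. One RNG stream per
(variable, stratum) is derived from the master seed, so estimates do not
depend on evaluation order. Strata with fewer than 30 rows, or fewer
distinct years than the replicate size, are flagged rather than dropped.

## Choices made where the design was open

* **Smoother target.** The spline is fit to the cumulative fraction as a
  function of the index value (not to a binned density later integrated);
  the cumulative reading is the direct transcription of "accumulated area
  burned along the variable" and makes the 50% crossing well-defined.
* **Non-monotone fits.** GCV smoothing of a noisy cumulative curve can
  wiggle; isotonic projection before root-finding guarantees a unique
  first crossing. The crossing is located on a fixed 1000-point grid with
  linear interpolation — deterministic and resolution-limited to 0.1% of
  the observed range.
* **Few distinct values.** Below five distinct index values a spline has
  nothing to smooth; the empirical midpoint interpolant is used directly.
* **Percentile convention.** Type-7 plotting positions $(j-1)/(n-1)$ with
  linear interpolation; ties take the midpoint of their rank range, so a
  fully tied sample ranks its own value at the 50th percentile.
  Percentiles are computed over the paired growth-day values, unweighted:
  area enters only through the cumulative curve.
* **Table summary rows.** Ecozone threshold tables summarize as the mean
  of the per-ecozone means and the mean of the per-ecozone s.d.s; the
  percentile table uses the population (denominator $n$) s.d. of the
  per-ecozone values. These conventions reproduce the packaged reference
  rows (`reference_tables()`) exactly.
* **Exceedance is strict** (`> threshold`) in PSD/RSD counting, the PSD
  window is the fire's calendar year (an April–October window is available
  behind a flag), and the per-day spatial aggregate over a fire's grid
  points follows the pairing rule (means; median for FWI).
* **Kriging.** The variogram is fitted by weighted least squares
  (weights $N_j/h_j^2$) over spherical, exponential and Gaussian models;
  failure (non-convergence, non-positive partial sill, or fewer than three
  usable bins) triggers a deterministic fallback — elevation trend plus
  inverse-distance-weighted residuals — which is logged. Grid points are
  selected within 50 km of the footprint, extended to 200 km when fewer
  than four support the model. With a zero nugget at distance zero the
  kriging predictor is exact at source points.
* **FWI engine.** The 1987 daily-update structure with the standard
  constant set and mid-latitude monthly day-length factors; startup codes
  FFMC 85, DMC 6, DC 15; each calendar year restarts from startup (no
  Drought Code overwintering — no overwintering rule is part of the
  design). Latitude-banded day-length tables sit behind `lat_adjust`.

## What the synthetic generator emulates

`generate_study()` produces every input the pipeline consumes, with known
ground truth:

* **Weather** (21 years from 2001 by default, 365-day years): seasonal
  sinusoids with AR(1) residuals for temperature and humidity, gamma wind,
  intermittent gamma precipitation. Defaults give boreal-plausible summer
  conditions (FFMC covering roughly 60–96 in season).
* **Fires**: circular, grown as one annulus per growth day (3–10 days,
  lognormal daily areas with a median near 150 ha, total ≥ 50 ha). Each
  growth day is matched to a season day whose value of the target variable
  is closest to a draw from a Gaussian centred on the configured
  threshold (default FFMC 89, s.d. 3), truncated symmetrically to the
  variable's in-season range. Areas are independent of the index, so the
  centre is the exact area-weighted median — the true threshold — by
  construction. The matching step leaves a small noise band between the
  drawn target and the day's actual value.
* **Hotspots**: at least one per growth day, Poisson counts at the
  configured density, placed in the day's annulus with a mid-annulus
  radial bias (detections cluster in the actively burning band).
* **Grids**: `generate_fwi_grid()` adds a linear elevation trend and a
  smooth spatial field to the daily series over a synthetic elevation
  surface, for the downscaling stage.

What it does **not** emulate: fire-spread physics, irregular fire shapes,
spatial covariance of real reanalysis products, detection gaps and cloud
obscuration, or any joint growth–weather distribution beyond the
stipulated area density. Passing tests therefore demonstrate that the
*algorithms* recover known structure, not that the defaults describe any
particular landscape.

Problem sizes used in the tests and the reproduction script were chosen to
make every stage's behaviour measurable at desk scale: threshold-recovery
runs use 21 years × 40 fires (≈ 5400 paired rows, recovery within 0.5
FFMC units of truth; observed mean absolute error is under 0.1),
delineation oracles use 100 m cells, and the cell-date-recovery property
uses a delineation-friendly configuration (3 growth days, 30 hotspots per
km²) — with sparse, MODIS-like densities the nearest-hotspot dating
accuracy drops well below 90%, which is a property of the data, not the
algorithm.

## Known limitations

* The delineation is the nearest-hotspot core of the source technique (an
  IDW-smoothed day surface is available); interior regions without
  hotspots inherit dates from the nearest detection however far.
* Kriging is isotropic and per-day; no temporal pooling, no anisotropy,
  no kriging-variance maps.
* The engine's day-length factors are monthly tables; sub-monthly latitude
  effects are ignored unless `lat_adjust` is set.
* Reported thresholds are descriptive statistics of where area burned;
  they are not switch values, and nothing here models ignition or
  suppression.
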