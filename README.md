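# spreadday

Fire-weather thresholds for wildfire **spread days** — the days on which
fires grow by substantial area. Most of a fire's area burns on a few such
days, and they cluster under severe fire weather, but there is no agreed
cut-off separating spread-day weather from ordinary weather. `spreadday`
implements a data-driven definition: for each Canadian Fire Weather Index
(FWI) System variable, **the index value below which 50% of the total area
burned** — the crossing point of the smoothed cumulative area-burned curve
along that variable.

For paired growth days \((x_i, a_i)\) (index value, burned area), the
cumulative area fraction
\(F(x) = \sum_{x_i \le x} a_i / \sum_i a_i\)
is smoothed with a penalized regression spline (GCV smoothness, isotonic
projection), and the threshold is the smallest \(x\) with
\(\hat F(x) \ge 0.5\). Uncertainty comes from the study design: 100
replicates, each pooling 10 of the 21 available years, give the reported
mean (s.d.). Downstream, the package ranks thresholds as percentiles of
the paired fire-weather distribution, computes area burned above
percentile cut-offs, and counts **potential spread days** (PSD — days
whose weather exceeds the threshold) versus **realized spread days** (RSD
— mapped growth days exceeding it).

The full pipeline is self-contained, from raw inputs to the statistic:

| stage | functions |
|---|---|
| six daily FWI System indices from noon weather | `fwi_calc()`, `fwi_step()`, `fwi_init()` |
| daily growth mapping from perimeter + hotspots | `map_daily_growth()` |
| pairing growth with downscaled gridded weather | `select_grid_points()`, `downscale()`, `pair_daily_growth()` |
| 50%-area thresholds with year resampling | `cumulative_smooth()`, `threshold_at_half()`, `resample_thresholds()` |
| percentile analysis | `percentile_of_threshold()`, `area_above_percentiles()` |
| PSD/RSD accounting | `count_psd()`, `count_rsd()`, `ratio_and_summaries()` |
| synthetic studies with known true thresholds | `synth_config()`, `generate_study()` |

Ecozone-level reference summaries for Canadian fires (≥ 50 ha, 2001–2021,
11 ecozones with Taiga Shield and Boreal Shield split west/east) ship with
the package: `reference_tables()`.

## Worked example

A small synthetic study whose true FFMC threshold is 89 by construction:

```r
library(spreadday)

st <- generate_study(synth_config(n_years = 5, n_fires_per_year = 8,
                                  seed = 11))
nrow(st$growth)              # 255 paired growth days

threshold_at_half(st$growth, "ffmc")
#> [1] 89.14

resample_thresholds(st$growth, "ffmc",
                    config = resample_config(n_reps = 100,
                                             years_per_rep = 3, seed = 11))
#>   variable  stratum  mean     sd n_reps_used n_rows flag
#> 1     ffmc national 89.06 0.2614         100    255
```

The point estimate (89.14) and the resampled mean (89.06 ± 0.26) recover
the generated truth to well within the replicate spread. How extreme is
that threshold within spread-day weather, and how much of the potential
does a fire typically use?

```r
percentile_of_threshold(st$growth$ffmc, 89.14)
#> [1] 48.6      # the threshold sits near the median of growth-day weather

acc <- spread_day_accounts(st$growth, st$fwi, c(ffmc = 89.14), "ffmc")
ratio_and_summaries(acc)$summary
#>   variable threshold_source mean   sd n_ecozones
#> 1     ffmc         national 9.63 5.04         11
```

On average a synthetic fire realizes ~10% of its year's potential spread
days — fires are short; fire-conducive weather is not.

The packaged reference rows reproduce their published summary lines
exactly:

```r
ref <- reference_tables()
round(mean(ref$thresholds$ffmc_mean), 1)  #> 89.1
round(mean(ref$rsd_psd$ez_fwi_mean), 1)   #> 30.4
```

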