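# Percentile analysis: how extreme the spread-day thresholds are within the
# paired fire-weather distribution, and area burned above percentile
# cut-offs.

#' Percentile ladder
#'
#' The default ladder runs from the 50th to the 95th percentile in steps of
#' 5, plus the 99th.
#'
#' @param percentiles strictly increasing values in (0, 100).
#' @return validated numeric vector.
#' @export
percentile_ladder <- function(percentiles = c(seq(50, 95, by = 5), 99)) {
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) ||
      any(percentiles >= 100))
    stop("percentiles must be strictly increasing and inside (0, 100)")
  percentiles
}

#' Percentile rank of a threshold in the paired distribution
#'
#' Empirical cumulative fraction of the paired (unweighted) index values at
#' the threshold, linearly interpolated between order statistics (the
#' "type 7" plotting positions `(j-1)/(n-1)`), times 100. Tied values take
#' the midpoint of their rank range, so a completely tied sample evaluated
#' at its own value returns 50. Thresholds outside the observed range clamp
#' to 0 or 100 with a `clamped` flag.
#'
#' @param values numeric index values of the paired rows (length >= 2).
#' @param threshold index value to rank.
#' @return percentile in `[0, 100]` with attribute `clamped`.
#' @export
#' @examples
#' percentile_of_threshold(1:100, 64.5)  # 64.1
percentile_of_threshold <- function(values, threshold) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  xs <- sort(values)
  pos <- (seq_len(n) - 1) / (n - 1)
  pos_u <- tapply(pos, xs, mean)          # midpoint of tied rank range
  vu <- as.numeric(names(pos_u))
  clamped <- FALSE
  if (length(vu) == 1L) {
    out <- if (threshold < vu) 0 else if (threshold > vu) 100 else 50
    clamped <- threshold != vu
  } else if (threshold <= vu[1]) {
    out <- if (threshold < vu[1]) 0 else 100 * pos_u[[1]]
    clamped <- threshold < vu[1]
  } else if (threshold >= vu[length(vu)]) {
    out <- if (threshold > vu[length(vu)]) 100 else
      100 * pos_u[[length(vu)]]
    clamped <- threshold > vu[length(vu)]
    if (threshold == vu[length(vu)]) out <- 100 * pos_u[[length(vu)]]
  } else {
    out <- 100 * approx(vu, as.numeric(pos_u), xout = threshold,
                        ties = "ordered")$y
  }
  # the maximum observed value ranks 100 unless tied
  if (threshold > vu[length(vu)]) out <- 100
  attr(out, "clamped") <- clamped
  out
}

#' Percentage of area burned above percentile cut-offs
#'
#' Per year-resampling replicate: the variable's p-th percentile value over
#' the replicate's (unweighted) rows is located, the smoothed cumulative
#' area-burned curve is evaluated there, and `100 * (1 - fraction)` is
#' reported; the mean and s.d. over replicates are returned for each rung
#' of the ladder. Percentiles are unweighted; area enters only through the
#' cumulative curve.
#'
#' @param rows paired rows (`year`, `area`, the variable column).
#' @param variable index column name.
#' @param ladder a [percentile_ladder()].
#' @param config a [resample_config()]; the RNG stream is salted with the
#'   variable name so it matches [resample_thresholds()] replicates.
#' @param stratum label used to salt the RNG stream.
#' @return data frame: `variable`, `percentile`, `mean`, `sd` (percent of
#'   total area burned above that percentile's value).
#' @export
area_above_percentiles <- function(rows, variable,
                                   ladder = percentile_ladder(),
                                   config = resample_config(),
                                   stratum = "national") {
  years <- sort(unique(rows$year))
  seed <- derive_seed(config$seed, paste("area", variable, stratum,
                                         sep = "|"))
  one_rep <- function(rr) {
    cs <- cumulative_smooth(rr, variable, k = config$k)
    q <- quantile(rr[[variable]], ladder / 100, type = 7, names = FALSE)
    100 * (1 - predict(cs, q))
  }
  if (length(years) < config$years_per_rep) {
    m <- one_rep(rows)
    return(data.frame(variable = variable, percentile = ladder,
                      mean = m, sd = NA_real_))
  }
  reps <- with_seed(seed, {
    vapply(seq_len(config$n_reps), function(r) {
      ys <- sample(years, config$years_per_rep)
      one_rep(rows[rows$year %in% ys, , drop = FALSE])
    }, numeric(length(ladder)))
  })
  reps <- matrix(reps, nrow = length(ladder))
  data.frame(variable = variable, percentile = ladder,
             mean = apply(reps, 1, mean), sd = apply(reps, 1, sd))
}

#' Percentile-table summary row: column mean and population s.d.
#'
#' The summary row of an ecozone percentile table: per variable, the
#' arithmetic mean over ecozones and the population standard deviation
#' (denominator n), rounded to 1 decimal for display.
#'
#' @param tab data frame of per-ecozone percentiles: one row per ecozone,
#'   one numeric column per variable (non-numeric columns ignored).
#' @return data frame: `variable`, `mean`, `sd`.
#' @export
summarize_percentile_table <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1))
  vs <- names(tab)[num]
  if (nrow(tab) < 2) stop("need at least 2 ecozones")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(variable = vs,
             mean = vapply(vs, function(v) round(mean(tab[[v]]), 1),
                           numeric(1)),
             sd = vapply(vs, function(v) round(pop_sd(tab[[v]]), 1),
                         numeric(1)),
             row.names = NULL)
}
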