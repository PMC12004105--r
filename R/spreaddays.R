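# Potential vs realized spread-day accounting: PSD counts from weather
# series, RSD counts from mapped growth, RSD/PSD ratios by stratum.

#' Daily spatial aggregate of a fire's grid-point series
#'
#' Collapses the fire's selected grid points to one value per day:
#' the mean across points for FFMC/DMC/DC/ISI/BUI, the median for FWI
#' (consistent with the footprint pairing rule).
#'
#' @param grid long table of the fire's grid points (`date` plus index
#'   columns).
#' @param variable index column name.
#' @return data frame: `date`, `value`.
#' @export
aggregate_grid_daily <- function(grid, variable) {
  f <- if (variable == "fwi") median else mean
  agg <- tapply(grid[[variable]], as.character(as.Date(grid$date)), f)
  data.frame(date = as.Date(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}

#' Count potential spread days (PSD)
#'
#' Days in the counting window whose aggregated index value strictly
#' exceeds the threshold. The window is the fire's calendar year by
#' default; a fire-season window (April–October) is available behind a
#' flag for sensitivity checks.
#'
#' @param daily data frame `date`, `value` (see [aggregate_grid_daily()]).
#' @param year calendar year of the fire.
#' @param threshold index threshold.
#' @param window `"annual"` (default) or `"fire_season"` (Apr–Oct).
#' @return integer count.
#' @export
count_psd <- function(daily, year, threshold,
                      window = c("annual", "fire_season")) {
  window <- match.arg(window)
  if (is.null(daily) || nrow(daily) == 0)
    stop("accounting error: empty weather series")
  d <- as.Date(daily$date)
  keep <- as.integer(format(d, "%Y")) == year
  if (window == "fire_season")
    keep <- keep & as.integer(format(d, "%m")) %in% 4:10
  sum(daily$value[keep] > threshold)
}

#' Count realized spread days (RSD)
#'
#' Mapped growth days of one fire whose paired index value strictly exceeds
#' the threshold.
#'
#' @param fire_rows paired rows of one fire.
#' @param variable index column name.
#' @param threshold index threshold.
#' @return integer count.
#' @export
count_rsd <- function(fire_rows, variable, threshold) {
  if (nrow(fire_rows) == 0) stop("fire has no growth days")
  sum(fire_rows[[variable]] > threshold)
}

#' Per-fire spread-day accounts
#'
#' Builds one account row per fire × variable: PSD from the fire's daily
#' grid aggregate, RSD from its paired growth days, and their ratio
#' (`NA`, flagged, when PSD is 0). Thresholds may be national (one value
#' per variable) or per-ecozone (a data frame with an `ecozone` column and
#' one column per variable). Accounting is per variable; no joint
#' multi-variable rule is applied.
#'
#' @param paired paired growth table (`fire_id`, `year`, `ecozone`, index
#'   columns).
#' @param daily_series list keyed by `fire_id`, each a long table of that
#'   fire's grid points (`date` + index columns) covering the counting
#'   window, or a single table used for all fires.
#' @param thresholds named numeric (national), e.g.
#'   `c(ffmc = 89.4, isi = 7.5, fwi = 20.1)`, or per-ecozone data frame.
#' @param variables variables to account (default the fast-reacting three:
#'   FFMC, ISI, FWI).
#' @param threshold_source label recorded in the output (`"national"` or
#'   `"ecozone"`).
#' @param window passed to [count_psd()].
#' @return data frame: `fire_id`, `year`, `ecozone`, `variable`,
#'   `threshold_source`, `threshold`, `psd`, `rsd`, `ratio`.
#' @export
spread_day_accounts <- function(paired, daily_series, thresholds,
                                variables = c("ffmc", "isi", "fwi"),
                                threshold_source = "national",
                                window = "annual") {
  fires <- unique(paired$fire_id)
  per_ecozone <- is.data.frame(thresholds)
  out <- list()
  for (f in fires) {
    rows <- paired[paired$fire_id == f, , drop = FALSE]
    year <- rows$year[1]
    ez <- rows$ecozone[1]
    series <- if (is.data.frame(daily_series)) daily_series else
      daily_series[[f]]
    for (v in variables) {
      thr <- if (per_ecozone) {
        i <- match(ez, thresholds$ecozone)
        if (is.na(i)) stop("no threshold for ecozone ", ez)
        thresholds[[v]][i]
      } else unname(thresholds[[v]])
      psd <- count_psd(aggregate_grid_daily(series, v), year, thr,
                       window = window)
      rsd <- count_rsd(rows, v, thr)
      out[[length(out) + 1L]] <- data.frame(
        fire_id = f, year = year, ecozone = ez, variable = v,
        threshold_source = threshold_source, threshold = thr,
        psd = psd, rsd = rsd,
        ratio = if (psd > 0) rsd / psd else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' RSD/PSD ratio summaries by stratum
#'
#' Per-fire ratios (fires with PSD = 0 are excluded and counted) are
#' summarized as percentages: mean and sample s.d. per ecozone × variable ×
#' threshold source, plus a summary row per variable — the column mean over
#' ecozones of the per-ecozone means (and of the per-ecozone s.d.s). The
#' raw ratio vectors are returned for density plots.
#'
#' @param accounts data frame from [spread_day_accounts()].
#' @return list: `by_ecozone` (mean/sd % per stratum), `summary` (column
#'   means over ecozones), `ratios` (per-fire ratios with labels),
#'   `n_zero_psd` (excluded fires logged).
#' @export
ratio_and_summaries <- function(accounts) {
  zero <- is.na(accounts$ratio)
  n_zero <- sum(zero)
  acc <- accounts[!zero, , drop = FALSE]
  if (nrow(acc) == 0) stop("no fires with psd > 0")
  key <- interaction(acc$ecozone, acc$variable, acc$threshold_source,
                     drop = TRUE)
  by_ez <- do.call(rbind, lapply(split(acc, key), function(d) {
    data.frame(ecozone = d$ecozone[1], variable = d$variable[1],
               threshold_source = d$threshold_source[1],
               mean = 100 * mean(d$ratio),
               sd = 100 * sd(d$ratio),
               n_fires = nrow(d))
  }))
  rownames(by_ez) <- NULL
  key2 <- interaction(by_ez$variable, by_ez$threshold_source, drop = TRUE)
  summary <- do.call(rbind, lapply(split(by_ez, key2), function(d) {
    data.frame(variable = d$variable[1],
               threshold_source = d$threshold_source[1],
               mean = mean(d$mean), sd = mean(d$sd, na.rm = TRUE),
               n_ecozones = nrow(d))
  }))
  rownames(summary) <- NULL
  list(by_ecozone = by_ez, summary = summary,
       ratios = acc[, c("fire_id", "ecozone", "variable",
                        "threshold_source", "ratio")],
       n_zero_psd = n_zero)
}
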