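# Canadian Forest Fire Weather Index System: the six daily indices from
# noon weather. Structure and constants follow the 1987 system definition
# (FF-scale FFMC; standard monthly day-length factors for ~46.5 N).

# DMC effective day-length factors and DC day-length adjustments, by month.
.DMC_EL <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
.DC_FL <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)

.day_length_factors <- function(mon, lat, lat_adjust) {
  el <- .DMC_EL; fl <- .DC_FL
  if (lat_adjust) {
    if (abs(lat) <= 15) {
      # near-equatorial: effectively constant day length
      el <- rep(9, 12); fl <- rep(1.4, 12)
    } else if (lat < 0) {
      shift <- c(7:12, 1:6)
      el <- el[shift]; fl <- fl[shift]
    }
  }
  list(el = el[mon], fl = fl[mon])
}

.check_weather <- function(temp, rh, ws, prec) {
  if (any(!is.finite(temp))) stop("weather validation: 'temp' must be finite")
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100))
    stop("weather validation: 'rh' must lie in [0, 100]")
  if (any(!is.finite(ws)) || any(ws < 0))
    stop("weather validation: 'ws' must be >= 0")
  if (any(!is.finite(prec)) || any(prec < 0))
    stop("weather validation: 'prec' must be >= 0")
  invisible(TRUE)
}

#' Startup values for the three FWI System moisture codes
#'
#' Returns the conventional spring startup triple FFMC = 85, DMC = 6,
#' DC = 15, or user overrides. Each year of a multi-year run is restarted
#' from these codes (no overwintering of the Drought Code).
#'
#' @param ffmc,dmc,dc optional overrides for the startup codes.
#' @return a list with elements `ffmc`, `dmc`, `dc`.
#' @export
#' @examples
#' fwi_init()            # the documented defaults
#' fwi_init(85, 6, 15)   # identical, explicit
fwi_init <- function(ffmc = 85, dmc = 6, dc = 15) {
  if (!is.finite(ffmc) || ffmc < 0 || ffmc > 101)
    stop("startup validation: 'ffmc' must lie in [0, 101]")
  if (!is.finite(dmc) || dmc < 0)
    stop("startup validation: 'dmc' must be >= 0")
  if (!is.finite(dc) || dc < 0)
    stop("startup validation: 'dc' must be >= 0")
  list(ffmc = ffmc, dmc = dmc, dc = dc)
}

#' One daily FWI System update
#'
#' Advances the three moisture codes by one day of noon weather (rain phase
#' then drying/wetting, month-dependent day-length factors) and derives the
#' three behaviour indices: ISI from FFMC and wind, BUI from DMC and DC,
#' FWI from ISI and BUI.
#'
#' @param prev list with yesterday's `ffmc`, `dmc`, `dc` (see [fwi_init()]).
#' @param temp noon screen-level air temperature, deg C.
#' @param rh noon relative humidity, percent in \[0, 100\].
#' @param ws noon 10 m open wind speed, km/h.
#' @param prec 24 h accumulated precipitation, mm.
#' @param mon month 1–12 (selects day-length factors).
#' @param lat latitude in degrees, used only when `lat_adjust = TRUE`.
#' @param lat_adjust use latitude-banded day-length factors instead of the
#'   standard mid-latitude tables. Default `FALSE`.
#' @return list with `ffmc`, `dmc`, `dc`, `isi`, `bui`, `fwi`.
#' @export
fwi_step <- function(prev, temp, rh, ws, prec, mon, lat = 46.5,
                     lat_adjust = FALSE) {
  if (is.null(prev$ffmc) || is.null(prev$dmc) || is.null(prev$dc))
    stop("startup error: previous codes missing; build them with fwi_init()")
  .check_weather(temp, rh, ws, prec)
  if (!mon %in% 1:12) stop("weather validation: 'mon' must be 1..12")
  dl <- .day_length_factors(mon, lat, lat_adjust)

  # -- FFMC -----------------------------------------------------------------
  wmo <- 147.2 * (101 - prev$ffmc) / (59.5 + prev$ffmc)
  if (prec > 0.5) {
    ra <- prec - 0.5
    corr <- 42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra))
    wmo <- wmo + corr + if (wmo > 150) 0.0015 * (wmo - 150)^2 * sqrt(ra) else 0
    wmo <- min(wmo, 250)
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  if (wmo > ed) {
    z <- 0.424 * (1 - (rh / 100)^1.7) + 0.0694 * sqrt(ws) * (1 - (rh / 100)^8)
    wm <- ed + (wmo - ed) * 10^(-z * 0.581 * exp(0.0365 * temp))
  } else {
    ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
      0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
    if (wmo < ew) {
      z <- 0.424 * (1 - ((100 - rh) / 100)^1.7) +
        0.0694 * sqrt(ws) * (1 - ((100 - rh) / 100)^8)
      wm <- ew - (ew - wmo) * 10^(-z * 0.581 * exp(0.0365 * temp))
    } else {
      wm <- wmo
    }
  }
  ffmc <- min(max(59.5 * (250 - wm) / (147.2 + wm), 0), 101)

  # -- DMC ------------------------------------------------------------------
  rk <- 1.894 * (max(temp, -1.1) + 1.1) * (100 - rh) * dl$el * 1e-4
  if (prec > 1.5) {
    rw <- 0.92 * prec - 1.27
    wmi <- 20 + 280 / exp(0.023 * prev$dmc)
    b <- if (prev$dmc <= 33) 100 / (0.5 + 0.3 * prev$dmc)
         else if (prev$dmc <= 65) 14 - 1.3 * log(prev$dmc)
         else 6.2 * log(prev$dmc) - 17.2
    wmr <- wmi + 1000 * rw / (48.77 + b * rw)
    pr <- 43.43 * (5.6348 - log(wmr - 20))
  } else {
    pr <- prev$dmc
  }
  dmc <- max(pr, 0) + rk

  # -- DC -------------------------------------------------------------------
  pe <- max((0.36 * (max(temp, -2.8) + 2.8) + dl$fl) / 2, 0)
  if (prec > 2.8) {
    rw <- 0.83 * prec - 1.27
    smi <- 800 * exp(-prev$dc / 400)
    dr <- max(prev$dc - 400 * log(1 + 3.937 * rw / smi), 0)
    dc <- dr + pe
  } else {
    dc <- prev$dc + pe
  }
  dc <- max(dc, 0)

  # -- behaviour indices ----------------------------------------------------
  fm <- 147.2 * (101 - ffmc) / (59.5 + ffmc)
  isi <- 0.208 * exp(0.05039 * ws) *
    (91.9 * exp(-0.1386 * fm) * (1 + fm^5.31 / 4.93e7))
  bui <- if (dmc == 0 && dc == 0) 0 else if (dmc <= 0.4 * dc)
    0.8 * dmc * dc / (dmc + 0.4 * dc)
  else
    dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) * (0.92 + (0.0114 * dmc)^1.7)
  bui <- max(bui, 0)
  fd <- if (bui > 80) 1000 / (25 + 108.64 * exp(-0.023 * bui)) else
    0.626 * bui^0.809 + 2
  bb <- 0.1 * isi * fd
  fwi <- if (bb > 1) exp(2.72 * (0.434 * log(bb))^0.647) else bb

  list(ffmc = ffmc, dmc = dmc, dc = dc, isi = isi, bui = bui, fwi = fwi)
}

#' FWI System indices for a daily weather series
#'
#' Runs the daily update over a weather table. Each calendar year is
#' restarted from the startup codes (no Drought Code overwintering), the
#' usual convention for snow-covered winters.
#'
#' @param wx data frame with columns `date` (Date), `temp`, `rh`, `ws`,
#'   `prec` (units as in [fwi_step()]).
#' @param init startup codes, see [fwi_init()].
#' @param lat,lat_adjust passed to [fwi_step()].
#' @param restart_each_year logical; restart codes every January 1st
#'   (default `TRUE`).
#' @return data frame: `date`, `ffmc`, `dmc`, `dc`, `isi`, `bui`, `fwi`.
#' @export
#' @examples
#' wx <- data.frame(date = as.Date("2021-07-01") + 0:4,
#'                  temp = c(22, 25, 27, 24, 18), rh = c(40, 35, 30, 45, 70),
#'                  ws = c(12, 15, 20, 10, 8), prec = c(0, 0, 0, 0, 6))
#' fwi_calc(wx)
fwi_calc <- function(wx, init = fwi_init(), lat = 46.5, lat_adjust = FALSE,
                     restart_each_year = TRUE) {
  need <- c("date", "temp", "rh", "ws", "prec")
  if (!all(need %in% names(wx)))
    stop("weather table must have columns: ", paste(need, collapse = ", "))
  wx <- wx[order(as.Date(wx$date)), , drop = FALSE]
  .check_weather(wx$temp, wx$rh, wx$ws, wx$prec)
  dates <- as.Date(wx$date)
  mons <- as.integer(format(dates, "%m"))
  yrs <- as.integer(format(dates, "%Y"))
  n <- nrow(wx)
  out <- matrix(NA_real_, n, 6)
  prev <- init
  for (i in seq_len(n)) {
    if (restart_each_year && i > 1 && yrs[i] != yrs[i - 1]) prev <- init
    v <- fwi_step(prev, wx$temp[i], wx$rh[i], wx$ws[i], wx$prec[i], mons[i],
                  lat = lat, lat_adjust = lat_adjust)
    out[i, ] <- unlist(v)
    prev <- v
  }
  res <- data.frame(date = dates, out)
  names(res) <- c("date", "ffmc", "dmc", "dc", "isi", "bui", "fwi")
  res
}

#' The six FWI System variable names
#' @return character vector `c("ffmc","dmc","dc","isi","bui","fwi")`.
#' @export
fwi_variables <- function() c("ffmc", "dmc", "dc", "isi", "bui", "fwi")
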