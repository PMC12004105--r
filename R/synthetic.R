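# Synthetic study generator: multi-year daily weather and FWI series,
# circular fires grown as daily annuli, hotspot scatters, and paired
# growth/weather rows whose burned-area density along one index variable is
# Gaussian around a configurable centre — making that centre the true
# 50%-area spread-day threshold by construction.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the real study frame: 21 fire seasons starting in 2001
#' and the 11 ecozone strata used for Canadian fire analysis (Taiga Shield
#' and Boreal Shield split west/east).
#'
#' @param n_years number of years (>= 2; default 21).
#' @param year_start first year (default 2001).
#' @param n_fires_per_year fires generated per year (default 12).
#' @param ecozone_labels stratum labels cycled over fires.
#' @param true_threshold named value: the index variable the area density is
#'   centred on and its centre, e.g. `c(ffmc = 89)`. The centre is the true
#'   50%-area threshold.
#' @param threshold_sd width (s.d.) of the Gaussian burned-area density
#'   along the index axis, in index units.
#' @param area_distribution lognormal parameters for daily growth areas in
#'   hectares: `list(meanlog, sdlog)`.
#' @param growth_days integer range `c(min, max)` of growth days per fire.
#' @param weather_model seasonal-cycle and AR(1) parameters per weather
#'   element; see the defaults for the recognised names.
#' @param hotspot_density expected hotspots per km2 of daily growth (> 0).
#' @param hotspot_jitter logical: add ±1 day of dating noise to hotspots
#'   (default `FALSE`).
#' @param seed RNG seed; identical seed and config give identical output.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_years = 21,
                         year_start = 2001,
                         n_fires_per_year = 12,
                         ecozone_labels = c("TP", "TSW", "BSW", "BP", "TC",
                                            "BC", "PM", "MC", "HP", "BSE",
                                            "TSE"),
                         true_threshold = c(ffmc = 89),
                         threshold_sd = 3,
                         area_distribution = list(meanlog = log(150),
                                                  sdlog = 0.7),
                         growth_days = c(3L, 10L),
                         weather_model = list(temp_mean = 8, temp_amp = 16,
                                              temp_ar1 = 0.6, temp_sd = 3.5,
                                              rh_mean = 62, rh_amp = 20,
                                              rh_ar1 = 0.5, rh_sd = 9,
                                              ws_shape = 3, ws_scale = 4,
                                              wet_prob = 0.3,
                                              prec_shape = 0.6,
                                              prec_scale = 10),
                         hotspot_density = 2,
                         hotspot_jitter = FALSE,
                         seed = 1L) {
  if (!is.numeric(n_years) || n_years < 2)
    stop("configuration error: 'n_years' must be >= 2")
  if (n_fires_per_year < 1)
    stop("configuration error: 'n_fires_per_year' must be >= 1")
  if (hotspot_density <= 0)
    stop("configuration error: 'hotspot_density' must be > 0")
  if (threshold_sd <= 0)
    stop("configuration error: 'threshold_sd' must be > 0")
  if (length(true_threshold) != 1 || is.null(names(true_threshold)) ||
      !names(true_threshold) %in% fwi_variables())
    stop("configuration error: 'true_threshold' must be one named FWI ",
         "System variable, e.g. c(ffmc = 89)")
  wm <- weather_model
  if (!is.null(wm$wet_prob) && (wm$wet_prob < 0 || wm$wet_prob > 1))
    stop("configuration error: 'weather_model$wet_prob' must be in [0, 1]")
  structure(list(n_years = as.integer(n_years),
                 year_start = as.integer(year_start),
                 n_fires_per_year = as.integer(n_fires_per_year),
                 ecozone_labels = ecozone_labels,
                 true_threshold = true_threshold,
                 threshold_sd = threshold_sd,
                 area_distribution = area_distribution,
                 growth_days = as.integer(growth_days),
                 weather_model = wm,
                 hotspot_density = hotspot_density,
                 hotspot_jitter = hotspot_jitter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic study configuration\n")
  cat(sprintf("  years: %d starting %d; fires/year: %d; ecozones: %d\n",
              x$n_years, x$year_start, x$n_fires_per_year,
              length(x$ecozone_labels)))
  cat(sprintf("  true threshold: %s = %g (density sd %g)\n",
              names(x$true_threshold), x$true_threshold, x$threshold_sd))
  cat(sprintf("  hotspot density: %g / km2; jitter: %s; seed: %d\n",
              x$hotspot_density, x$hotspot_jitter, x$seed))
  invisible(x)
}

.study_dates <- function(config) {
  d <- seq(as.Date(sprintf("%d-01-01", config$year_start)),
           as.Date(sprintf("%d-12-31",
                           config$year_start + config$n_years - 1)),
           by = "day")
  d[format(d, "%m-%d") != "02-29"]  # 365-day years
}

# AR(1) series with innovation s.d. `sd` (marginal s.d. sd/sqrt(1-phi^2)).
.ar1 <- function(n, phi, sd) {
  z <- rnorm(n, 0, sd)
  if (phi == 0) return(z)
  e <- numeric(n)
  e[1] <- z[1] / sqrt(1 - phi^2)
  for (t in 2:n) e[t] <- phi * e[t - 1] + z[t]
  e
}

#' Generate a synthetic daily weather series
#'
#' One record per calendar day per year (Feb 29 dropped so every year has
#' 365 days). Temperature and relative humidity follow seasonal sinusoids
#' with AR(1) residuals; wind is gamma-distributed; precipitation is
#' intermittent (wet-day probability times a gamma amount).
#'
#' @param config a [synth_config()].
#' @param location optional `c(x, y)` point; distinct locations yield
#'   distinct (still reproducible) series under one seed.
#' @return data frame: `date`, `temp`, `rh`, `ws`, `prec`.
#' @export
generate_weather <- function(config, location = c(0, 0)) {
  stopifnot(inherits(config, "synth_config"))
  wm <- config$weather_model
  dates <- .study_dates(config)
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seas <- -cos(2 * pi * (doy - 15) / 365)  # peaks mid-July
  seed <- derive_seed(config$seed, sprintf("weather|%g|%g",
                                           location[1], location[2]))
  with_seed(seed, {
    temp <- wm$temp_mean + wm$temp_amp * seas +
      .ar1(n, wm$temp_ar1, wm$temp_sd)
    rh <- wm$rh_mean - wm$rh_amp * seas + .ar1(n, wm$rh_ar1, wm$rh_sd)
    rh <- pmin(pmax(rh, 2), 100)
    ws <- rgamma(n, shape = wm$ws_shape, scale = wm$ws_scale)
    wet <- runif(n) < wm$wet_prob
    prec <- ifelse(wet,
                   rgamma(n, shape = wm$prec_shape, scale = wm$prec_scale),
                   0)
    data.frame(date = dates, temp = temp, rh = rh, ws = ws, prec = prec)
  })
}

# Regular 128-gon with exact target area (radius adjusted for the polygon
# area deficit relative to the circle), centred at (cx, cy).
.fire_polygon <- function(cx, cy, area_m2, n_vertices = 128L) {
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r <- sqrt(2 * area_m2 / (n_vertices * sin(2 * pi / n_vertices)))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate synthetic fires, hotspots and paired growth truth
#'
#' Each fire is a disk grown as one annulus per growth day.  Growth days are
#' chosen so that the paired value of the configured index variable follows
#' a Gaussian density centred on the true threshold (symmetric truncation to
#' the variable's fire-season range keeps the centre the exact area-weighted
#' median); daily growth areas are lognormal and independent of the index,
#' so the configured centre is the true 50%-area threshold by construction.
#' Every fire's total area is at least 50 ha and every growth day receives
#' at least one hotspot inside its annulus, dated that day.
#'
#' @param config a [synth_config()].
#' @param fwi daily index table from [fwi_calc()] covering the study years.
#' @return list with `perimeters` (data frame, list-column `geometry` of
#'   vertex matrices), `hotspots`, `growth` (the paired ground-truth rows),
#'   `rings` (per-day annulus radii, for cell-level truth), and `truth`
#'   (true threshold, per-year exceedance counts).
#' @export
generate_fires <- function(config, fwi) {
  stopifnot(inherits(config, "synth_config"))
  variable <- names(config$true_threshold)
  theta <- unname(config$true_threshold)
  fwi$date <- as.Date(fwi$date)
  fwi$year <- as.integer(format(fwi$date, "%Y"))
  fwi$doy <- as.integer(format(fwi$date, "%j"))
  years <- config$year_start + seq_len(config$n_years) - 1
  if (!all(years %in% fwi$year))
    stop("fwi series does not cover all configured years")

  # season pool and symmetric truncation band around the centre
  pool_all <- fwi[fwi$doy >= 105 & fwi$doy <= 288, ]  # ~Apr 15 - Oct 15
  rng <- range(pool_all[[variable]])
  if (theta <= rng[1] || theta >= rng[2])
    stop("configuration error: 'true_threshold' (", theta,
         ") lies outside the generated ", variable, " range [",
         round(rng[1], 1), ", ", round(rng[2], 1), "]")
  k <- min(theta - rng[1], rng[2] - theta)

  seed <- derive_seed(config$seed, "fires")
  ez <- config$ecozone_labels
  nez <- length(ez)
  gmin <- config$growth_days[1]; gmax <- config$growth_days[2]
  ad <- config$area_distribution

  with_seed(seed, {
    per <- list(); hs <- list(); gr <- list(); rg <- list()
    fid <- 0L
    for (y in years) {
      pool <- pool_all[pool_all$year == y, ]
      for (j in seq_len(config$n_fires_per_year)) {
        fid <- fid + 1L
        fire_id <- sprintf("F%04d", fid)
        zone_i <- ((fid - 1L) %% nez) + 1L
        g <- if (gmin == gmax) gmin else sample(gmin:gmax, 1)

        # draw target index values, match to nearest unused season days
        xs <- rnorm(4 * g, theta, config$threshold_sd)
        xs <- xs[abs(xs - theta) <= k][seq_len(g)]
        while (anyNA(xs)) {  # extremely narrow band: refill
          more <- rnorm(4 * g, theta, config$threshold_sd)
          xs[is.na(xs)] <- more[abs(more - theta) <= k][seq_len(sum(is.na(xs)))]
        }
        avail <- rep(TRUE, nrow(pool))
        day_idx <- integer(g)
        for (q in seq_len(g)) {
          d <- abs(pool[[variable]] - xs[q])
          d[!avail] <- Inf
          day_idx[q] <- which.min(d)
          avail[day_idx[q]] <- FALSE
        }
        ord <- order(pool$date[day_idx])
        day_idx <- day_idx[ord]
        dates_g <- pool$date[day_idx]

        areas <- rlnorm(g, ad$meanlog, ad$sdlog)
        if (sum(areas) < 50) areas <- areas * 60 / sum(areas)
        total_m2 <- sum(areas) * 1e4
        r_out <- sqrt(cumsum(areas) * 1e4 / pi)
        r_in <- c(0, head(r_out, -1))
        cx <- (zone_i - 1) * 2e5 + runif(1, 2e4, 1.8e5)
        cy <- runif(1, 2e4, 1.8e5)

        per[[fid]] <- data.frame(fire_id = fire_id, year = y,
                                 ecozone = ez[zone_i],
                                 area_ha = sum(areas),
                                 center_x = cx, center_y = cy)
        per[[fid]]$geometry <- list(.fire_polygon(cx, cy, total_m2))
        rg[[fid]] <- data.frame(fire_id = fire_id, date = dates_g,
                                r_inner = r_in, r_outer = r_out)
        gr[[fid]] <- data.frame(fire_id = fire_id, date = dates_g,
                                year = y, ecozone = ez[zone_i],
                                season = season_of(dates_g),
                                area = areas,
                                pool[day_idx, fwi_variables()],
                                row.names = NULL)
        # hotspots: >= 1 per growth day, uniform in its annulus
        for (q in seq_len(g)) {
          nh <- max(1L, rpois(1, config$hotspot_density * areas[q] / 100))
          # radial placement biased toward mid-annulus: detections cluster
          # in the actively burning band, away from the day's start/stop
          # fronts (sharpens the dating signal for delineation)
          rr <- sqrt(r_in[q]^2 + (r_out[q]^2 - r_in[q]^2) *
                       stats::rbeta(nh, 2, 2))
          th <- runif(nh, 0, 2 * pi)
          hdate <- rep(dates_g[q], nh)
          if (config$hotspot_jitter)
            hdate <- hdate + sample(-1:1, nh, replace = TRUE)
          sensor <- if (y <= 2012) rep("MODIS", nh) else
            sample(c("MODIS", "VIIRS"), nh, replace = TRUE, prob = c(.3, .7))
          hs[[length(hs) + 1L]] <-
            data.frame(fire_id = fire_id, x = cx + rr * cos(th),
                       y = cy + rr * sin(th), date = hdate, sensor = sensor)
        }
      }
    }
    growth <- do.call(rbind, gr)
    truth <- list(true_threshold = config$true_threshold,
                  variable = variable,
                  growth_schedule = growth[, c("fire_id", "date", "area")],
                  psd_per_year = data.frame(
                    year = years,
                    n_days_above = vapply(years, function(yy)
                      sum(fwi[[variable]][fwi$year == yy] > theta),
                      integer(1))))
    list(perimeters = do.call(rbind, per),
         hotspots = do.call(rbind, hs),
         growth = growth,
         rings = do.call(rbind, rg),
         truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: weather, FWI indices, fires/hotspots/paired growth
#' truth under one configuration.
#'
#' @param config a [synth_config()].
#' @return list: `config`, `weather`, `fwi`, plus everything returned by
#'   [generate_fires()].
#' @export
#' @examples
#' st <- generate_study(synth_config(n_years = 3, n_fires_per_year = 4))
#' head(st$growth)
generate_study <- function(config = synth_config()) {
  weather <- generate_weather(config)
  fwi <- fwi_calc(weather)
  c(list(config = config, weather = weather, fwi = fwi),
    generate_fires(config, fwi))
}

#' True burn dates of raster cells of a synthetic fire
#'
#' Looks up which daily annulus each cell centre falls in; the outermost
#' ring is extended outward so boundary slivers inherit the last growth day.
#'
#' @param study a [generate_study()] result.
#' @param fire_id fire identifier.
#' @param px,py cell-centre coordinates.
#' @return `Date` vector of true burn dates.
#' @export
true_growth_dates <- function(study, fire_id, px, py) {
  p <- study$perimeters[study$perimeters$fire_id == fire_id, ]
  r <- study$rings[study$rings$fire_id == fire_id, ]
  stopifnot(nrow(p) == 1, nrow(r) >= 1)
  d <- sqrt((px - p$center_x)^2 + (py - p$center_y)^2)
  br <- c(r$r_inner[1], r$r_outer)
  br[length(br)] <- Inf
  as.Date(r$date[findInterval(d, br, rightmost.closed = TRUE,
                              all.inside = TRUE)])
}

#' Synthetic coarse fire-weather grid with elevation
#'
#' Builds the analogue of a coarse gridded fire-weather product for the
#' pairing stage: regular points with a smooth synthetic elevation surface;
#' each index value is the daily series value plus a linear elevation trend
#' and a smooth spatial field, clamped to index bounds.
#'
#' @param fwi daily index table from [fwi_calc()].
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param spacing grid spacing in metres (default 25000, a coarse-grid
#'   stand-in at desk scale).
#' @param elev_base,elev_amp elevation surface parameters (m).
#' @param beta per-metre elevation trend added to every index.
#' @param spatial_amp amplitude of the smooth spatial field (index units).
#' @return data frame: `x`, `y`, `elev`, then one row per date per point
#'   with the six index columns (long format with a `date` column).
#' @export
generate_fwi_grid <- function(fwi, extent, spacing = 25000,
                              elev_base = 500, elev_amp = 250,
                              beta = -0.004, spatial_amp = 1.5) {
  xs <- seq(extent[1], extent[2], by = spacing)
  ys <- seq(extent[3], extent[4], by = spacing)
  pts <- expand.grid(x = xs, y = ys)
  pts$elev <- synth_elevation(pts$x, pts$y, elev_base, elev_amp)
  L <- max(extent[2] - extent[1], extent[4] - extent[3], spacing * 4)
  spat <- spatial_amp * sin(2 * pi * pts$x / L) * cos(2 * pi * pts$y / L)
  out <- lapply(seq_len(nrow(fwi)), function(i) {
    g <- pts
    g$date <- as.Date(fwi$date[i])
    for (v in fwi_variables()) {
      val <- fwi[[v]][i] + beta * (g$elev - elev_base) + spat
      val <- pmax(val, 0)
      if (v == "ffmc") val <- pmin(val, 101)
      g[[v]] <- val
    }
    g
  })
  do.call(rbind, out)
}

#' Smooth synthetic elevation surface
#' @param x,y coordinates in metres.
#' @param base,amp base elevation and relief amplitude in metres.
#' @return elevations in metres.
#' @export
synth_elevation <- function(x, y, base = 500, amp = 250) {
  base + amp * sin(x / 7e4) * cos(y / 9e4)
}
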