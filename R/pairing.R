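# Pairing daily fire growth with fire weather: select coarse grid points
# near the footprint, downscale with elevation as a covariate (regression
# kriging), aggregate within the footprint.

#' Select coarse grid points near a growth footprint
#'
#' Returns the grid points within `buffer` metres of the footprint (distance
#' to the nearest footprint cell centre). The two-stage rule — retry with an
#' extended buffer when too few points support the downscaling model — lives
#' in [pair_daily_growth()].
#'
#' @param footprint data frame of footprint cell centres (`x`, `y`).
#' @param grid grid points for one date (`x`, `y`, plus value columns).
#' @param buffer radius in metres (default 50 km).
#' @return the selected rows of `grid`.
#' @export
select_grid_points <- function(footprint, grid, buffer = 50000) {
  if (is.null(grid) || nrow(grid) == 0)
    stop("pairing failure: weather grid empty for this date")
  stopifnot(nrow(footprint) >= 1)
  d <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(footprint))) {
    d <- pmin(d, sqrt((grid$x - footprint$x[i])^2 +
                      (grid$y - footprint$y[i])^2))
  }
  grid[d <= buffer, , drop = FALSE]
}

#' Downscale an index variable to fine targets (regression kriging)
#'
#' Fits a linear trend of the value on elevation, interpolates the
#' residuals by ordinary kriging with an automatically fitted variogram
#' (see [fit_variogram()]), and returns trend + kriged residual at each
#' target. When the variogram fit fails the residuals are interpolated by
#' inverse-distance weighting instead, and the result is flagged.
#'
#' @param points source points: `x`, `y`, `elev`, `value`.
#' @param targets fine targets: `x`, `y`, `elev`.
#' @return numeric vector of values at targets with attribute `method` one
#'   of `"regression_kriging"`, `"idw_fallback"`, `"trend_only"`.
#' @export
downscale <- function(points, targets) {
  if (nrow(points) < 4)
    stop("pairing failure: fewer than 4 grid points for downscaling")
  if (sd(points$elev) > 1e-9) {
    fit <- lm(value ~ elev, data = points)
    trend_src <- fitted(fit)
    trend_tgt <- predict(fit, newdata = targets)
  } else {
    trend_src <- rep(mean(points$value), nrow(points))
    trend_tgt <- rep(mean(points$value), nrow(targets))
  }
  res <- points$value - trend_src
  if (sd(res) < 1e-9) {
    out <- trend_tgt
    attr(out, "method") <- "trend_only"
    return(out)
  }
  vg <- fit_variogram(empirical_variogram(points$x, points$y, res))
  kr <- NULL
  if (!is.null(vg))
    kr <- .krige_ok(points$x, points$y, res, targets$x, targets$y, vg)
  if (is.null(kr)) {
    out <- trend_tgt + .idw(points$x, points$y, res, targets$x, targets$y)
    attr(out, "method") <- "idw_fallback"
  } else {
    out <- trend_tgt + kr
    attr(out, "method") <- "regression_kriging"
  }
  out
}

#' Aggregate downscaled values over a footprint into a paired row
#'
#' Footprint means for FFMC, DMC, DC, ISI and BUI; the footprint median for
#' FWI (its relationship with potential fire intensity is exponential, so
#' the median is the more robust summary). Season follows the month:
#' MAM/JJA/SON, `NA` for December–February (kept in annual pools only).
#'
#' @param growth_row one daily-growth row (`fire_id`, `date`, `area`).
#' @param fine data frame of downscaled values at footprint cells, columns
#'   `ffmc`, `dmc`, `dc`, `isi`, `bui`, `fwi`.
#' @return one paired row: growth fields + six index values + `season`.
#' @export
aggregate_pair <- function(growth_row, fine) {
  stopifnot(nrow(fine) >= 1)
  out <- data.frame(fire_id = growth_row$fire_id,
                    date = as.Date(growth_row$date),
                    area = growth_row$area)
  for (v in c("ffmc", "dmc", "dc", "isi", "bui"))
    out[[v]] <- mean(fine[[v]])
  out$fwi <- median(fine$fwi)
  out$season <- season_of(out$date)
  out
}

#' Pair each daily growth footprint with downscaled fire weather
#'
#' For every growth day: select coarse grid points within 50 km of the
#' footprint, extending to 200 km when fewer than 4 support the model;
#' downscale all six indices to the footprint cells (elevations from
#' `elev_fun`); aggregate into a paired row. Days that fail even at the
#' extended buffer are dropped and logged.
#'
#' @param growth result of [map_daily_growth()] (carries the `cells`
#'   attribute with per-cell dates).
#' @param grid long coarse-grid table (`date`, `x`, `y`, `elev`, six index
#'   columns), e.g. from [generate_fwi_grid()].
#' @param elev_fun `function(x, y)` giving elevation at footprint cells
#'   (default [synth_elevation()], matching the synthetic grid).
#' @param buffer,extended_buffer selection radii in metres.
#' @return paired data frame (one row per growth day) with attribute `log`
#'   (rows dropped, buffer extensions, fallback counts).
#' @export
pair_daily_growth <- function(growth, grid, elev_fun = synth_elevation,
                              buffer = 50000, extended_buffer = 200000) {
  cells <- attr(growth, "cells")
  if (is.null(cells)) stop("growth must carry the 'cells' attribute ",
                           "(use map_daily_growth())")
  grid$date <- as.Date(grid$date)
  rows <- list()
  nlog <- list(dropped = 0L, extended = 0L, idw_fallback = 0L)
  for (i in seq_len(nrow(growth))) {
    day <- as.Date(growth$date[i])
    fp <- cells[cells$date == day, c("x", "y"), drop = FALSE]
    g <- grid[grid$date == day, , drop = FALSE]
    sel <- select_grid_points(fp, g, buffer)
    if (nrow(sel) < 4) {
      sel <- select_grid_points(fp, g, extended_buffer)
      nlog$extended <- nlog$extended + 1L
    }
    if (nrow(sel) < 4) {
      nlog$dropped <- nlog$dropped + 1L
      next
    }
    targets <- data.frame(x = fp$x, y = fp$y, elev = elev_fun(fp$x, fp$y))
    fine <- targets
    for (v in fwi_variables()) {
      src <- data.frame(x = sel$x, y = sel$y, elev = sel$elev,
                        value = sel[[v]])
      dv <- downscale(src, targets)
      if (attr(dv, "method") == "idw_fallback")
        nlog$idw_fallback <- nlog$idw_fallback + 1L
      fine[[v]] <- as.numeric(dv)
    }
    rows[[length(rows) + 1L]] <- aggregate_pair(growth[i, ], fine)
  }
  out <- do.call(rbind, rows)
  attr(out, "log") <- nlog
  out
}
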