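# Daily fire-growth delineation: rasterize the final perimeter and date
# every cell from the hotspots it contains (nearest-hotspot interpolation,
# constrained by the final perimeter).

# nominal hotspot footprints (m) by sensor; tolerance is half the footprint
.SENSOR_FOOTPRINT <- c(MODIS = 1000, VIIRS = 375)

#' Delineate daily fire growth from dated hotspots
#'
#' Rasterizes the final perimeter at `cell_size` and assigns every cell the
#' detection date of its nearest usable hotspot (ties: the earlier date, a
#' growth-conservative choice). Hotspots farther from the perimeter than
#' half their sensor's nominal footprint are ignored and counted in the
#' exclusion log. An optional inverse-distance smoothed day-of-year surface
#' (rounded to whole days) is available instead of nearest-neighbour.
#'
#' @param perimeter a perimeter record from [get_perimeter()] (a list with
#'   `fire_id` and a vertex-matrix `geometry`).
#' @param hotspots data frame: `x`, `y`, `date`, `sensor`.
#' @param cell_size cell edge in metres (default 30, the mapping
#'   resolution of the source technique; raise to 100+ for quick runs).
#' @param method `"nearest"` (default) or `"idw"` (smoothed day surface).
#' @param idw_power inverse-distance power for `method = "idw"`.
#' @return data frame of daily growth (`fire_id`, `date`, `area` in ha,
#'   `n_cells`) with attributes `cells` (per-cell assignment: `x`, `y`,
#'   `date`) and `log` (hotspots excluded, cells mapped). `NULL` with a
#'   warning if no usable hotspot remains.
#' @export
map_daily_growth <- function(perimeter, hotspots, cell_size = 30,
                             method = c("nearest", "idw"), idw_power = 2) {
  method <- match.arg(method)
  v <- perimeter$geometry
  stopifnot(is.matrix(v), ncol(v) == 2)

  tol <- .SENSOR_FOOTPRINT[as.character(hotspots$sensor)] / 2
  tol[is.na(tol)] <- max(.SENSOR_FOOTPRINT) / 2
  d_per <- dist_to_poly(hotspots$x, hotspots$y, v[, 1], v[, 2])
  usable <- d_per <= tol
  n_excluded <- sum(!usable)
  hs <- hotspots[usable, , drop = FALSE]
  if (nrow(hs) == 0) {
    warning("fire ", perimeter$fire_id,
            " excluded: no usable hotspots (", n_excluded,
            " outside perimeter tolerance)")
    return(NULL)
  }
  hs$date <- as.Date(hs$date)

  # cell centres inside the perimeter
  gx <- seq(min(v[, 1]) + cell_size / 2, max(v[, 1]), by = cell_size)
  gy <- seq(min(v[, 2]) + cell_size / 2, max(v[, 2]), by = cell_size)
  cells <- expand.grid(x = gx, y = gy)
  inside <- points_in_poly(cells$x, cells$y, v[, 1], v[, 2])
  cells <- cells[inside, , drop = FALSE]
  if (nrow(cells) == 0) stop("perimeter rasterized to zero cells; ",
                             "decrease cell_size")

  if (method == "nearest") {
    # order hotspots by date so that ties pick the earlier date
    hs <- hs[order(hs$date), , drop = FALSE]
    d2 <- outer(cells$x, hs$x, "-")^2 + outer(cells$y, hs$y, "-")^2
    assigned <- hs$date[max.col(-d2, ties.method = "first")]
  } else {
    doy0 <- as.numeric(hs$date)
    d2 <- outer(cells$x, hs$x, "-")^2 + outer(cells$y, hs$y, "-")^2
    w <- 1 / pmax(d2, 1e-6)^(idw_power / 2)
    num <- w %*% doy0
    assigned <- as.Date(round(num / rowSums(w)), origin = "1970-01-01")
  }

  cells$date <- assigned
  per_day <- as.data.frame(table(date = assigned), stringsAsFactors = FALSE)
  out <- data.frame(fire_id = perimeter$fire_id,
                    date = as.Date(per_day$date),
                    area = per_day$Freq * cell_size^2 / 1e4,
                    n_cells = per_day$Freq)
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cells") <- cells
  attr(out, "log") <- list(hotspots_excluded = n_excluded,
                           hotspots_used = nrow(hs),
                           n_cells = nrow(cells),
                           cell_size = cell_size)
  out
}

#' Map daily growth for every fire in a perimeter table
#'
#' @param perimeters perimeter data frame (geometry list-column).
#' @param hotspots hotspot table with a `fire_id` column.
#' @param ... passed to [map_daily_growth()].
#' @return combined daily-growth data frame; fires with no usable hotspots
#'   are dropped (with their warnings) and listed in the `excluded_fires`
#'   attribute.
#' @export
map_all_fires <- function(perimeters, hotspots, ...) {
  res <- list(); excluded <- character()
  for (i in seq_len(nrow(perimeters))) {
    p <- get_perimeter(perimeters, perimeters$fire_id[i])
    g <- map_daily_growth(p, hotspots[hotspots$fire_id == p$fire_id, ], ...)
    if (is.null(g)) excluded <- c(excluded, p$fire_id) else
      res[[length(res) + 1L]] <- g
  }
  out <- do.call(rbind, lapply(res, function(g) {
    attr(g, "cells") <- NULL
    attr(g, "log") <- NULL
    g
  }))
  attr(out, "excluded_fires") <- excluded
  out
}
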