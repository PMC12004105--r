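# Plain-text study I/O: CSV tables, GeoJSON perimeters, JSON truth.

#' Write a synthetic study to a directory
#'
#' Emits `weather.csv`, `fwi.csv`, `perimeters.geojson`, `hotspots.csv`,
#' `growth_truth.csv` and `truth.json`.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$weather, file.path(dir, "weather.csv"), row.names = FALSE)
  write.csv(study$fwi, file.path(dir, "fwi.csv"), row.names = FALSE)
  write.csv(study$hotspots, file.path(dir, "hotspots.csv"),
            row.names = FALSE)
  write.csv(study$growth, file.path(dir, "growth_truth.csv"),
            row.names = FALSE)
  write_perimeters(study$perimeters, file.path(dir, "perimeters.geojson"))
  jsonlite::write_json(
    list(true_threshold = as.list(study$truth$true_threshold),
         psd_per_year = study$truth$psd_per_year),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write fire perimeters as GeoJSON
#'
#' Planar coordinates are written as-is (the package works in a metric CRS
#' throughout; no reprojection is attempted).
#'
#' @param perimeters data frame with `fire_id`, `year`, `ecozone`,
#'   `area_ha` and a `geometry` list-column of vertex matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_perimeters <- function(perimeters, path) {
  feats <- lapply(seq_len(nrow(perimeters)), function(i) {
    v <- perimeters$geometry[[i]]
    ring <- rbind(v, v[1, , drop = FALSE])  # closed ring
    list(type = "Feature",
         properties = list(fire_id = perimeters$fire_id[i],
                           year = perimeters$year[i],
                           ecozone = perimeters$ecozone[i],
                           area_ha = perimeters$area_ha[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(j) c(ring[j, 1], ring[j, 2]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fire perimeters from GeoJSON
#'
#' Inverse of [write_perimeters()]: parses a FeatureCollection of Polygon
#' features into the data-frame-with-geometry-list form used throughout.
#'
#' @param path GeoJSON file.
#' @return data frame with `fire_id`, `year`, `ecozone`, `area_ha` and a
#'   `geometry` list-column (first ring only, closing vertex dropped).
#' @export
read_perimeters <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    pr <- f$properties
    d <- data.frame(fire_id = pr$fire_id, year = pr$year,
                    ecozone = pr$ecozone, area_ha = pr$area_ha)
    d$geometry <- list(m)
    d
  })
  do.call(rbind, rows)
}

#' Extract one fire's perimeter record
#' @param perimeters perimeter data frame (see [read_perimeters()]).
#' @param fire_id fire identifier.
#' @return one-row perimeter record as a list (geometry as a matrix).
#' @export
get_perimeter <- function(perimeters, fire_id) {
  i <- which(perimeters$fire_id == fire_id)
  if (length(i) != 1) stop("fire_id not found (or duplicated): ", fire_id)
  out <- as.list(perimeters[i, setdiff(names(perimeters), "geometry")])
  out$geometry <- perimeters$geometry[[i]]
  out
}
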