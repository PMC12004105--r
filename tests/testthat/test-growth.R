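# Daily growth delineation: nearest-hotspot dating, conservation,
# exclusion rules, truth recovery on synthetic fires.

square_perimeter <- function(side = 2000, cx = 0, cy = 0, id = "SQ1") {
  h <- side / 2
  list(fire_id = id, area_ha = side^2 / 1e4,
       geometry = cbind(x = c(cx - h, cx + h, cx + h, cx - h),
                        y = c(cy - h, cy - h, cy + h, cy + h)))
}

test_that("hotspots sharing one date give a single growth day covering the fire", {
  p <- square_perimeter()
  hs <- data.frame(x = c(-300, 200, 500), y = c(0, -400, 300),
                   date = as.Date("2021-07-10"), sensor = "VIIRS")
  g <- map_daily_growth(p, hs, cell_size = 100)
  expect_equal(nrow(g), 1L)
  expect_equal(g$date, as.Date("2021-07-10"))
  # rasterization tolerance: one cell's area times the boundary cell count
  n_boundary <- 4 * (2000 / 100)
  expect_lt(abs(g$area - p$area_ha), n_boundary * 100^2 / 1e4)
})

test_that("cell dates equal brute-force nearest-hotspot assignment", {
  set.seed(31)
  for (rep in 1:3) {
    p <- square_perimeter(side = 1500)
    nh <- 6
    hs <- data.frame(x = runif(nh, -700, 700), y = runif(nh, -700, 700),
                     date = as.Date("2021-07-01") + sample(0:5, nh, TRUE),
                     sensor = "VIIRS")
    g <- map_daily_growth(p, hs, cell_size = 100)
    cells <- attr(g, "cells")
    # brute force: per-cell loop over hotspots, earlier date on ties
    hs_o <- hs[order(hs$date), ]
    brute <- as.Date(vapply(seq_len(nrow(cells)), function(i) {
      d2 <- (cells$x[i] - hs_o$x)^2 + (cells$y[i] - hs_o$y)^2
      as.character(hs_o$date[which.min(d2)])
    }, character(1)))
    expect_identical(cells$date, brute)
    # label set: assigned dates are hotspot dates
    expect_true(all(cells$date %in% hs$date))
  }
})

test_that("equidistant hotspots with different dates resolve to the earlier date", {
  # 500 m square on 100 m cells puts a centre column exactly on x = 0,
  # equidistant from hotspots mirror-symmetric about the y axis
  p <- square_perimeter(side = 500)
  hs <- data.frame(x = c(-200, 200), y = c(0, 0),
                   date = as.Date(c("2021-07-05", "2021-07-01")),
                   sensor = "VIIRS")
  g <- map_daily_growth(p, hs, cell_size = 100)
  cells <- attr(g, "cells")
  mid <- cells[abs(cells$x) < 1e-9, ]
  expect_gt(nrow(mid), 0)
  expect_true(all(mid$date == as.Date("2021-07-01")))
})

test_that("hotspots beyond the sensor tolerance are ignored and logged", {
  p <- square_perimeter(side = 1000)
  hs <- data.frame(x = c(0, 5000), y = c(0, 0),
                   date = as.Date(c("2021-07-01", "2021-07-09")),
                   sensor = c("VIIRS", "VIIRS"))
  g <- map_daily_growth(p, hs, cell_size = 100)
  expect_equal(nrow(g), 1L)                     # far hotspot dropped
  expect_equal(attr(g, "log")$hotspots_excluded, 1L)
  # a MODIS hotspot 450 m out is within its 500 m tolerance
  hs2 <- data.frame(x = 950, y = 0, date = as.Date("2021-07-02"),
                    sensor = "MODIS")
  g2 <- map_daily_growth(p, hs2, cell_size = 100)
  expect_equal(attr(g2, "log")$hotspots_excluded, 0L)
  # nothing usable: fire flagged and excluded
  expect_warning(
    g3 <- map_daily_growth(p, hs[2, , drop = FALSE], cell_size = 100),
    "no usable hotspots")
  expect_null(g3)
})

test_that("daily areas conserve the perimeter area", {
  st <- SMALL_STUDY
  for (f in head(st$perimeters$fire_id, 3)) {
    p <- get_perimeter(st$perimeters, f)
    g <- map_daily_growth(p, st$hotspots[st$hotspots$fire_id == f, ],
                          cell_size = 60)
    n_cells <- sum(g$n_cells)
    expect_equal(sum(g$area), n_cells * 60^2 / 1e4, tolerance = 1e-12)
    # mapped area approximates polygon area at raster tolerance
    expect_lt(abs(sum(g$area) - p$area_ha) / p$area_ha, 0.1)
  }
})

test_that("smoothed interpolation keeps dates within the hotspot date range", {
  p <- square_perimeter(side = 1500)
  set.seed(5)
  hs <- data.frame(x = runif(8, -700, 700), y = runif(8, -700, 700),
                   date = as.Date("2021-07-01") + sample(0:9, 8, TRUE),
                   sensor = "VIIRS")
  g <- map_daily_growth(p, hs, cell_size = 100, method = "idw")
  expect_true(all(g$date >= min(hs$date) & g$date <= max(hs$date)))
})

test_that("most cells get their true burn date on delineation-friendly fires", {
  cfg <- synth_config(n_years = 2, n_fires_per_year = 3, seed = 2,
                      hotspot_density = 30, growth_days = c(3L, 3L),
                      area_distribution = list(meanlog = log(400),
                                               sdlog = 0.4))
  st <- generate_study(cfg)
  accs <- vapply(head(st$perimeters$fire_id, 3), function(f) {
    p <- get_perimeter(st$perimeters, f)
    g <- map_daily_growth(p, st$hotspots[st$hotspots$fire_id == f, ],
                          cell_size = 100)
    cells <- attr(g, "cells")
    mean(cells$date == true_growth_dates(st, f, cells$x, cells$y))
  }, numeric(1))
  expect_true(all(accs >= 0.9))
})
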