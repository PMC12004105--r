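# Threshold estimation: cumulative curves, the 50% crossing, year
# resampling, ecozone table summaries.

test_that("cumulative curves match the brute-force sorted cumulative sum", {
  set.seed(13)
  for (rep in 1:3) {
    rows <- data.frame(ffmc = round(runif(1000, 60, 100), 1),
                       area = rlnorm(1000, 4, 1))
    cc <- cumulative_curve(rows, "ffmc")
    o <- order(rows$ffmc)
    brute_v <- rows$ffmc[o]; brute_c <- cumsum(rows$area[o]) / sum(rows$area)
    # at every knot the step height equals the brute-force sum there
    at_knot <- vapply(cc$value, function(v) max(brute_c[brute_v <= v]),
                      numeric(1))
    expect_equal(cc$cum_frac, at_knot, tolerance = 1e-12)
    expect_true(all(diff(cc$cum_frac) >= 0))
    expect_equal(cc$cum_frac[nrow(cc)], 1)
  }
})

test_that("single and two-point masses give the textbook steps", {
  one <- cumulative_curve(data.frame(ffmc = 90, area = 100), "ffmc")
  expect_equal(one$value, 90)
  expect_equal(one$cum_frac, 1)
  two <- cumulative_curve(data.frame(ffmc = c(80, 90), area = c(1, 1)),
                          "ffmc")
  expect_equal(two$cum_frac, c(0.5, 1))
  expect_error(cumulative_curve(data.frame(ffmc = 90, area = 0), "ffmc"),
               "positive area")
})

test_that("the 50% crossing handles degenerate and two-mass cases", {
  t1 <- threshold_at_half(data.frame(ffmc = rep(90, 5), area = 1:5), "ffmc")
  expect_equal(as.numeric(t1), 90)
  expect_true(attr(t1, "degenerate"))
  t2 <- threshold_at_half(data.frame(ffmc = c(80, 90), area = c(1, 1)),
                          "ffmc")
  expect_equal(as.numeric(t2), 85)    # midpoint interpolation convention
  expect_gte(as.numeric(t2), 80); expect_lte(as.numeric(t2), 90)
})

test_that("the smoothed crossing agrees with the weighted-median oracle", {
  set.seed(17)
  for (rep in 1:4) {
    n <- 600
    rows <- data.frame(ffmc = rnorm(n, 88, 3) + runif(n, -1, 1),
                       area = rlnorm(n, 4.5, 0.8))
    est <- as.numeric(threshold_at_half(rows, "ffmc"))
    oracle <- weighted_quantile(rows$ffmc, rows$area)
    rng <- diff(range(rows$ffmc))
    expect_lt(abs(est - oracle), 0.02 * rng)
  }
})

test_that("the estimator recovers the generator's true threshold", {
  st <- generate_study(synth_config(n_fires_per_year = 40, seed = 3))
  est <- as.numeric(threshold_at_half(st$growth, "ffmc"))
  expect_lt(abs(est - 89), 0.5)
})

test_that("year resampling is deterministic and sees between-year variation", {
  st <- SMALL_STUDY
  cfg <- resample_config(n_reps = 20, years_per_rep = 2, seed = 99)
  a <- resample_thresholds(st$growth, "ffmc", config = cfg)
  b <- resample_thresholds(st$growth, "ffmc", config = cfg)
  expect_identical(a, b)
  expect_identical(attr(a, "replicates"), attr(b, "replicates"))
  expect_gt(a$sd, 0)
  expect_equal(a$n_reps_used, 20L)
})

test_that("identical row sets across years give zero resampling s.d.", {
  base <- data.frame(ffmc = c(84, 86, 88, 90, 92, 94), area = c(1, 2, 5, 5, 2, 1))
  rows <- do.call(rbind, lapply(2001:2021, function(y)
    transform(base, year = y)))
  est <- resample_thresholds(rows, "ffmc",
                             config = resample_config(n_reps = 25,
                                                      years_per_rep = 10,
                                                      seed = 4))
  expect_equal(est$sd, 0)
})

test_that("too few years falls back to a flagged all-years estimate", {
  rows <- data.frame(ffmc = runif(40, 80, 95), area = rlnorm(40, 4, 1),
                     year = rep(2001:2004, each = 10))
  est <- resample_thresholds(rows, "ffmc",
                             config = resample_config(years_per_rep = 10))
  expect_equal(est$n_reps_used, 1L)
  expect_match(est$flag, "insufficient_years")
  expect_equal(est$mean, as.numeric(threshold_at_half(rows, "ffmc")))
})

test_that("resampling all years in one replicate equals the pooled estimate", {
  st <- SMALL_STUDY
  cfg <- resample_config(n_reps = 1, years_per_rep = 3, seed = 1)
  est <- resample_thresholds(st$growth, "ffmc", config = cfg)
  expect_equal(est$mean, as.numeric(threshold_at_half(st$growth, "ffmc")))
  expect_true(est$mean >= min(st$growth$ffmc) &
                est$mean <= max(st$growth$ffmc))
})

test_that("estimate_thresholds covers national and ecozone strata", {
  st <- SMALL_STUDY
  est <- estimate_thresholds(st$growth,
                             resample_config(n_reps = 5, years_per_rep = 2,
                                             seed = 2),
                             variables = c("ffmc", "fwi"))
  expect_true("national" %in% est$scope)
  expect_true(all(unique(st$growth$ecozone) %in% est$scope))
  expect_true(all(est$mean >= 0))
})

test_that("the ecozone summary row averages the printed per-ecozone rows", {
  ref <- reference_tables()$thresholds
  sm <- summarize_ecozone_table(ref_long(ref))
  expect_equal(sm$mean[sm$variable == "ffmc"], 89.1)
  expect_equal(sm$mean[sm$variable == "dc"], 265.1)
  # a single ecozone summarizes to itself
  one <- summarize_ecozone_table(data.frame(variable = "ffmc",
                                            mean = 88.8, sd = 0.3))
  expect_equal(one$mean, 88.8)
  expect_equal(one$sd, 0.3)
})
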