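# Spread-day accounting: PSD/RSD counts, ratios, stratified summaries.

mk_daily <- function(values, start = "2021-06-01") {
  data.frame(date = as.Date(start) + seq_along(values) - 1, value = values)
}

test_that("PSD counting is a strict exceedance count over the window", {
  expect_equal(count_psd(mk_daily(rep(80, 30)), 2021, 89.4), 0)
  vals <- rep(80, 30); vals[c(3, 10, 22)] <- 92
  expect_equal(count_psd(mk_daily(vals), 2021, 89.4), 3)
  # exactly-at-threshold days do not count (strict >)
  expect_equal(count_psd(mk_daily(c(89.4, 89.41)), 2021, 89.4), 1)
  # days of other years are outside the window
  d <- rbind(mk_daily(rep(95, 5), "2020-12-29"), mk_daily(rep(95, 5)))
  expect_equal(count_psd(d, 2021, 90), 7)  # 3 of the Dec days are 2020
  expect_error(count_psd(mk_daily(numeric(0)), 2021, 90),
               "accounting error")
})

test_that("PSD equals the brute-force day-by-day comparison", {
  set.seed(41)
  for (rep in 1:5) {
    vals <- runif(365, 60, 100)
    d <- mk_daily(vals, "2021-01-01")
    thr <- runif(1, 70, 95)
    brute <- sum(vals > thr)
    expect_equal(count_psd(d, 2021, thr), brute)
    # seasonal window restricts to April-October
    mons <- as.integer(format(d$date, "%m"))
    expect_equal(count_psd(d, 2021, thr, window = "fire_season"),
                 sum(vals > thr & mons %in% 4:10))
  }
})

test_that("RSD counts growth days above threshold, brute-force checked", {
  fire <- data.frame(ffmc = c(90, 91, 88))
  expect_equal(count_rsd(fire, "ffmc", 89.4), 2)
  expect_equal(count_rsd(fire, "ffmc", 95), 0)
  set.seed(42)
  f2 <- data.frame(ffmc = runif(50, 80, 95))
  thr <- 88.7
  expect_equal(count_rsd(f2, "ffmc", thr), sum(f2$ffmc > thr))
})

test_that("accounts combine PSD, RSD and the ratio correctly", {
  paired <- data.frame(fire_id = "F1", year = 2021, ecozone = "BSW",
                       ffmc = c(91, 92, 85))
  vals <- rep(80, 365); vals[100:109] <- 95   # 10 exceedance days
  series <- mk_daily(vals, "2021-01-01")
  names(series)[2] <- "ffmc"
  acc <- spread_day_accounts(paired, series, c(ffmc = 89.4),
                             variables = "ffmc")
  expect_equal(acc$psd, 10)
  expect_equal(acc$rsd, 2)
  expect_equal(acc$ratio, 0.2)
  # one fire, psd 10, rsd 3 -> 30%
  sm <- ratio_and_summaries(transform(acc, rsd = 3, ratio = 0.3))
  expect_equal(sm$by_ecozone$mean, 30)
})

test_that("a fire using every exceedance day reaches ratio exactly 1", {
  vals <- rep(70, 365); above <- c(150:152, 200:204)
  vals[above] <- 93
  series <- mk_daily(vals, "2021-01-01"); names(series)[2] <- "ffmc"
  paired <- data.frame(fire_id = "F1", year = 2021, ecozone = "TP",
                       ffmc = vals[above])
  acc <- spread_day_accounts(paired, series, c(ffmc = 89), "ffmc")
  expect_equal(acc$ratio, 1)
})

test_that("ratios lie in [0, 1] and are monotone in the threshold", {
  st <- SMALL_STUDY
  # per-fire series: the national daily series (all fires share weather)
  series <- st$fwi
  for (thr in c(85, 88, 91)) {
    acc <- spread_day_accounts(st$growth, series, c(ffmc = thr), "ffmc")
    ok <- !is.na(acc$ratio)
    expect_true(all(acc$ratio[ok] >= 0 & acc$ratio[ok] <= 1))
  }
  acc_lo <- spread_day_accounts(st$growth, series, c(ffmc = 85), "ffmc")
  acc_hi <- spread_day_accounts(st$growth, series, c(ffmc = 92), "ffmc")
  expect_true(all(acc_hi$psd <= acc_lo$psd))
  expect_true(all(acc_hi$rsd <= acc_lo$rsd))
})

test_that("zero-PSD fires are excluded and logged; summaries average ecozones", {
  acc <- data.frame(fire_id = sprintf("F%d", 1:5), year = 2021,
                    ecozone = c("TP", "TP", "BSW", "BSW", "BSW"),
                    variable = "fwi", threshold_source = "national",
                    threshold = 20,
                    psd = c(10, 10, 20, 20, 0),
                    rsd = c(2, 4, 5, 15, 0),
                    ratio = c(0.2, 0.4, 0.25, 0.75, NA))
  sm <- ratio_and_summaries(acc)
  expect_equal(sm$n_zero_psd, 1)
  expect_equal(sort(sm$by_ecozone$mean), c(30, 50))
  expect_equal(sm$summary$mean, 40)   # mean of the two ecozone means
})

test_that("per-ecozone thresholds are looked up per fire", {
  paired <- data.frame(fire_id = c("F1", "F2"), year = 2021,
                       ecozone = c("TP", "MC"), ffmc = c(89, 89))
  vals <- rep(89, 365)
  series <- mk_daily(vals, "2021-01-01"); names(series)[2] <- "ffmc"
  thr <- data.frame(ecozone = c("TP", "MC"), ffmc = c(88.8, 90.8))
  acc <- spread_day_accounts(paired, series, thr, "ffmc",
                             threshold_source = "ecozone")
  expect_equal(acc$rsd[acc$fire_id == "F1"], 1)   # 89 > 88.8
  expect_equal(acc$rsd[acc$fire_id == "F2"], 0)   # 89 < 90.8
  expect_error(spread_day_accounts(
    transform(paired, ecozone = "XX"), series, thr, "ffmc"), "XX")
})

test_that("the printed ratio table's summary row is the ecozone column mean", {
  ref <- reference_tables()$rsd_psd
  expect_equal(round(mean(ref$nat_fwi_mean), 1), 27.4)
  expect_equal(round(mean(ref$ez_fwi_mean), 1), 30.4)
  expect_equal(round(mean(ref$nat_isi_mean), 1), 16.9)
  expect_equal(round(mean(ref$ez_ffmc_mean), 1), 22.8)
})
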