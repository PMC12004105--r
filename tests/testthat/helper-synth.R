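# Shared fixtures, built in code once per test run.

small_config <- function(seed = 42, ...) {
  synth_config(n_years = 3, n_fires_per_year = 4, seed = seed, ...)
}

# A small study reused across test files (3 years, 12 fires, ~80 rows).
SMALL_STUDY <- generate_study(small_config())

# Random noon-weather table for FWI engine tests.
random_weather <- function(n, seed, year = 2020) {
  set.seed(seed)
  data.frame(date = seq(as.Date(sprintf("%d-01-01", year)), by = "day",
                        length.out = n),
             temp = round(runif(n, -10, 35), 1),
             rh = round(runif(n, 10, 100), 1),
             ws = round(runif(n, 0, 50), 1),
             prec = round(ifelse(runif(n) < 0.3, rgamma(n, 0.7, 0.1), 0), 1))
}

# Reference tables reshaped to the long (variable, mean, sd) form expected
# by summarize_ecozone_table().
ref_long <- function(tab, vars = c("ffmc", "dmc", "dc", "isi", "bui", "fwi"),
                     prefix = "") {
  do.call(rbind, lapply(vars, function(v) {
    data.frame(variable = v, ecozone = tab$ecozone,
               mean = tab[[paste0(prefix, v, "_mean")]],
               sd = tab[[paste0(prefix, v, "_sd")]])
  }))
}
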