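# Spread-day threshold estimation: the index value at which the smoothed
# cumulative area-burned curve along an FWI System variable crosses 50%,
# with mean/s.d. over year-resampling replicates.

#' Cumulative area-burned curve along an index variable
#'
#' Rows are sorted by the variable, ties merged into one step, and burned
#' area accumulated and normalized: a nondecreasing step function from 0
#' to 1.
#'
#' @param rows paired data frame with an `area` column.
#' @param variable index column name (one of [fwi_variables()]).
#' @return data frame: `value`, `area`, `cum_frac` (right-continuous step
#'   heights) and `cum_mid` (mass-midpoint heights used for interpolation).
#' @export
cumulative_curve <- function(rows, variable) {
  a <- rows$area
  v <- rows[[variable]]
  keep <- is.finite(v) & is.finite(a) & a > 0
  if (!any(keep)) stop("estimation error: no rows with positive area")
  o <- order(v[keep])
  vs <- v[keep][o]; as_ <- a[keep][o]
  grp <- cumsum(c(TRUE, diff(vs) != 0))   # exact tie grouping
  out <- data.frame(value = vs[!duplicated(grp)],
                    area = as.numeric(tapply(as_, grp, sum)))
  tot <- sum(out$area)
  if (tot <= 0) stop("estimation error: zero total area")
  cf <- cumsum(out$area) / tot
  out$cum_frac <- cf
  out$cum_mid <- cf - out$area / (2 * tot)
  rownames(out) <- NULL
  out
}

#' Smoothed cumulative area-burned curve
#'
#' Fits a penalized regression spline (basis dimension `k`, smoothness by
#' GCV) to the cumulative fraction as a function of the index value, then
#' projects the fit onto a monotone nondecreasing curve over a 1000-point
#' evaluation grid. With fewer than five distinct values, the empirical
#' mass-midpoint interpolant is used directly (a spline has nothing to
#' smooth).
#'
#' @param rows paired data frame (`area` + the variable column).
#' @param variable index column name.
#' @param k spline basis dimension (default 10; reduced automatically when
#'   there are fewer distinct values).
#' @param n_grid evaluation grid size (default 1000).
#' @return object of class `cumulative_smooth`: list with `grid`, `frac`,
#'   `curve` (the step data), `method`, `variable`.
#' @export
cumulative_smooth <- function(rows, variable, k = 10, n_grid = 1000) {
  cc <- cumulative_curve(rows, variable)
  nv <- nrow(cc)
  rng <- range(cc$value)
  if (nv == 1L) {
    obj <- list(grid = rep(cc$value, 2), frac = c(0.5, 0.5), curve = cc,
                method = "degenerate", variable = variable)
    class(obj) <- "cumulative_smooth"
    return(obj)
  }
  xs <- seq(rng[1], rng[2], length.out = n_grid)
  if (nv < 5L) {
    ys <- approx(cc$value, cc$cum_mid, xout = xs, rule = 2,
                 ties = "ordered")$y
    method <- "empirical"
  } else {
    kk <- max(3L, min(k, nv - 1L))
    fit <- mgcv::gam(cum_mid ~ s(value, k = kk), data = cc)
    ys <- as.numeric(predict(fit, newdata = data.frame(value = xs)))
    ys <- isoreg(xs, ys)$yf          # monotone projection
    ys <- pmin(pmax(ys, 0), 1)
    method <- "gam"
  }
  obj <- list(grid = xs, frac = ys, curve = cc, method = method,
              variable = variable)
  class(obj) <- "cumulative_smooth"
  obj
}

#' @export
print.cumulative_smooth <- function(x, ...) {
  cat(sprintf("cumulative area-burned curve for %s (%s; %d distinct values)\n",
              x$variable, x$method, nrow(x$curve)))
  invisible(x)
}

#' Evaluate a smoothed cumulative curve
#' @param object a [cumulative_smooth()] result.
#' @param x index values at which to evaluate.
#' @param ... unused.
#' @return cumulative area fractions in `[0, 1]` (flat beyond the range).
#' @export
predict.cumulative_smooth <- function(object, x, ...) {
  if (object$method == "degenerate")
    return(ifelse(x < object$grid[1], 0, ifelse(x > object$grid[1], 1, 0.5)))
  approx(object$grid, object$frac, xout = x, rule = 2, ties = "ordered")$y
}

# first crossing of level p on the monotone grid, linearly interpolated
.curve_crossing <- function(object, p) {
  if (object$method == "degenerate") return(object$grid[1])
  ys <- object$frac; xs <- object$grid
  i <- which(ys >= p)[1]
  if (is.na(i)) return(xs[length(xs)])
  if (i == 1L || ys[i] == ys[i - 1L]) return(xs[i])
  xs[i - 1L] + (p - ys[i - 1L]) / (ys[i] - ys[i - 1L]) * (xs[i] - xs[i - 1L])
}

#' Spread-day threshold: the 50%-area crossing of the smoothed curve
#'
#' The smallest index value at which the smoothed cumulative area-burned
#' curve reaches `p` (default 0.5), clamped to the observed range of the
#' variable. A variable with a single distinct value returns that value
#' with a `degenerate` flag.
#'
#' @inheritParams cumulative_smooth
#' @param p crossing level (default 0.5).
#' @return the threshold (numeric scalar) with attribute `degenerate`.
#' @export
#' @examples
#' rows <- data.frame(ffmc = c(80, 90), area = c(1, 1))
#' threshold_at_half(rows, "ffmc")  # 85 by the midpoint convention
threshold_at_half <- function(rows, variable, k = 10, p = 0.5) {
  cs <- cumulative_smooth(rows, variable, k = k)
  out <- .curve_crossing(cs, p)
  rng <- range(cs$curve$value)
  out <- min(max(out, rng[1]), rng[2])
  attr(out, "degenerate") <- cs$method == "degenerate"
  out
}

#' Year-resampling configuration
#'
#' @param n_reps number of replicates (default 100).
#' @param years_per_rep years drawn (without replacement) per replicate
#'   (default 10).
#' @param seed master RNG seed; one stream per (variable, stratum) is
#'   derived from it, so results are reproducible regardless of call order.
#' @param k spline basis dimension passed to [cumulative_smooth()].
#' @return list of class `resample_config`.
#' @export
resample_config <- function(n_reps = 100, years_per_rep = 10, seed = 1,
                            k = 10) {
  stopifnot(n_reps >= 1, years_per_rep >= 1)
  structure(list(n_reps = as.integer(n_reps),
                 years_per_rep = as.integer(years_per_rep),
                 seed = as.integer(seed), k = k),
            class = "resample_config")
}

#' Threshold estimate over year-resampling replicates
#'
#' For each replicate, `years_per_rep` distinct years are sampled uniformly
#' without replacement, their rows pooled, and [threshold_at_half()]
#' computed; the mean and sample (n−1) standard deviation across replicates
#' are returned. Strata with fewer available years than `years_per_rep`
#' fall back to a single all-years estimate, flagged; strata with fewer
#' than 30 rows are flagged unreliable (small sample).
#'
#' @param rows paired rows of one stratum, with `year` and `area` columns.
#' @param variable index column name.
#' @param stratum stratum label recorded in the output (also salts the
#'   RNG stream).
#' @param config a [resample_config()].
#' @return one-row data frame: `variable`, `stratum`, `mean`, `sd`,
#'   `n_reps_used`, `n_rows`, `flag`; replicate values in attribute
#'   `replicates`.
#' @export
resample_thresholds <- function(rows, variable, stratum = "national",
                                config = resample_config()) {
  years <- sort(unique(rows$year))
  flag <- if (nrow(rows) < 30) "small_sample" else ""
  seed <- derive_seed(config$seed, paste(variable, stratum, sep = "|"))
  if (length(years) < config$years_per_rep) {
    est <- threshold_at_half(rows, variable, k = config$k)
    flag <- paste0(flag, if (nzchar(flag)) "+", "insufficient_years")
    out <- data.frame(variable = variable, stratum = stratum,
                      mean = as.numeric(est), sd = NA_real_,
                      n_reps_used = 1L, n_rows = nrow(rows), flag = flag)
    attr(out, "replicates") <- as.numeric(est)
    return(out)
  }
  reps <- with_seed(seed, {
    vapply(seq_len(config$n_reps), function(r) {
      ys <- sample(years, config$years_per_rep)
      as.numeric(threshold_at_half(rows[rows$year %in% ys, , drop = FALSE],
                                   variable, k = config$k))
    }, numeric(1))
  })
  out <- data.frame(variable = variable, stratum = stratum,
                    mean = mean(reps), sd = sd(reps),
                    n_reps_used = config$n_reps, n_rows = nrow(rows),
                    flag = flag)
  attr(out, "replicates") <- reps
  out
}

#' Threshold estimates for every variable and stratum
#'
#' Runs [resample_thresholds()] for each FWI System variable over the
#' national pool and (optionally) each ecozone, annually and by season.
#'
#' @param paired paired data frame with `year`, `area`, `ecozone`,
#'   `season` and the six index columns.
#' @param config a [resample_config()].
#' @param variables index variables (default all six).
#' @param by_ecozone,by_season include ecozone / seasonal strata.
#' @return long data frame of estimates (one row per variable × stratum ×
#'   season; season `"annual"` pools all rows including winter).
#' @export
estimate_thresholds <- function(paired, config = resample_config(),
                                variables = fwi_variables(),
                                by_ecozone = TRUE, by_season = FALSE) {
  strata <- list(list(label = "national", rows = paired))
  if (by_ecozone) {
    for (ez in sort(unique(paired$ecozone)))
      strata[[length(strata) + 1L]] <-
        list(label = ez, rows = paired[paired$ecozone == ez, , drop = FALSE])
  }
  out <- list()
  for (st in strata) {
    seasons <- if (by_season) c("annual", "MAM", "JJA", "SON") else "annual"
    for (sn in seasons) {
      rows <- if (sn == "annual") st$rows else
        st$rows[!is.na(st$rows$season) & st$rows$season == sn, , drop = FALSE]
      if (nrow(rows) == 0) next
      for (v in variables) {
        e <- resample_thresholds(rows, v,
                                 stratum = paste(st$label, sn, sep = ":"),
                                 config = config)
        e$season <- sn
        e$scope <- st$label
        out[[length(out) + 1L]] <- e
      }
    }
  }
  do.call(rbind, out)
}

#' Ecozone-table summary row: mean of means, mean of s.d.s
#'
#' The summary row of an ecozone threshold table: for each variable, the
#' arithmetic mean over ecozones of the per-ecozone means and, in
#' parentheses in the printed form, the mean of the per-ecozone s.d. values.
#' Values are rounded to 1 decimal for display.
#'
#' @param estimates long data frame with `variable`, `mean`, `sd` (one row
#'   per ecozone × variable), e.g. from [estimate_thresholds()].
#' @return data frame: `variable`, `mean`, `sd` (rounded, 1 dp).
#' @export
summarize_ecozone_table <- function(estimates) {
  vs <- unique(estimates$variable)
  data.frame(
    variable = vs,
    mean = vapply(vs, function(v)
      round(mean(estimates$mean[estimates$variable == v]), 1), numeric(1)),
    sd = vapply(vs, function(v)
      round(mean(estimates$sd[estimates$variable == v]), 1), numeric(1)),
    row.names = NULL)
}
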