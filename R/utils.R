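# Shared small helpers: seasons, weighted quantiles, planar geometry.

#' Meteorological season of a date
#'
#' Maps month to `"MAM"` (spring), `"JJA"` (summer) or `"SON"` (fall).
#' December–February return `NA`: winter rows are kept in annual pools but
#' excluded from seasonal strata.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @return character vector of season codes, `NA` for winter.
#' @export
#' @examples
#' season_of(as.Date("2021-04-15"))  # "MAM"
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  s <- rep(NA_character_, length(m))
  s[m %in% 3:5] <- "MAM"
  s[m %in% 6:8] <- "JJA"
  s[m %in% 9:11] <- "SON"
  s
}

#' Area-weighted quantile with linear interpolation
#'
#' The empirical oracle behind the spread-day threshold: values are sorted,
#' mass is accumulated, and the cumulative fraction is attributed to each
#' distinct value at the midpoint of its step, then linearly interpolated.
#' With two equal masses at 80 and 90 the median is 85; with all mass at one
#' value the quantile is that value.
#'
#' @param x numeric values.
#' @param w nonnegative weights (areas), same length as `x`.
#' @param p probability in `[0, 1]` (default 0.5, the weighted median).
#' @return the interpolated quantile, clamped to `range(x)`.
#' @export
weighted_quantile <- function(x, w, p = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), p >= 0, p <= 1)
  keep <- is.finite(x) & is.finite(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) stop("no rows with positive weight")
  o <- order(x)
  xs <- x[o]; ws <- w[o]
  grp <- cumsum(c(TRUE, diff(xs) != 0))   # exact tie grouping
  v <- xs[!duplicated(grp)]
  m <- as.numeric(tapply(ws, grp, sum))
  m <- m / sum(m)
  cum <- cumsum(m)
  cmid <- cum - m / 2
  if (length(v) == 1L) return(v)
  if (p <= cmid[1]) return(v[1])
  if (p >= cmid[length(v)]) return(v[length(v)])
  approx(cmid, v, xout = p, ties = "ordered")$y
}

# --- planar geometry -------------------------------------------------------

# Shoelace area of a closed polygon given as x/y vertex vectors (first
# vertex not repeated). Units: those of the coordinates, squared.
poly_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

points_in_poly <- function(px, py, vx, vy) {
  pracma::inpolygon(px, py, vx, vy, boundary = TRUE)
}

# Distance from points to a polygon: 0 inside, else nearest edge distance.
dist_to_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- points_in_poly(px, py, vx, vy)
  d <- rep(Inf, length(px))
  x2 <- c(vx[-1], vx[1]); y2 <- c(vy[-1], vy[1])
  for (i in seq_len(n)) {
    d <- pmin(d, .dist_point_segment(px, py, vx[i], vy[i], x2[i], y2[i]))
  }
  d[inside] <- 0
  d
}

.dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

# Deterministic per-stream seed derived from a master seed and a label,
# kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
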