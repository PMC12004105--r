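# Minimal geostatistics for the downscaling step: empirical variogram, WLS
# fit over a small model family, ordinary kriging, IDW fallback.

.vgm_models <- c("spherical", "exponential", "gaussian")

.vgm_eval <- function(h, model, nugget, psill, range) {
  s <- switch(model,
    spherical = ifelse(h < range,
                       1.5 * h / range - 0.5 * (h / range)^3, 1),
    exponential = 1 - exp(-3 * h / range),
    gaussian = 1 - exp(-3 * (h / range)^2))
  out <- nugget + psill * s
  out[h == 0] <- 0  # exactness convention
  out
}

#' Empirical semivariogram of scattered values
#'
#' @param x,y coordinates (m); `z` values.
#' @param n_bins number of distance bins (default 10).
#' @param cutoff maximum pair distance considered; default half the maximum
#'   distance.
#' @return data frame `dist`, `gamma`, `n` (pairs per bin); empty bins
#'   dropped.
#' @export
empirical_variogram <- function(x, y, z, n_bins = 10, cutoff = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 2) stop("need at least 2 points")
  dmat <- as.matrix(dist(cbind(x, y)))
  gmat <- 0.5 * outer(z, z, "-")^2
  iu <- upper.tri(dmat)
  d <- dmat[iu]; g <- gmat[iu]
  if (is.null(cutoff)) cutoff <- max(d) / 2
  keep <- d <= cutoff & d > 0
  d <- d[keep]; g <- g[keep]
  if (!length(d)) return(data.frame(dist = numeric(), gamma = numeric(),
                                    n = integer()))
  br <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE)
  out <- data.frame(dist = tapply(d, bin, mean),
                    gamma = tapply(g, bin, mean),
                    n = as.integer(table(bin)))
  out[complete.cases(out) & out$n > 0, , drop = FALSE]
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget/partial-sill/range for spherical, exponential and Gaussian
#' models to an empirical variogram (weights `n / dist^2`) and keeps the
#' best. Failure — too few bins, non-convergence, or a non-positive sill —
#' returns `NULL`, signalling the caller to fall back to inverse-distance
#' weighting.
#'
#' @param ev empirical variogram from [empirical_variogram()].
#' @return list (`model`, `nugget`, `psill`, `range`, `sse`) or `NULL`.
#' @export
fit_variogram <- function(ev) {
  if (is.null(ev) || nrow(ev) < 3) return(NULL)
  if (all(ev$gamma < 1e-12)) return(NULL)
  w <- ev$n / pmax(ev$dist, 1)^2
  best <- NULL
  for (model in .vgm_models) {
    obj <- function(par) {
      nug <- exp(par[1]); ps <- exp(par[2]); rg <- exp(par[3])
      sum(w * (ev$gamma - .vgm_eval(ev$dist, model, nug, ps, rg))^2)
    }
    init <- log(c(max(min(ev$gamma), 1e-8),
                  max(max(ev$gamma) - min(ev$gamma), 1e-8),
                  max(ev$dist) * 0.6))
    ft <- tryCatch(optim(init, obj, method = "Nelder-Mead",
                         control = list(maxit = 500)),
                   error = function(e) NULL)
    if (is.null(ft) || ft$convergence != 0) next
    cand <- list(model = model, nugget = exp(ft$par[1]),
                 psill = exp(ft$par[2]), range = exp(ft$par[3]),
                 sse = ft$value)
    if (cand$psill <= 1e-10) next
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  best
}

# Ordinary kriging of residuals; exact at data points when nugget acts only
# off-zero (gamma(0) = 0). Returns NULL on a singular system.
.krige_ok <- function(x, y, z, tx, ty, vg) {
  n <- length(x)
  G <- .vgm_eval(as.matrix(dist(cbind(x, y))), vg$model, vg$nugget,
                 vg$psill, vg$range)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(tx, x, "-")^2 + outer(ty, y, "-")^2)
  B <- rbind(t(.vgm_eval(d0, vg$model, vg$nugget, vg$psill, vg$range)),
             1)
  lam <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(lam)) return(NULL)
  as.numeric(crossprod(lam[seq_len(n), , drop = FALSE], z))
}

.idw <- function(x, y, z, tx, ty, power = 2) {
  d2 <- outer(tx, x, "-")^2 + outer(ty, y, "-")^2
  out <- numeric(length(tx))
  for (i in seq_along(tx)) {
    hit <- which(d2[i, ] < 1e-12)
    if (length(hit)) { out[i] <- z[hit[1]]; next }
    w <- 1 / d2[i, ]^(power / 2)
    out[i] <- sum(w * z) / sum(w)
  }
  out
}
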