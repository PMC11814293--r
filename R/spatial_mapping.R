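#' Empirical correlogram of station values
#'
#' Computes the empirical semivariogram over distance-lag bins (the
#' Matheron moment estimator) and expresses it as a correlogram,
#' `corr(h) = 1 - gamma(h) / var(values)`, the form used to judge how far
#' spatial dependence reaches before interpolating. Bins with fewer than
#' 10 station pairs are flagged unreliable. A Moran's I estimator per
#' distance class is available as an alternative.
#'
#' @param x,y station coordinates (m).
#' @param values the station measurements (>= 10 stations, non-constant).
#' @param bins numeric vector of bin edges (m); default 10 bins of width
#'   `spacing / 2` from 0 up to `5 * spacing`.
#' @param spacing grid spacing used for the default bins (m).
#' @param estimator `"variogram"` (default) or `"moran"`.
#' @return object of class `correlogram`: data.frame with `lag` (bin
#'   midpoint), `correlation`, `gamma`, `n_pairs`, `reliable`; attributes
#'   `variance` and `estimator`.
#' @export
estimate_correlogram <- function(x, y, values, bins = NULL, spacing = 500,
                                 estimator = c("variogram", "moran")) {
  estimator <- match.arg(estimator)
  n <- length(values)
  if (n < 10L) stop("need at least 10 stations", call. = FALSE)
  s2 <- stats::var(values)
  if (!is.finite(s2) || s2 <= 0) {
    stop("values have zero variance; correlogram is degenerate", call. = FALSE)
  }
  if (is.null(bins)) bins <- seq(0, 5 * spacing, by = spacing / 2)
  d <- stats::dist(cbind(x, y))
  dv <- as.vector(d)
  cls <- cut(dv, bins, include.lowest = FALSE)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  if (estimator == "variogram") {
    sq <- (values[ii] - values[jj])^2 / 2
    gamma <- tapply(sq, cls, mean)
    npairs <- tapply(sq, cls, length)
    corr <- 1 - gamma / s2
  } else {
    zc <- values - mean(values)
    prod <- zc[ii] * zc[jj]
    m2 <- sum(zc^2) / n
    corr <- tapply(prod, cls, mean) / m2
    npairs <- tapply(prod, cls, length)
    gamma <- s2 * (1 - corr)
  }
  npairs[is.na(npairs)] <- 0
  out <- data.frame(
    lag = (bins[-length(bins)] + bins[-1]) / 2,
    lag_lo = bins[-length(bins)], lag_hi = bins[-1],
    correlation = as.vector(corr), gamma = as.vector(gamma),
    n_pairs = as.vector(npairs))
  out$reliable <- out$n_pairs >= 10
  structure(out, variance = s2, estimator = estimator,
            class = c("correlogram", "data.frame"))
}

#' Construct a variogram model
#'
#' @param nugget non-negative nugget variance.
#' @param psill non-negative partial sill.
#' @param range positive range parameter (e-folding distance for the
#'   exponential family; `exp(-h/range)` correlation).
#' @param family `"exponential"` (default) or `"spherical"`.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(nugget, psill, range, family = c("exponential", "spherical")) {
  family <- match.arg(family)
  if (nugget < 0 || psill < 0) stop("nugget and psill must be >= 0", call. = FALSE)
  stopifnot_positive(range, "range")
  if (nugget + psill <= 0) stop("nugget + psill must be positive", call. = FALSE)
  structure(list(nugget = nugget, psill = psill, range = range,
                 family = family, converged = TRUE, unidentifiable = FALSE),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, psill %.4g, range %.4g m%s\n",
              x$family, x$nugget, x$psill, x$range,
              if (isTRUE(x$unidentifiable)) " (range unidentifiable)" else ""))
  invisible(x)
}

## model semivariance / covariance
vgm_gamma <- function(model, h) {
  s <- switch(model$family,
              exponential = 1 - exp(-h / model$range),
              spherical = ifelse(h >= model$range, 1,
                                 1.5 * h / model$range - 0.5 * (h / model$range)^3))
  model$nugget * (h > 0) + model$psill * s
}

vgm_cov <- function(model, h) {
  (model$nugget + model$psill) - vgm_gamma(model, h)
}

#' Fit a variogram model to an empirical correlogram
#'
#' Weighted least squares on the per-bin semivariances, with weights
#' equal to the pair counts; multiple range starting values guard
#' against local minima. If the fitted structure carries (almost) no
#' spatially correlated component, the range is flagged unidentifiable.
#'
#' @param cg a [estimate_correlogram()] result, or a data.frame with
#'   columns `lag`, `gamma`, `n_pairs`.
#' @param family variogram family passed to [variogram_model()].
#' @param min_pairs bins with fewer pairs are dropped before fitting.
#' @return a [variogram_model()] with fields `converged`,
#'   `unidentifiable` and `sse`.
#' @export
fit_variogram <- function(cg, family = c("exponential", "spherical"),
                          min_pairs = 10L) {
  family <- match.arg(family)
  use <- is.finite(cg$gamma) & cg$n_pairs >= min_pairs
  h <- cg$lag[use]; g <- cg$gamma[use]; w <- cg$n_pairs[use]
  if (length(h) < 3L) stop("need at least 3 usable lag bins", call. = FALSE)
  sill0 <- max(g)
  obj <- function(p) {
    m <- list(nugget = p[1], psill = p[2], range = p[3], family = family)
    sum(w * (g - vgm_gamma(m, h))^2)
  }
  ## the range is not identifiable beyond the observed lag span; bound it
  ## at twice the largest usable lag
  lower <- c(0, 0, min(h) / 100)
  upper <- c(2 * sill0, 4 * sill0, 2 * max(h))
  starts <- lapply(c(0.25, 0.5, 1, 2), function(f)
    c(0.1 * sill0, 0.9 * sill0, f * max(h) / 3))
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("variogram fit failed to converge", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  m <- variogram_model(best$par[1], max(best$par[2], 1e-12), best$par[3],
                       family = family)
  m$converged <- best$convergence == 0
  m$sse <- best$value
  ## nugget-only data: no spatial structure to carry a range
  m$unidentifiable <- m$psill < 1e-6 * (m$nugget + m$psill) ||
    m$range <= lower[3] * 1.01
  m
}

## ---- ordinary kriging -------------------------------------------------

## Ordinary-kriging weights for prediction points (columns of the
## returned matrix); solves the bordered system
##   [ C  1 ] [lambda]   [ c0 ]
##   [ 1' 0 ] [  mu  ] = [ 1  ]
## once via an LU factorisation shared across prediction points.
ok_weights <- function(sx, sy, model, px, py) {
  n <- length(sx)
  d <- as.matrix(stats::dist(cbind(sx, sy)))
  C <- vgm_cov(model, d)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  dp <- sqrt(outer(sx, px, "-")^2 + outer(sy, py, "-")^2)
  B <- rbind(vgm_cov(model, dp), 1)
  solve(A, B)
}

#' Ordinary-kriging prediction at arbitrary points
#'
#' Point-support companion of [interpolate()]: predicts at the supplied
#' coordinates instead of a regular grid. With a zero-nugget model the
#' prediction at a station location reproduces the observation exactly.
#' A singular kriging system (e.g. duplicated stations with zero nugget)
#' falls back to nearest-neighbour prediction with a warning.
#'
#' @param sx,sy,values stations and their measurements.
#' @param px,py prediction coordinates.
#' @param model a [variogram_model()].
#' @return numeric vector of predictions at (`px`, `py`).
#' @export
krige_points <- function(sx, sy, values, px, py, model) {
  sol <- tryCatch(ok_weights(sx, sy, model, px, py), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular kriging system; falling back to nearest neighbour")
    nn <- apply(sqrt(outer(sx, px, "-")^2 + outer(sy, py, "-")^2), 2, which.min)
    return(values[nn])
  }
  as.vector(crossprod(sol[seq_along(values), , drop = FALSE], values))
}

#' Ordinary-kriging interpolation onto a regular grid
#'
#' Interpolates station values onto a fine regular grid (25 m by
#' default, the resolution used for published abundance maps) with
#' ordinary kriging under the fitted variogram model. Weights sum to one
#' at every cell (unbiasedness); with a zero nugget the surface honours
#' the data exactly at station locations. Cells farther than three
#' ranges from every station are flagged low-confidence. An optional
#' `log1p` transform accommodates right-skewed density fields; note the
#' back-transformed mean is a median-type estimate and carries
#' retransformation bias.
#'
#' @param x,y,values stations and their measurements (>= 2 stations).
#' @param model a [variogram_model()].
#' @param resolution grid resolution (m).
#' @param extent `c(xmin, xmax, ymin, ymax)`; defaults to the station
#'   bounding box.
#' @param transform `"none"` or `"log1p"`.
#' @return list of class `kriged_map`: `prediction` ([mud_raster()]),
#'   `low_confidence` (logical raster), `weight_sum_error` (max
#'   deviation of any cell's weight sum from 1), `model`, `stations`.
#' @export
interpolate <- function(x, y, values, model, resolution = 25, extent = NULL,
                        transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  if (length(values) < 2L) stop("need at least 2 stations", call. = FALSE)
  if (!inherits(model, "variogram_model")) stop("need a variogram_model", call. = FALSE)
  z <- if (transform == "log1p") log1p(values) else values
  if (is.null(extent)) extent <- c(min(x), max(x), min(y), max(y))
  nxc <- max(1L, ceiling((extent[2] - extent[1]) / resolution))
  nyc <- max(1L, ceiling((extent[4] - extent[3]) / resolution))
  gx <- extent[1] + (rep(seq_len(nxc), each = nyc) - 0.5) * resolution
  gy <- extent[3] + (rep(seq_len(nyc), times = nxc) - 0.5) * resolution

  sol <- tryCatch(ok_weights(x, y, model, gx, gy), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular kriging system; falling back to nearest neighbour")
    nn <- apply(sqrt(outer(x, gx, "-")^2 + outer(y, gy, "-")^2), 2, which.min)
    pred <- z[nn]
    werr <- NA_real_
  } else {
    W <- sol[seq_along(z), , drop = FALSE]
    pred <- as.vector(crossprod(W, z))
    werr <- max(abs(colSums(W) - 1))
  }
  if (transform == "log1p") pred <- expm1(pred)
  dmin <- sqrt(outer(x, gx, "-")^2 + outer(y, gy, "-")^2)
  lowconf <- apply(dmin, 2, min) > 3 * model$range
  structure(
    list(prediction = mud_raster(matrix(pred, nyc, nxc), extent[1], extent[3],
                                 resolution),
         low_confidence = mud_raster(matrix(lowconf, nyc, nxc), extent[1],
                                     extent[3], resolution),
         weight_sum_error = werr, model = model,
         stations = data.frame(x = x, y = y, value = values)),
    class = "kriged_map")
}
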