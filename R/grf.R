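## Gaussian-random-field simulation with exponential covariance.
##
## The exponential model is parameterised throughout the package as
##   cov(h)   = psill * exp(-h / range)
##   gamma(h) = nugget + psill * (1 - exp(-h / range))
## so `range` is the e-folding distance (practical range ~ 3 * range).
## Correlogram shapes seen in mudflat monitoring decay smoothly and
## monotonically, which this family captures with one shape parameter.

exp_cov <- function(h, psill, range) psill * exp(-h / range)

exp_semivariance <- function(h, nugget, psill, range) {
  nugget * (h > 0) + psill * (1 - exp(-h / range))
}

## Simulate one or more zero-mean GRF draws at arbitrary coordinates by
## Cholesky factorisation of the covariance matrix. `nugget` adds white
## noise; `range = 0` or `psill = 0` degenerate cleanly to pure nugget /
## constant fields. Returns an n x ndraw matrix.
sim_grf <- function(x, y, nugget = 0, psill = 1, range = 500, ndraw = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  out <- matrix(0, n, ndraw)
  if (psill > 0 && range > 0) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    C <- exp_cov(d, psill, range)
    diag(C) <- psill + 1e-9 * psill  # jitter for numerical PD
    L <- chol(C)
    out <- crossprod(L, matrix(stats::rnorm(n * ndraw), n, ndraw))
  }
  if (nugget > 0) {
    out <- out + sqrt(nugget) * matrix(stats::rnorm(n * ndraw), n, ndraw)
  }
  out
}
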