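## Internal helpers: seeded evaluation, truncated normals, windowed means.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded simulation calls do not disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

## Deterministic sub-seed derivation; keeps results < 2^31 so they remain
## valid R integer seeds.
derive_seed <- function(master_seed, index) {
  s <- (abs(as.double(master_seed)) %% 2147483647) * 10007 + index * 7919 + 1
  as.integer(s %% 2147483647)
}

## Truncated normal draws via inverse-CDF; sd = 0 collapses to the mean
## (used by the zero-variance-prior determinism contract).
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## Mean of a sampled signal over the trailing `span` seconds, computed by
## trapezoidal integration with linear interpolation of the fractional
## starting sample. Second-order accurate in the sample interval, which is
## what makes cardiac-cycle averaging insensitive to the cycle length not
## being a whole number of samples.
trailing_mean <- function(x, dt, span) {
  n <- length(x)
  total <- (n - 1) * dt
  if (span > total + 1e-9) span <- total
  a <- total - span
  i0 <- min(n - 1L, as.integer(floor(a / dt + 1e-12)) + 1L)
  t0 <- (i0 - 1) * dt
  xs <- x[i0:n]
  integral <- sum((xs[-1] + xs[-length(xs)]) / 2) * dt
  if (a > t0 + 1e-12) {
    xa <- x[i0] + (x[i0 + 1L] - x[i0]) * (a - t0) / dt
    integral <- integral - (a - t0) * (x[i0] + xa) / 2
  }
  integral / span
}

## Linear-prediction refinement of a sinusoid's period. For x = C + tone,
## the first difference y is a pure tone satisfying
## y[k+1] + y[k-1] = 2 cos(w dt) y[k] exactly, so the least-squares ratio
## recovers the period to machine precision on noise-free data. Returns NA
## when the data do not follow the recurrence (noise, multiple components),
## judged by proximity to the autocorrelation estimate `p0`.
prony_refine <- function(x, dt, p0) {
  y <- diff(x)
  m <- length(y)
  if (m < 5) return(NA_real_)
  k <- 2:(m - 1)
  denom <- 2 * sum(y[k]^2)
  if (denom <= 0) return(NA_real_)
  ct <- sum(y[k] * (y[k - 1] + y[k + 1])) / denom
  if (abs(ct) >= 1) return(NA_real_)
  p <- 2 * pi * dt / acos(ct)
  if (!is.finite(p) || abs(p - p0) > max(2 * dt, 0.05 * p0)) {
    return(NA_real_)
  }
  p
}

## Cardiac cycle length (s) from the unbiased sample autocorrelation of a
## windowed signal, searched in `lag_band` and refined by parabolic
## interpolation around the peak. Returns NA when no positive-correlation
## peak exists in the band (e.g. no periodic component).
estimate_cycle <- function(x, dt, lag_band = c(0.4, 2)) {
  n <- length(x)
  x <- x - mean(x)
  if (sum(x * x) <= 0) return(NA_real_)
  max_lag <- min(floor(lag_band[2] / dt), floor((n - 1) / 2))
  min_lag <- max(1L, ceiling(lag_band[1] / dt))
  if (max_lag - min_lag < 2) return(NA_real_)
  lags <- min_lag:max_lag
  r <- vapply(lags, function(k) {
    sum(x[1:(n - k)] * x[(k + 1):n]) / (n - k)
  }, numeric(1))
  i <- which.max(r)
  if (r[i] <= 0) return(NA_real_)
  k <- lags[i]
  if (i > 1 && i < length(r)) {
    denom <- r[i - 1] - 2 * r[i] + r[i + 1]
    delta <- if (abs(denom) > .Machine$double.eps) {
      0.5 * (r[i - 1] - r[i + 1]) / denom
    } else 0
    delta <- max(-0.5, min(0.5, delta))
    k <- k + delta
  }
  k * dt
}
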