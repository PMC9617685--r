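#' Generate the benchmark simulated series with known ground truth
#'
#' Builds an 800-point Gaussian series around a deterministic skeleton with
#' the same qualitative structure used to benchmark the method: sudden mean
#' shifts at positions 49, 60, 600, 699 and 700 (including an isolated
#' single-point segment at index 700), an increasing linear ramp over indices
#' 201–400, and a sinusoidal seasonal pattern over indices 401–600. The
#' shift/trend positions are the benchmark's; the effect sizes (5-sigma
#' jumps, an 8-sigma total ramp rise, a 3-sigma seasonal amplitude with
#' period 50) are this package's defaults, calibrated so that recovery is
#' unambiguous. The ramp starts at slope `ramp_rise / diff(linear_interval)`
#' from the pre-trend baseline, so its onset is shallow and its detected
#' start may lag the true start.
#'
#' @param seed optional integer seed.
#' @param n series length (default 800).
#' @param sigma noise standard deviation (default 1).
#' @param jump mean-shift size in units of `sigma` (default 5).
#' @param ramp_rise total rise of the linear trend in units of `sigma`
#'   (default 8).
#' @param amplitude seasonal amplitude in units of `sigma` (default 3).
#' @param period seasonal period in observations (default 50).
#' @param shift_positions the five sudden mean-shift positions.
#' @param linear_interval,seasonal_interval inclusive index ranges of the
#'   linear and seasonal trends; must not overlap.
#' @return A list with `series` (an `ascept_series`), `truth` (list with
#'   `mean_shift_positions`, `linear_interval`, `seasonal_interval`,
#'   `params`), and `skeleton` (the noiseless mean vector).
#' @export
generate_benchmark <- function(seed = NULL, n = 800L, sigma = 1,
                               jump = 5, ramp_rise = 8, amplitude = 3,
                               period = 50,
                               shift_positions = c(49L, 60L, 600L, 699L, 700L),
                               linear_interval = c(201L, 400L),
                               seasonal_interval = c(401L, 600L)) {
  n <- as.integer(n)
  if (n < 2L || sigma <= 0) {
    stop("need n >= 2 and sigma > 0")
  }
  li <- as.integer(linear_interval)
  si <- as.integer(seasonal_interval)
  if (length(li) != 2L || length(si) != 2L || li[1L] > li[2L] ||
    si[1L] > si[2L] || min(li, si) < 1L || max(li, si) > n) {
    stop("trend intervals must be ordered and lie within [1, n]")
  }
  if (li[1L] <= si[2L] && si[1L] <= li[2L]) {
    stop("linear and seasonal intervals must not overlap")
  }
  p <- validate_changepoints(shift_positions, n)
  if (length(p) != 5L) {
    stop("expected five mean-shift positions")
  }

  # skeleton: baseline 0; a +jump spike between shifts 1 and 2; a ramp from
  # the baseline up to ramp_rise; the seasonal pattern oscillating around the
  # ramp's endpoint; then -jump, a one-point +jump spike, and -jump again.
  base2 <- ramp_rise - jump # level after the shift ending the seasonal block
  mu <- numeric(n)
  mu[1:p[1L]] <- 0
  mu[(p[1L] + 1L):p[2L]] <- jump * sigma
  mu[(p[2L] + 1L):(li[1L] - 1L)] <- 0
  ramp_t <- li[1L]:li[2L]
  mu[ramp_t] <- ramp_rise * sigma * (ramp_t - (li[1L] - 1L)) /
    (li[2L] - li[1L] + 1L)
  seas_t <- si[1L]:si[2L]
  mu[seas_t] <- ramp_rise * sigma +
    amplitude * sigma * sin(2 * pi * (seas_t - si[1L] + 1L) / period)
  mu[(p[3L] + 1L):p[4L]] <- base2 * sigma
  mu[(p[4L] + 1L):p[5L]] <- (base2 + jump) * sigma
  mu[(p[5L] + 1L):n] <- base2 * sigma

  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  y <- mu + stats::rnorm(n, sd = sigma)
  list(
    series = as_series(y),
    truth = list(
      mean_shift_positions = p,
      linear_interval = li,
      seasonal_interval = si,
      params = list(
        n = n, sigma = sigma, jump = jump, ramp_rise = ramp_rise,
        amplitude = amplitude, period = period, seed = seed
      )
    ),
    skeleton = mu
  )
}

#' Generate a pure white-noise series
#'
#' The null fixture: i.i.d. Normal draws with no changepoints, used to
#' exercise false-positive control.
#'
#' @param n series length (>= 2).
#' @param mu,sigma Normal mean and standard deviation (`sigma > 0`).
#' @param seed optional integer seed.
#' @return An `ascept_series`.
#' @export
generate_noise <- function(n, mu = 0, sigma = 1, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) {
    stop("n must be >= 2")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be positive")
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  as_series(stats::rnorm(n, mean = mu, sd = sigma))
}
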