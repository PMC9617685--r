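# Independent oracles used across the suite.

# Minus twice the sum of Normal log-densities at the segment's fitted mean
# and (floored) sd — the definitional check for segment_cost, computed the
# slow way through dnorm.
density_sum_cost <- function(y, sd_floor) {
  m <- mean(y)
  s <- max(sqrt(sum((y - m)^2) / length(y)), sd_floor)
  -2 * sum(stats::dnorm(y, mean = m, sd = s, log = TRUE))
}

# Exhaustive minimum of the penalized segmentation objective over all
# 2^(n-1) changepoint subsets (bitmask enumeration), honoring a minimum
# segment length. Independent of the PELT dynamic program.
exhaustive_objective <- function(y, penalty, min_seg_len = 1L,
                                 sd_floor = 1e-8) {
  n <- length(y)
  stopifnot(n <= 14L)
  cost <- matrix(Inf, n, n)
  for (a in 1:n) {
    for (b in a:n) {
      cost[a, b] <- segment_cost(y[a:b], sd_floor)
    }
  }
  pow <- 2^(0:(n - 2L))
  best <- Inf
  for (code in 0:(2^(n - 1L) - 1L)) {
    cps <- which(bitwAnd(code, pow) > 0)
    bounds <- c(0L, cps, n)
    lens <- diff(bounds)
    if (any(lens < min_seg_len)) next
    tot <- penalty * length(cps)
    for (i in seq_along(lens)) {
      tot <- tot + cost[bounds[i] + 1L, bounds[i + 1L]]
    }
    if (tot < best) best <- tot
  }
  best
}

# Raw periodogram peak on the plain Fourier grid k/n — the coarse reference
# against which the oversampled estimator is compared.
fourier_grid_period <- function(y) {
  n <- length(y)
  x <- y - mean(y)
  pw <- Mod(stats::fft(x))^2 / n
  ks <- seq_len(n %/% 2L)
  n / ks[which.max(pw[ks + 1L])]
}
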