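#' Gaussian log-likelihood of a segmentation
#'
#' Sum over induced segments of the Normal log-density evaluated at the
#' segment's maximum-likelihood mean and (floored) standard deviation.
#' Identically equal to `-0.5 *` the total [segment_cost()].
#'
#' @inheritParams pelt
#' @param cps changepoint positions (possibly empty).
#' @return A single number.
#' @examples
#' gaussian_loglik(c(0, 2), integer(0)) # -log(2*pi) - 1
#' @export
gaussian_loglik <- function(series, cps = integer(0L), sd_floor = NULL) {
  s <- as_series(series)
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(s$values)
  }
  -0.5 * total_cost(s$values, cps, sd_floor)
}

# Per-observation segment mean and (floored) sd vectors for a segmentation —
# the null model that both simulate_null_series() and the vectorized
# Monte-Carlo sampler draw from.
segment_mu_sd <- function(y, cps, sd_floor) {
  b <- segment_bounds(cps, length(y))
  mu <- numeric(length(y))
  sdv <- numeric(length(y))
  for (i in seq_len(nrow(b))) {
    idx <- b[i, 1L]:b[i, 2L]
    m <- mean(y[idx])
    v <- sum((y[idx] - m)^2) / length(idx)
    mu[idx] <- m
    sdv[idx] <- max(sqrt(v), sd_floor)
  }
  list(mu = mu, sd = sdv, bounds = b)
}

#' Simulate one null series under a segmentation
#'
#' Draws independent Normal observations segment-wise, with each segment's
#' mean and (floored) standard deviation taken from the observed data — the
#' parametric-bootstrap null used by the stage-1 significance tests.
#'
#' @inheritParams gaussian_loglik
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @return An `ascept_series` of the same length and labels as the input.
#' @export
simulate_null_series <- function(series, cps = integer(0L), seed = NULL,
                                 sd_floor = NULL) {
  s <- as_series(series)
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(s$values)
  }
  ms <- segment_mu_sd(s$values, cps, sd_floor)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  as_series(stats::rnorm(s$n, mean = ms$mu, sd = ms$sd), labels = s$labels)
}

# Log-likelihood of each column of a draw matrix under a fixed segmentation,
# vectorized across draws (columns).
loglik_matrix <- function(Y, bounds, floor2) {
  nc <- ncol(Y)
  cost <- numeric(nc)
  for (i in seq_len(nrow(bounds))) {
    a <- bounds[i, 1L]
    b <- bounds[i, 2L]
    ns <- b - a + 1L
    block <- Y[a:b, , drop = FALSE]
    s1 <- .colSums(block, ns, nc)
    s2 <- .colSums(block * block, ns, nc)
    m <- s1 / ns
    v <- if (ns == 1L) numeric(nc) else pmax(s2 / ns - m * m, 0)
    ve <- pmax(v, floor2)
    cost <- cost + ns * (log(2 * pi) + log(ve) + v / ve)
  }
  -0.5 * cost
}

#' Empirical P-value for one path comparison
#'
#' Tests whether the richer set `Tk1` significantly improves the Gaussian
#' log-likelihood over the current set `Tk`. Null series are drawn
#' segment-wise under `Tk` ([simulate_null_series()]); both changepoint sets
#' are imposed unchanged on every draw (no re-detection), and the add-one
#' empirical estimate `p = (1 + #{null deltas >= observed}) / (N + 1)` is
#' returned — conservative and never zero.
#'
#' @inheritParams gaussian_loglik
#' @param Tk,Tk1 the current and proposed changepoint sets. `Tk1` need not
#'   contain `Tk`.
#' @param n_sim number of Monte-Carlo draws N (default 10000).
#' @param seed optional integer seed for the draws.
#' @return An object of class `ascept_mc`: list with `observed_delta`,
#'   `null_deltas`, `p_value`, `n_sim`.
#' @export
empirical_pvalue <- function(series, Tk, Tk1, n_sim = 10000L, seed = NULL,
                             sd_floor = NULL) {
  s <- as_series(series)
  n_sim <- as.integer(n_sim)
  if (n_sim < 1L) {
    stop("n_sim must be >= 1")
  }
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(s$values)
  }
  fl2 <- sd_floor^2
  y <- s$values
  b0 <- segment_bounds(Tk, s$n)
  b1 <- segment_bounds(Tk1, s$n)
  observed <- gaussian_loglik(s, Tk1, sd_floor) -
    gaussian_loglik(s, Tk, sd_floor)

  ms <- segment_mu_sd(y, Tk, sd_floor)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  Y <- matrix(stats::rnorm(s$n * n_sim), nrow = s$n) * ms$sd + ms$mu
  deltas <- loglik_matrix(Y, b1, fl2) - loglik_matrix(Y, b0, fl2)
  p <- (1 + sum(deltas >= observed)) / (n_sim + 1)

  structure(
    list(
      observed_delta = observed,
      null_deltas = deltas,
      p_value = p,
      n_sim = n_sim
    ),
    class = "ascept_mc"
  )
}

#' Stage 1: fixed-sequence Monte-Carlo selection along the candidate path
#'
#' Walks the candidate path T0, T1, ... in order, testing each consecutive
#' pair with [empirical_pvalue()]. While the test rejects at level `alpha`
#' the richer set is adopted; the walk stops at the first non-rejection and
#' returns the last adopted set. Because each test is only reached after all
#' earlier rejections, this fixed-sequence procedure controls the family-wise
#' error rate at `alpha`.
#'
#' @inheritParams empirical_pvalue
#' @param path an `ascept_path` from [build_candidate_path()].
#' @param alpha significance level (default 0.01).
#' @param seed root integer seed; each comparison derives its own seed from
#'   it, so results are reproducible.
#' @param verbose if `TRUE`, log one line per test (k, delta, p).
#' @return An object of class `ascept_stage1`: list with `selected`
#'   (changepoint positions), `selected_k`, `tests` (list of `ascept_mc`,
#'   each with the path index `k` attached), `alpha`, `exhausted`.
#' @export
select_stage1 <- function(series, path, alpha = 0.01, n_sim = 10000L,
                          seed = NULL, sd_floor = NULL, verbose = FALSE) {
  stopifnot(inherits(path, "ascept_path"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  s <- as_series(series)
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(s$values)
  }
  tests <- list()
  k <- 0L
  exhausted <- TRUE
  while (k < path$K) {
    seed_k <- if (is.null(seed)) NULL else derive_seed(seed, k + 1L)
    mc <- empirical_pvalue(
      s, path_entry(path, k), path_entry(path, k + 1L),
      n_sim = n_sim, seed = seed_k, sd_floor = sd_floor
    )
    mc$k <- k
    tests[[length(tests) + 1L]] <- mc
    if (verbose) {
      message(sprintf(
        "stage1: T%d -> T%d  delta_ll = %.2f  p = %.4g",
        k, k + 1L, mc$observed_delta, mc$p_value
      ))
    }
    if (mc$p_value <= alpha) {
      k <- k + 1L
    } else {
      exhausted <- FALSE
      break
    }
  }
  if (exhausted && path$K > 0L) {
    warning(
      "candidate path exhausted at T", path$K,
      "; consider a wider penalty range (smaller beta_min)"
    )
  }
  structure(
    list(
      selected = path_entry(path, k),
      selected_k = k,
      tests = tests,
      alpha = alpha,
      exhausted = exhausted
    ),
    class = "ascept_stage1"
  )
}

# Deterministic sub-seed for comparison k of a run with root seed `seed`.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

#' @export
print.ascept_stage1 <- function(x, ...) {
  cat(
    "<ascept_stage1> selected T", x$selected_k, " (",
    length(x$selected), " changepoints) after ", length(x$tests),
    " tests at alpha = ", x$alpha, "\n",
    sep = ""
  )
  invisible(x)
}
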