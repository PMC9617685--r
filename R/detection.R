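#' Gaussian segment cost
#'
#' Cost of one segment under the Gaussian mean-and-variance model: minus twice
#' the log-likelihood maximized over the segment mean and over all variances
#' at or above the floor,
#' \deqn{C(y) = n (\log 2\pi + \log \hat\sigma_e^2 + \hat\sigma^2/\hat\sigma_e^2),}
#' where \eqn{\hat\sigma^2} is the maximum-likelihood (divide-by-n) variance
#' and \eqn{\hat\sigma_e^2 = \max(\hat\sigma^2, }`sd_floor`\eqn{^2)}. For
#' segments above the floor this is the familiar
#' \eqn{n(\log 2\pi + \log\hat\sigma^2 + 1)}; at or below it, the constraint
#' binds and the last term drops below 1. Because the cost is a constrained
#' maximum likelihood, splitting a segment can never increase total cost, so
#' PELT's pruning stays exact for any floor. The cost always equals minus
#' twice the sum of Normal log-densities at \eqn{(\hat\mu, \hat\sigma_e)}.
#'
#' @param values numeric vector, the observations of one segment.
#' @param sd_floor lower bound for the segment standard deviation. Callers
#'   working on a whole series should pass the series-level floor (half the
#'   robust first-difference noise scale; see the package vignette); the
#'   default is the absolute minimum.
#' @return A single number, the segment cost.
#' @examples
#' segment_cost(c(0, 2)) # 2 * (log(2*pi) + log(1) + 1)
#' @export
segment_cost <- function(values, sd_floor = 1e-8) {
  y <- as.numeric(values)
  if (length(y) == 0L) {
    stop("segment_cost: empty segment")
  }
  if (!all(is.finite(y))) {
    stop("segment_cost: values must be finite")
  }
  n <- length(y)
  m <- mean(y)
  v <- sum((y - m)^2) / n
  ve <- max(v, sd_floor^2)
  n * (log(2 * pi) + log(ve) + v / ve)
}

# Cumulative-sum machinery shared by pelt() and the likelihood functions.
# cost of segment [a, b] (1-based inclusive), vectorized over a and/or b.
cost_cums <- function(y) {
  list(s1 = c(0, cumsum(y)), s2 = c(0, cumsum(y * y)))
}

seg_cost_from_cums <- function(cums, a, b, floor2) {
  ns <- b - a + 1
  m <- (cums$s1[b + 1L] - cums$s1[a]) / ns
  v <- pmax((cums$s2[b + 1L] - cums$s2[a]) / ns - m * m, 0)
  v[ns == 1] <- 0 # exact zero: the cumsum difference only leaves noise
  ve <- pmax(v, floor2)
  ns * (log(2 * pi) + log(ve) + v / ve)
}

# Total unpenalized cost of a segmentation.
total_cost <- function(y, cps, sd_floor) {
  b <- segment_bounds(cps, length(y))
  cums <- cost_cums(y)
  sum(seg_cost_from_cums(cums, b[, 1L], b[, 2L], sd_floor^2))
}

#' Exact penalized segmentation by PELT
#'
#' Finds the changepoint set minimizing total Gaussian segment cost plus a
#' constant penalty per changepoint, using the pruned exact dynamic program
#' (PELT). The solution is exact; among equal-objective segmentations the
#' one with fewer changepoints is preferred (then the smaller last-change
#' position), so output is deterministic.
#'
#' @param series numeric vector or [as_series()] object.
#' @param penalty nonnegative per-changepoint penalty \eqn{\beta}.
#' @param min_seg_len minimum segment length; the default 1 permits
#'   single-point segments (needed to capture one-day shifts).
#' @param sd_floor segment standard-deviation floor; default derived from the
#'   whole series via `max(1e-8, 1e-4 * sd)`.
#' @return Sorted integer vector of changepoint positions, with attribute
#'   `objective` (the minimized penalized cost).
#' @examples
#' y <- c(rnorm(10), rnorm(10, mean = 8))
#' pelt(y, penalty = 3 * log(20))
#' @export
pelt <- function(series, penalty, min_seg_len = 1L, sd_floor = NULL) {
  s <- as_series(series)
  y <- s$values
  n <- s$n
  msl <- as.integer(min_seg_len)
  if (msl < 1L) {
    stop("min_seg_len must be >= 1")
  }
  if (n < 2L * msl || n < 2L) {
    stop("series too short for the requested minimum segment length")
  }
  if (!is.finite(penalty) || penalty < 0) {
    stop("penalty must be a nonnegative number")
  }
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(y)
  }
  fl2 <- sd_floor^2
  cums <- cost_cums(y)

  # F[t+1] = optimal penalized cost of y[1..t] (F[1] = -penalty so that each
  # segment's +penalty counts changepoints, not segments); prev[t+1] = last
  # changepoint of the optimum; cnt[t+1] = its changepoint count (tie-break).
  F <- c(-penalty, rep(Inf, n))
  prev <- integer(n + 1L)
  cnt <- integer(n + 1L)
  cands <- 0L

  for (t in seq_len(n)) {
    elig <- cands[t - cands >= msl]
    if (length(elig) > 0L) {
      cost <- seg_cost_from_cums(cums, elig + 1L, t, fl2)
      tot <- F[elig + 1L] + cost + penalty
      fmin <- min(tot)
      if (is.finite(fmin)) {
        ties <- which(tot == fmin)
        if (length(ties) > 1L) {
          tc <- cnt[elig[ties] + 1L] + as.integer(elig[ties] > 0L)
          ties <- ties[tc == min(tc)]
          pick <- ties[which.min(elig[ties])]
        } else {
          pick <- ties
        }
        sbest <- elig[pick]
        F[t + 1L] <- fmin
        prev[t + 1L] <- sbest
        cnt[t + 1L] <- cnt[sbest + 1L] + as.integer(sbest > 0L)
        # prune: s stays a candidate only if it could still be optimal later
        keep <- elig[tot <= fmin + penalty]
        cands <- c(keep, cands[t - cands < msl], t)
      } else {
        cands <- c(cands, t)
      }
    } else {
      cands <- c(cands, t)
    }
  }

  pos <- integer(0L)
  sp <- prev[n + 1L]
  while (sp > 0L) {
    pos <- c(sp, pos)
    sp <- prev[sp + 1L]
  }
  structure(pos, objective = F[n + 1L])
}

#' Sweep PELT over a penalty range (CROPS)
#'
#' Recovers every distinct PELT solution attained for penalties in
#' `[beta_min, beta_max]`, each tagged with the penalty interval on which it
#' is optimal. Uses the interval-bisection recursion of the CROPS algorithm:
#' because the optimal penalized cost is piecewise linear in the penalty with
#' slope equal to the changepoint count, the crossing penalty of two known
#' solutions is `(Q_high - Q_low) / (m_low - m_high)` where `Q` is the
#' unpenalized cost and `m` the count.
#'
#' @inheritParams pelt
#' @param beta_min,beta_max penalty range, `0 < beta_min <= beta_max`.
#' @return A list of raw path entries ordered by increasing penalty, each a
#'   list with `beta_lo`, `beta_hi`, `positions`, `n_changepoints` and `cost`
#'   (unpenalized).
#' @seealso [build_candidate_path()] to turn the raw entries into a
#'   decreasing-penalty candidate path starting from the empty set.
#' @export
crops_sweep <- function(series, beta_min, beta_max, min_seg_len = 1L,
                        sd_floor = NULL) {
  s <- as_series(series)
  if (!is.finite(beta_min) || !is.finite(beta_max) ||
    beta_min <= 0 || beta_min > beta_max) {
    stop("need 0 < beta_min <= beta_max")
  }
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(s$values)
  }

  run <- function(beta) {
    cps <- pelt(s, beta, min_seg_len = min_seg_len, sd_floor = sd_floor)
    list(
      positions = as.integer(cps),
      m = length(cps),
      q = attr(cps, "objective") - beta * length(cps)
    )
  }

  lo <- run(beta_min)
  hi <- run(beta_max)

  recurse <- function(bl, sl, bh, sh) {
    if (sl$m <= sh$m) {
      # identical solution throughout (counts can only decrease with penalty)
      return(list(list(lo = bl, hi = bh, sol = sh)))
    }
    bstar <- (sh$q - sl$q) / (sl$m - sh$m)
    if (bstar <= bl || bstar >= bh) {
      # crossing outside the interval: one of the two dominates throughout
      win <- if (bstar <= bl) sh else sl
      return(list(list(lo = bl, hi = bh, sol = win)))
    }
    sm <- run(bstar)
    if (sm$m == sh$m) {
      list(
        list(lo = bl, hi = bstar, sol = sl),
        list(lo = bstar, hi = bh, sol = sh)
      )
    } else {
      c(recurse(bl, sl, bstar, sm), recurse(bstar, sm, bh, sh))
    }
  }

  iv <- recurse(beta_min, lo, beta_max, hi)
  lapply(iv, function(e) {
    list(
      beta_lo = e$lo,
      beta_hi = e$hi,
      positions = e$sol$positions,
      n_changepoints = e$sol$m,
      cost = e$sol$q
    )
  })
}

#' Assemble the candidate path T0..TK
#'
#' Orders raw sweep entries by decreasing penalty, collapses consecutive
#' duplicates, and prepends the empty set T0 (corresponding to an arbitrarily
#' large penalty) if the largest-penalty solution is nonempty, so the path
#' always starts from "no changepoints".
#'
#' @param raw list of raw entries from [crops_sweep()].
#' @param series the series the sweep was run on (used to record length and
#'   the unpenalized cost of the empty set).
#' @param sd_floor optional; as in [pelt()].
#' @return An object of class `ascept_path`: list with `entries` (each with
#'   `positions`, `beta_lo`, `beta_hi`, `cost`), indexable as T0..TK via
#'   [path_entry()], and `n` the series length.
#' @export
build_candidate_path <- function(raw, series, sd_floor = NULL) {
  s <- as_series(series)
  if (length(raw) == 0L) {
    stop("raw sweep entries must be nonempty")
  }
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(s$values)
  }
  ord <- order(vapply(raw, function(e) e$beta_hi, numeric(1L)),
    decreasing = TRUE
  )
  raw <- raw[ord]
  entries <- list()
  for (e in raw) {
    last <- if (length(entries)) entries[[length(entries)]]$positions else NULL
    if (!is.null(last) && identical(last, e$positions)) {
      entries[[length(entries)]]$beta_lo <- e$beta_lo
      next
    }
    entries[[length(entries) + 1L]] <- list(
      positions = e$positions,
      beta_lo = e$beta_lo,
      beta_hi = e$beta_hi,
      cost = e$cost
    )
  }
  if (length(entries[[1L]]$positions) > 0L) {
    entries <- c(
      list(list(
        positions = integer(0L),
        beta_lo = entries[[1L]]$beta_hi,
        beta_hi = Inf,
        cost = total_cost(s$values, integer(0L), sd_floor)
      )),
      entries
    )
  }
  structure(
    list(entries = entries, n = s$n, K = length(entries) - 1L),
    class = "ascept_path"
  )
}

#' Extract the k-th set of a candidate path
#'
#' @param path an `ascept_path`.
#' @param k path index, 0-based (`k = 0` is the empty set T0).
#' @return Integer vector of changepoint positions.
#' @export
path_entry <- function(path, k) {
  stopifnot(inherits(path, "ascept_path"))
  if (k < 0L || k > path$K) {
    stop("path index out of range 0..", path$K)
  }
  path$entries[[k + 1L]]$positions
}

#' @export
print.ascept_path <- function(x, ...) {
  sizes <- vapply(x$entries, function(e) length(e$positions), integer(1L))
  cat(
    "<ascept_path> K =", x$K, " set sizes:",
    paste(utils::head(sizes, 12L), collapse = " "),
    if (length(sizes) > 12L) "..." else "", "\n"
  )
  invisible(x)
}
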