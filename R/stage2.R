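#' Estimate a segment's period from the periodogram peak
#'
#' Computes the raw periodogram of the mean-centered values (no taper, no
#' detrending) and returns the period associated with the frequency of
#' maximal power. The spectrum is evaluated on a frequency grid oversampled
#' by zero-padding (factor `oversample`), restricted to frequencies between
#' 1/n and 1/2 so the estimated period always fits inside the segment; this
#' keeps the estimate accurate when the true period is not a divisor of the
#' segment length, which matters when short merged segments hold a fraction
#' of a seasonal cycle. Segments shorter than 4 points, or with (near-)zero
#' variance, have no usable spectral peak and return `NA` (infeasible).
#'
#' @param values numeric vector.
#' @param oversample frequency-grid oversampling factor (default 8; 1 gives
#'   the plain Fourier grid k/n).
#' @return The estimated period (a positive real), or `NA_real_` if
#'   infeasible.
#' @examples
#' estimate_period(sin(2 * pi * (1:200) / 20)) # 20
#' @export
estimate_period <- function(values, oversample = 8L) {
  y <- as.numeric(values)
  n <- length(y)
  if (n < 4L) {
    return(NA_real_)
  }
  x <- y - mean(y)
  if (sqrt(sum(x^2) / n) < 1e-12 * max(1, max(abs(y)))) {
    return(NA_real_)
  }
  os <- max(1L, as.integer(oversample))
  np <- os * n
  pw <- Mod(stats::fft(c(x, numeric(np - n))))^2 / n
  ks <- seq.int(os, np %/% 2L) # frequencies k/np in [1/n, 1/2]
  kstar <- ks[which.max(pw[ks + 1L])]
  np / kstar
}

#' Least-squares fit of one model kind to a segment
#'
#' Fits a constant, linear, or single-harmonic (intercept + sine + cosine at
#' a given period) model by least squares. The regressor is the global
#' 1-based index `t`, so fits on different segments share a common time axis
#' (phase differences are absorbed by the sine/cosine pair). Segments with no
#' more observations than parameters are fit exactly (RMSE 0).
#'
#' @param values numeric observations of the segment.
#' @param kind one of `"constant"`, `"linear"`, `"harmonic"`.
#' @param period period for the harmonic model; must be finite and greater
#'   than 2 (above the Nyquist limit) for a feasible harmonic fit.
#' @param t global 1-based indices of the observations (defaults to
#'   `seq_along(values)`).
#' @return An object of class `ascept_fit`: list with `kind`, `feasible`,
#'   `rmse` (`sqrt(sse / n)`), `sse`, `fitted`, `residuals`, `n`,
#'   `n_params`, `period` (harmonic only).
#' @export
fit_model <- function(values, kind = c("constant", "linear", "harmonic"),
                      period = NULL, t = seq_along(values)) {
  kind <- match.arg(kind)
  y <- as.numeric(values)
  n <- length(y)
  if (n == 0L) {
    stop("fit_model: empty segment")
  }
  if (length(t) != n) {
    stop("fit_model: t must match values in length")
  }

  if (kind == "harmonic" &&
    (is.null(period) || !is.finite(period) || period <= 2)) {
    return(structure(
      list(
        kind = kind, feasible = FALSE, rmse = NA_real_, sse = NA_real_,
        fitted = NULL, residuals = NULL, n = n, n_params = 3L,
        period = if (is.null(period)) NA_real_ else period
      ),
      class = "ascept_fit"
    ))
  }

  X <- switch(kind,
    constant = matrix(1, n, 1L),
    linear = cbind(1, t),
    harmonic = cbind(1, sin(2 * pi * t / period), cos(2 * pi * t / period))
  )
  p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  sse <- sum(res^2)
  structure(
    list(
      kind = kind,
      feasible = TRUE,
      rmse = sqrt(sse / n),
      sse = sse,
      fitted = y - res,
      residuals = res,
      n = n,
      n_params = p,
      period = if (kind == "harmonic") period else NA_real_
    ),
    class = "ascept_fit"
  )
}

#' @export
print.ascept_fit <- function(x, ...) {
  cat("<ascept_fit>", x$kind)
  if (!x$feasible) {
    cat(" (infeasible)\n")
  } else {
    cat(sprintf(" rmse = %.4g n = %d", x$rmse, x$n))
    if (x$kind == "harmonic") cat(sprintf(" period = %.3f", x$period))
    cat("\n")
  }
  invisible(x)
}

# RMSE values at or below this (relative) tolerance count as exact fits for
# the 0/0 -> 1 and x/0 -> Inf ratio conventions.
rmse_is_zero <- function(rmse, scale) {
  is.finite(rmse) && rmse <= 1e-8 * max(1, scale)
}

# Best trend fit (linear or feasible harmonic, by SSE) to y at global
# indices t; period re-estimated on the given values.
best_trend_fit <- function(y, t) {
  fl <- fit_model(y, "linear", t = t)
  fh <- fit_model(y, "harmonic", period = estimate_period(y), t = t)
  if (fh$feasible && fh$sse < fl$sse) fh else fl
}

#' RMSE ratio of cross-segment to piecewise fits at one changepoint
#'
#' For the changepoint at `position`, fits the best of {linear, feasible
#' harmonic} separately to the segments on either side (piecewise) and to
#' the merged segment ignoring the changepoint (cross-segment; period
#' re-estimated on the merge). The piecewise RMSE pools residuals,
#' `sqrt((SSE_L + SSE_R) / (n_L + n_R))` — per-side SSE minimization also
#' minimizes this pooled value. Relevant changepoints give large ratios;
#' nuisance changepoints inside an ongoing trend give ratios near 1.
#'
#' Exact fits define RMSE 0, with the conventions 0/0 -> 1 and x/0 (x > 0)
#' -> `Inf`; an infinite ratio means the changepoint can never be trimmed,
#' which preserves sudden single-point shifts.
#'
#' @inheritParams gaussian_loglik
#' @param position a changepoint in `cps`.
#' @return A single nonnegative number (possibly `Inf`).
#' @export
changepoint_ratio <- function(series, cps, position) {
  s <- as_series(series)
  p <- validate_changepoints(cps, s$n)
  i <- match(position, p)
  if (is.na(i)) {
    stop("position ", position, " is not in the changepoint set")
  }
  lb <- if (i > 1L) p[i - 1L] + 1L else 1L
  rb <- if (i < length(p)) p[i + 1L] else s$n
  tl <- lb:position
  tr <- (position + 1L):rb
  tm <- lb:rb
  y <- s$values
  scale <- max(abs(y[tm]))

  fL <- best_trend_fit(y[tl], tl)
  fR <- best_trend_fit(y[tr], tr)
  piecewise <- sqrt((fL$sse + fR$sse) / (length(tl) + length(tr)))
  cross <- best_trend_fit(y[tm], tm)$rmse

  pz <- rmse_is_zero(piecewise, scale)
  cz <- rmse_is_zero(cross, scale)
  if (pz && cz) {
    1
  } else if (pz) {
    Inf
  } else {
    cross / piecewise
  }
}

#' Stage 2: trim nuisance changepoints inside linear or seasonal trends
#'
#' Iteratively computes the [changepoint_ratio()] of every changepoint in the
#' current set, removes the one with the smallest ratio if that ratio falls
#' below `threshold` (ties broken by the smallest position), and repeats
#' until no ratio is below the threshold. After a removal only the segments
#' adjacent to the merge change, so unaffected ratios are reused.
#'
#' @inheritParams changepoint_ratio
#' @param threshold trimming threshold; changepoints whose best cross-segment
#'   fit has RMSE within `threshold`-fold of the best piecewise fit are
#'   candidates for removal (default 1.2, i.e. within 20 percent).
#' @param recompute_all if `TRUE`, recompute every ratio from scratch each
#'   iteration instead of caching unaffected ones; results are identical.
#' @param verbose if `TRUE`, log one line per removal.
#' @return An object of class `ascept_trim`: list with `kept` (surviving
#'   positions) and `records`, a data frame audit trail with one row per
#'   evaluated changepoint per iteration (`iteration`, `position`, `ratio`,
#'   `removed`).
#' @export
trim <- function(series, cps, threshold = 1.2, recompute_all = FALSE,
                 verbose = FALSE) {
  s <- as_series(series)
  cur <- validate_changepoints(cps, s$n)
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a nonnegative number")
  }
  records <- list()
  iter <- 0L
  ratios <- vapply(cur, function(p) changepoint_ratio(s, cur, p), numeric(1L))

  while (length(cur) > 0L) {
    iter <- iter + 1L
    jmin <- which(ratios == min(ratios))[1L] # positions sorted: first = smallest
    hit <- ratios[jmin] < threshold
    records[[iter]] <- data.frame(
      iteration = iter,
      position = cur,
      ratio = ratios,
      removed = hit & seq_along(cur) == jmin
    )
    if (!hit) {
      break
    }
    if (verbose) {
      message(sprintf(
        "trim: removing %d (ratio %.3f)", cur[jmin], ratios[jmin]
      ))
    }
    removed_pos <- cur[jmin]
    cur <- cur[-jmin]
    ratios <- ratios[-jmin]
    if (length(cur) > 0L) {
      if (recompute_all) {
        ratios <- vapply(
          cur, function(p) changepoint_ratio(s, cur, p),
          numeric(1L)
        )
      } else {
        # only neighbors of the removed changepoint see a changed segment
        touch <- which(cur %in% c(
          cur[which(cur < removed_pos)[sum(cur < removed_pos)]],
          cur[which(cur > removed_pos)[1L]]
        ))
        for (j in touch) {
          ratios[j] <- changepoint_ratio(s, cur, cur[j])
        }
      }
    }
  }
  if (length(cur) == 0L && iter == 0L) {
    records <- list(data.frame(
      iteration = integer(0L), position = integer(0L),
      ratio = numeric(0L), removed = logical(0L)
    ))
  }
  structure(
    list(kept = cur, records = do.call(rbind, records)),
    class = "ascept_trim"
  )
}

#' @export
print.ascept_trim <- function(x, ...) {
  nrem <- sum(x$records$removed)
  cat(
    "<ascept_trim> kept", length(x$kept), "changepoints, removed",
    nrem, "\n"
  )
  invisible(x)
}
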