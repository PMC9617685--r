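#' Choose the best model for one segment
#'
#' Fits constant, linear, and (if a period is feasible) harmonic models and
#' declares the segment trended or seasonal only when the constant fit's RMSE
#' exceeds the best non-constant RMSE by more than `fitting_threshold`-fold;
#' otherwise the constant fit is kept. An exactly fitting non-constant model
#' on a non-constant segment counts as an infinite ratio.
#'
#' @inheritParams fit_model
#' @param fitting_threshold ratio threshold, greater than 1 (default 1.75).
#' @return The chosen `ascept_fit`.
#' @export
choose_segment_model <- function(values, fitting_threshold = 1.75,
                                 t = seq_along(values)) {
  y <- as.numeric(values)
  if (length(y) == 0L) {
    stop("choose_segment_model: empty segment")
  }
  if (!is.finite(fitting_threshold) || fitting_threshold <= 1) {
    stop("fitting_threshold must be > 1")
  }
  fc <- fit_model(y, "constant", t = t)
  fbest <- best_trend_fit(y, t)
  scale <- max(abs(y))
  cz <- rmse_is_zero(fc$rmse, scale)
  bz <- rmse_is_zero(fbest$rmse, scale)
  ratio <- if (cz && bz) 1 else if (bz) Inf else fc$rmse / fbest$rmse
  if (ratio > fitting_threshold) fbest else fc
}

#' Correct a series for its changepoints
#'
#' Per induced segment, chooses a model with [choose_segment_model()],
#' detrends or deseasonalizes (residuals plus the original segment mean; the
#' constant model leaves values untouched), then shifts and scales every
#' segment onto the reference segment: with location the segment's
#' pre-correction mean and scale the residual standard error
#' `sqrt(SSE / (n - p))` of its chosen model,
#' \deqn{z = (v - loc_s) / scale_s \times scale_{ref} + loc_{ref}.}
#' Segments whose scale is undefined (`n <= p`) or degenerate (below the
#' series sd floor) keep a scale factor of 1 with a warning.
#'
#' @inheritParams gaussian_loglik
#' @param reference_segment 1-based index of the reference segment among the
#'   `length(cps) + 1` induced segments.
#' @param fitting_threshold passed to [choose_segment_model()].
#' @return An object of class `ascept_correction`: list with `corrected`
#'   (an `ascept_series`), `per_segment` (data frame: bounds, model,
#'   location, scale, scale factor), `reference`.
#' @export
correct_series <- function(series, cps, reference_segment,
                           fitting_threshold = 1.75, sd_floor = NULL) {
  s <- as_series(series)
  b <- segment_bounds(cps, s$n)
  m <- nrow(b)
  if (!is.numeric(reference_segment) || length(reference_segment) != 1L ||
    reference_segment < 1L || reference_segment > m) {
    stop("reference_segment must index one of the ", m, " induced segments")
  }
  if (is.null(sd_floor)) {
    sd_floor <- sd_floor_for(s$values)
  }
  y <- s$values

  seg <- vector("list", m)
  for (i in seq_len(m)) {
    idx <- b[i, 1L]:b[i, 2L]
    fit <- choose_segment_model(y[idx], fitting_threshold, t = idx)
    loc <- mean(y[idx])
    dof <- fit$n - fit$n_params
    scl <- if (dof > 0L) sqrt(fit$sse / dof) else NA_real_
    v <- if (fit$kind == "constant") y[idx] else fit$residuals + loc
    seg[[i]] <- list(fit = fit, loc = loc, scale = scl, v = v, idx = idx)
  }

  ref <- seg[[reference_segment]]
  ref_degenerate <- is.na(ref$scale) || ref$scale < sd_floor
  if (ref_degenerate) {
    warning("reference segment has a degenerate scale; no rescaling applied")
  }

  z <- numeric(s$n)
  factors <- numeric(m)
  for (i in seq_len(m)) {
    si <- seg[[i]]
    degenerate <- is.na(si$scale) || si$scale < sd_floor || ref_degenerate
    if (degenerate && !ref_degenerate) {
      warning(
        "segment ", i, " has a degenerate scale; shift applied without rescaling"
      )
    }
    f <- if (degenerate) 1 else ref$scale / si$scale
    factors[i] <- f
    z[si$idx] <- (si$v - si$loc) * f + ref$loc
  }

  per_segment <- data.frame(
    segment = seq_len(m),
    start = b[, 1L],
    end = b[, 2L],
    model = vapply(seg, function(x) x$fit$kind, character(1L)),
    location = vapply(seg, function(x) x$loc, numeric(1L)),
    scale = vapply(seg, function(x) x$scale, numeric(1L)),
    scale_factor = factors
  )
  structure(
    list(
      corrected = as_series(z, labels = s$labels),
      per_segment = per_segment,
      reference = as.integer(reference_segment)
    ),
    class = "ascept_correction"
  )
}

#' @export
print.ascept_correction <- function(x, ...) {
  cat(
    "<ascept_correction>", nrow(x$per_segment), "segments, reference",
    x$reference, "\n"
  )
  print(x$per_segment)
  invisible(x)
}
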