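#' Construct a time-series object
#'
#' Light container for a univariate, regularly spaced series: a numeric value
#' vector plus optional calendar labels (one per observation). All analysis
#' functions in the package accept either a plain numeric vector or an
#' `ascept_series`.
#'
#' @param values numeric vector of observations; must be finite (the package
#'   requires a complete series — gap handling is the caller's job).
#' @param labels optional vector of calendar labels (e.g. `Date`), same length
#'   as `values`.
#' @return An object of class `ascept_series` with fields `values`, `labels`
#'   and `n`.
#' @examples
#' s <- as_series(rnorm(10))
#' s$n
#' @export
as_series <- function(values, labels = NULL) {
  if (inherits(values, "ascept_series")) {
    return(values)
  }
  v <- as.numeric(values)
  if (length(v) < 1L) {
    stop("a series needs at least one observation")
  }
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v))
    stop(
      "series values must be finite; offending indices: ",
      paste(utils::head(bad, 10L), collapse = ", ")
    )
  }
  if (!is.null(labels) && length(labels) != length(v)) {
    stop("labels must have the same length as values")
  }
  structure(
    list(values = v, labels = labels, n = length(v)),
    class = "ascept_series"
  )
}

#' @export
print.ascept_series <- function(x, ...) {
  cat("<ascept_series> n =", x$n)
  if (!is.null(x$labels)) {
    cat(
      ", labels", format(x$labels[1L]), "..",
      format(x$labels[x$n])
    )
  }
  cat("\n")
  invisible(x)
}

#' @export
length.ascept_series <- function(x) x$n

# Validate a changepoint set against a series length. A changepoint at
# position j (1-based) means the distribution changes between observations j
# and j+1, so valid positions live in [1, n-1]. Returns a sorted integer
# vector.
validate_changepoints <- function(cps, n) {
  if (length(cps) == 0L) {
    return(integer(0L))
  }
  p <- as.integer(round(cps))
  if (any(p != cps)) {
    stop("changepoint positions must be integers")
  }
  if (any(p < 1L) || any(p > n - 1L)) {
    stop("changepoint positions must lie in [1, n-1]")
  }
  p <- sort(p)
  if (anyDuplicated(p)) {
    stop("changepoint positions must be distinct")
  }
  p
}

# Segment bounds induced by a changepoint set: a set of size m splits 1..n
# into m+1 contiguous segments. Returns a two-column matrix (start, end),
# 1-based inclusive.
segment_bounds <- function(cps, n) {
  p <- validate_changepoints(cps, n)
  starts <- c(1L, p + 1L)
  ends <- c(p, n)
  cbind(start = starts, end = ends)
}

# Series-level standard-deviation floor: keeps length-1 and constant
# segments at a finite cost and a samplable null. Scales with the overall
# spread so a rescaled series behaves identically. Deliberately far below
# any plausible noise scale: the floor is a degeneracy guard, and its size
# also sets the likelihood bonus a length-1 segment earns, which in turn
# makes the first white-noise candidate a boundary singleton whose
# Monte-Carlo null is honest (see the methods vignette).
sd_floor_for <- function(values) {
  s <- if (length(values) >= 2L) stats::sd(values) else 0
  if (!is.finite(s)) s <- 0
  max(1e-8, 1e-4 * s)
}
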