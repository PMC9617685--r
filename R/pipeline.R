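#' Parameter set for an ASCEPT run
#'
#' Bundles and validates all tunable parameters of the pipeline. Defaults
#' follow the method's reference settings: significance level 0.01 with
#' 10000 Monte-Carlo simulations for stage 1, trimming threshold 1.2 for
#' stage 2, fitting threshold 1.75 for segment correction. The penalty range
#' defaults (resolved against the series length n at run time) are
#' `[0.05 log n, 50 log n]` — wide enough that the sweep's top entry is the
#' empty set and its bottom is near saturation.
#'
#' @param alpha stage-1 significance level, in (0, 1).
#' @param n_sim number of Monte-Carlo simulations N per stage-1 test.
#' @param trim_threshold stage-2 trimming threshold (>= 1 recommended).
#' @param fitting_threshold correction fitting threshold (> 1).
#' @param beta_min,beta_max penalty sweep range; `NULL` means the defaults
#'   above.
#' @param min_seg_len minimum segment length for detection.
#' @param seed integer root seed for the Monte-Carlo draws.
#' @param reference_segment reference segment index for correction
#'   (required when `correct = TRUE`).
#' @param correct run segment correction after trimming?
#' @return An object of class `ascept_params` (a validated list).
#' @export
ascept_params <- function(alpha = 0.01, n_sim = 10000L, trim_threshold = 1.2,
                          fitting_threshold = 1.75, beta_min = NULL,
                          beta_max = NULL, min_seg_len = 1L, seed = NULL,
                          reference_segment = NULL, correct = FALSE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (n_sim < 1L) {
    stop("n_sim must be >= 1")
  }
  if (!is.finite(trim_threshold) || trim_threshold < 1) {
    stop("trim_threshold must be >= 1")
  }
  if (!is.finite(fitting_threshold) || fitting_threshold <= 1) {
    stop("fitting_threshold must be > 1")
  }
  if (!is.null(beta_min) && !is.null(beta_max) &&
    (beta_min <= 0 || beta_min > beta_max)) {
    stop("need 0 < beta_min <= beta_max")
  }
  if (min_seg_len < 1L) {
    stop("min_seg_len must be >= 1")
  }
  if (isTRUE(correct) && is.null(reference_segment)) {
    stop("correct = TRUE requires a reference_segment")
  }
  structure(
    list(
      alpha = alpha, n_sim = as.integer(n_sim),
      trim_threshold = trim_threshold,
      fitting_threshold = fitting_threshold,
      beta_min = beta_min, beta_max = beta_max,
      min_seg_len = as.integer(min_seg_len),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      reference_segment = reference_segment,
      correct = isTRUE(correct)
    ),
    class = "ascept_params"
  )
}

#' Run the full ASCEPT pipeline
#'
#' Penalty sweep, candidate path, stage-1 fixed-sequence Monte-Carlo
#' selection, stage-2 trimming, and (optionally) segment correction, with one
#' log line per stage-1 test and per trim removal when `verbose = TRUE`.
#' Deterministic given `params$seed`.
#'
#' @inheritParams gaussian_loglik
#' @param params an [ascept_params()] object.
#' @param verbose log progress lines (default `TRUE`).
#' @return An object of class `ascept_report`: list with `n`, `labels_range`,
#'   `path_summary`, `stage1`, `trim`, `correction` (or `NULL`),
#'   `changepoints` (the final kept set), `changepoint_labels` (when the
#'   series carried labels), `params`, `version`.
#' @export
run_ascept <- function(series, params = ascept_params(), verbose = TRUE) {
  stopifnot(inherits(params, "ascept_params"))
  s <- as_series(series)
  bmin <- if (is.null(params$beta_min)) 0.05 * log(s$n) else params$beta_min
  bmax <- if (is.null(params$beta_max)) 50 * log(s$n) else params$beta_max
  sd_floor <- sd_floor_for(s$values)

  raw <- crops_sweep(s, bmin, bmax,
    min_seg_len = params$min_seg_len, sd_floor = sd_floor
  )
  path <- build_candidate_path(raw, s, sd_floor = sd_floor)
  if (verbose) {
    message(
      "sweep: ", path$K + 1L, " candidate sets over penalties [",
      signif(bmin, 4), ", ", signif(bmax, 4), "]"
    )
  }
  st1 <- select_stage1(s, path,
    alpha = params$alpha, n_sim = params$n_sim,
    seed = params$seed, sd_floor = sd_floor, verbose = verbose
  )
  tr <- trim(s, st1$selected,
    threshold = params$trim_threshold,
    verbose = verbose
  )
  corr <- NULL
  if (params$correct) {
    corr <- correct_series(s, tr$kept, params$reference_segment,
      fitting_threshold = params$fitting_threshold, sd_floor = sd_floor
    )
  }

  final <- tr$kept
  structure(
    list(
      n = s$n,
      labels_range = if (is.null(s$labels)) {
        NULL
      } else {
        c(format(s$labels[1L]), format(s$labels[s$n]))
      },
      path_summary = list(
        K = path$K,
        beta_min = bmin,
        beta_max = bmax,
        set_sizes = vapply(
          path$entries, function(e) length(e$positions), integer(1L)
        )
      ),
      stage1 = st1,
      trim = tr,
      correction = corr,
      changepoints = final,
      changepoint_labels = if (is.null(s$labels) || length(final) == 0L) {
        NULL
      } else {
        format(s$labels[final])
      },
      params = params,
      version = as.character(utils::packageVersion("ascept"))
    ),
    class = "ascept_report"
  )
}

#' @export
print.ascept_report <- function(x, ...) {
  cat("ASCEPT report (n =", x$n, ")\n")
  cat(
    "  candidate path: K =", x$path_summary$K, " penalties [",
    signif(x$path_summary$beta_min, 4), ",",
    signif(x$path_summary$beta_max, 4), "]\n"
  )
  cat(
    "  stage 1: selected T", x$stage1$selected_k, " with ",
    length(x$stage1$selected), " changepoints (",
    length(x$stage1$tests), " tests, alpha = ", x$stage1$alpha, ")\n",
    sep = ""
  )
  cat(
    "  stage 2: trimmed", sum(x$trim$records$removed), "->",
    length(x$changepoints), "changepoints kept\n"
  )
  if (length(x$changepoints)) {
    cat("  final changepoints:", paste(x$changepoints, collapse = ", "), "\n")
    if (!is.null(x$changepoint_labels)) {
      cat("  dates:", paste(x$changepoint_labels, collapse = ", "), "\n")
    }
  } else {
    cat("  final changepoints: none\n")
  }
  if (!is.null(x$correction)) {
    cat(
      "  correction: reference segment", x$correction$reference, "of",
      nrow(x$correction$per_segment), "\n"
    )
  }
  invisible(x)
}
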