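#' Read a series from a CSV file
#'
#' Reads a regular, complete univariate series from an RFC-4180 CSV. The
#' value column may be named (header present) or given by position (numeric
#' `value_column`, read without a header — the single-column headerless
#' dialect). Missing values are an error naming the offending rows, not
#' silently imputed: the analysis requires a complete series and gap handling
#' is the caller's job. Dates, when supplied, must be ISO-8601, strictly
#' increasing, and without duplicates.
#'
#' @param path path to the CSV file.
#' @param value_column column name (character) or 1-based position (numeric).
#' @param date_column optional column name or position holding ISO-8601
#'   dates.
#' @return An `ascept_series`, with `Date` labels when `date_column` was
#'   given.
#' @export
read_series_csv <- function(path, value_column = "value",
                            date_column = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  header <- is.character(value_column)
  df <- utils::read.csv(path,
    header = header, stringsAsFactors = FALSE,
    colClasses = "character", blank.lines.skip = FALSE
  )
  pick <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(df)) {
        stop("no column named '", col, "' for the ", what)
      }
      df[[col]]
    } else {
      col <- as.integer(col)
      if (col < 1L || col > ncol(df)) {
        stop(what, " column position ", col, " out of range")
      }
      df[[col]]
    }
  }
  raw <- pick(value_column, "value")
  vals <- suppressWarnings(as.numeric(raw))
  missing <- is.na(vals) | !nzchar(trimws(raw))
  if (any(missing)) {
    stop(
      "missing or non-numeric values in rows: ",
      paste(utils::head(which(missing), 20L), collapse = ", "),
      " — the series must be complete"
    )
  }
  labels <- NULL
  if (!is.null(date_column)) {
    d <- as.Date(pick(date_column, "date"), format = "%Y-%m-%d")
    if (any(is.na(d))) {
      stop(
        "unparseable dates (expect ISO-8601) in rows: ",
        paste(utils::head(which(is.na(d)), 20L), collapse = ", ")
      )
    }
    if (anyDuplicated(d)) {
      stop("duplicated dates in the date column")
    }
    if (is.unsorted(d, strictly = TRUE)) {
      stop("dates must be strictly increasing")
    }
    labels <- d
  }
  as_series(vals, labels = labels)
}

#' Write an ASCEPT report (and corrected series) to a directory
#'
#' Writes `ascept_report.json` — final changepoints with indices (and dates,
#' when available), the per-test stage-1 p-values and deltas, the trim audit
#' trail, the parameter echo and seed — and, when correction ran,
#' `corrected_series.csv` whose values are printed with 17 significant
#' digits so that re-reading round-trips exactly.
#'
#' @param report an `ascept_report` from [run_ascept()].
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the paths of the files written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "ascept_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      stop("cannot create output directory: ", out_dir)
    }
  }
  json_path <- file.path(out_dir, "ascept_report.json")
  obj <- list(
    version = report$version,
    n = report$n,
    labels_range = report$labels_range,
    params = report$params[!vapply(report$params, is.null, logical(1L))],
    path = list(
      K = report$path_summary$K,
      beta_min = report$path_summary$beta_min,
      beta_max = report$path_summary$beta_max,
      set_sizes = report$path_summary$set_sizes
    ),
    stage1 = list(
      selected_k = report$stage1$selected_k,
      alpha = report$stage1$alpha,
      exhausted = report$stage1$exhausted,
      tests = lapply(report$stage1$tests, function(m) {
        list(
          k = m$k, observed_delta = m$observed_delta,
          p_value = m$p_value, n_sim = m$n_sim
        )
      }),
      selected = report$stage1$selected
    ),
    trim = list(
      kept = report$trim$kept,
      records = report$trim$records
    ),
    changepoints = report$changepoints,
    changepoint_labels = report$changepoint_labels
  )
  if (!is.null(report$correction)) {
    obj$correction <- list(
      reference = report$correction$reference,
      per_segment = report$correction$per_segment
    )
  }
  jsonlite::write_json(obj, json_path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null"
  )
  paths <- json_path

  if (!is.null(report$correction)) {
    csv_path <- file.path(out_dir, "corrected_series.csv")
    corr <- report$correction$corrected
    lines <- if (is.null(corr$labels)) {
      c("value", sprintf("%.17g", corr$values))
    } else {
      c(
        "date,value",
        paste(format(corr$labels), sprintf("%.17g", corr$values), sep = ",")
      )
    }
    writeLines(lines, csv_path)
    paths <- c(paths, csv_path)
  }
  invisible(paths)
}
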