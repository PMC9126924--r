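#' Multi-series container
#'
#' A light container for a named collection of equal-length real-valued
#' time series from one simulation: a numeric matrix with one row per time
#' index and one named column per series, plus the sampling interval.
#'
#' @param values Numeric matrix, one column per series, with column names.
#' @param dt Sampling interval between consecutive rows (1 for maps).
#'
#' @return An object of class `multi_series`.
#' @export
multi_series <- function(values, dt = 1) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyNA(colnames(values))) {
    stopf("multi_series values must have column names")
  }
  if (nrow(values) < 2) stopf("multi_series needs at least 2 time points")
  if (anyNA(values) || any(!is.finite(values))) {
    stopf("multi_series values must be finite with no missing entries")
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stopf("dt must be a single positive number")
  }
  structure(values, dt = dt, class = c("multi_series", "matrix", "array"))
}

#' @export
print.multi_series <- function(x, ...) {
  cat(sprintf("<multi_series> %d time points x %d series (dt = %g)\n",
              nrow(x), ncol(x), attr(x, "dt")))
  cat("series:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.multi_series <- function(x, ...) {
  df <- as.data.frame(unclass(x), ...)
  df$time <- (seq_len(nrow(x)) - 1) * attr(x, "dt")
  df[c("time", colnames(x))]
}

#' Write a multi-series object to CSV
#'
#' One header row of series names, one row per time index. The sampling
#' interval is carried in a `time` column.
#'
#' @param ms A `multi_series` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multiseries <- function(ms, path) {
  stopifnot(inherits(ms, "multi_series"))
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-series object from CSV
#'
#' @param path CSV file written by [write_multiseries()] (or any CSV with
#'   numeric columns; an optional `time` column sets the sampling interval).
#' @return A `multi_series` object.
#' @export
read_multiseries <- function(path) {
  df <- utils::read.csv(path)
  dt <- 1
  if ("time" %in% names(df)) {
    tm <- df$time
    df$time <- NULL
    if (length(tm) > 1) dt <- tm[2] - tm[1]
  }
  multi_series(as.matrix(df), dt = dt)
}
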