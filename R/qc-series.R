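#' Relative standard deviation in percent
#'
#' Sample standard deviation over the mean, times 100. The stability
#' criterion used throughout this package: a QC series with RSD below 10%
#' is treated as stable.
#'
#' @param values Numeric vector, at least two finite values.
#' @return RSD in percent; `NA` with a warning when the mean is zero.
#' @examples
#' rsd_percent(c(1, 2, 3)) # 50
#' @export
rsd_percent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("rsd_percent needs at least two finite values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) {
    warning("Mean is zero; RSD undefined")
    return(NA_real_)
  }
  stats::sd(values) / m * 100
}

#' MinMax scaling to a fixed range
#'
#' Affine map sending the minimum to `lo` and the maximum to `hi` (default
#' \[-2, 2\], the range used before kinetics clustering so that series are
#' compared by shape, not amplitude). A constant series maps to the midpoint
#' everywhere.
#'
#' @param values Numeric vector of at least two values.
#' @param lo,hi Target range ends.
#' @return Scaled numeric vector.
#' @examples
#' minmax_scale(c(0, 5, 10)) # -2 0 2
#' @export
minmax_scale <- function(values, lo = -2, hi = 2) {
  stopifnot(length(values) >= 2, hi > lo)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    return(rep((lo + hi) / 2, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}

#' Extract per-feature QC time series
#'
#' Pulls each feature's peak areas in the QC runs, ordered by injection
#' time, and MinMax-scales them to \[-2, 2\]. Features with missing QC
#' values are dropped with a warning (the kinetics fit needs the full QC
#' grid).
#'
#' @param features Wide feature tibble.
#' @param schedule Schedule tibble.
#' @return A list of class `qc_series_set`: `times` (QC clock times,
#'   minutes), `values` (features x QC matrix of raw areas, rownames =
#'   feature ids), `scaled` (same, MinMax-scaled per feature).
#' @export
qc_series <- function(features, schedule) {
  schedule <- validate_schedule(schedule)
  qc <- schedule[schedule$class == "qc", ]
  if (nrow(qc) < 2) {
    stop("At least two QC runs are required", call. = FALSE)
  }
  qc <- qc[order(qc$time_min), ]
  vals <- as.matrix(features[, qc$run_id, drop = FALSE])
  rownames(vals) <- features$feature_id
  ok <- stats::complete.cases(vals)
  if (!all(ok)) {
    warning(sum(!ok), " feature(s) dropped: missing QC values")
    vals <- vals[ok, , drop = FALSE]
  }
  scaled <- t(apply(vals, 1, minmax_scale))
  structure(
    list(times = qc$time_min, values = vals, scaled = scaled),
    class = "qc_series_set"
  )
}

#' @export
print.qc_series_set <- function(x, ...) {
  cat(
    "<qc_series_set>", nrow(x$values), "features x", length(x$times),
    "QC injections at", paste(x$times, collapse = ", "), "min\n"
  )
  invisible(x)
}
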