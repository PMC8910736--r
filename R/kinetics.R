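.fit_linear <- function(t, y) {
  fit <- stats::lm(y ~ t)
  list(
    model = "linear",
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    breakpoint = NA_real_,
    slope_late = NA_real_,
    fitted = unname(stats::fitted(fit)),
    rss = sum(stats::resid(fit)^2),
    n_par = 2L
  )
}

# Continuous two-segment (hinge) linear model; the breakpoint is searched
# over the interior observation times.
.fit_piecewise <- function(t, y) {
  taus <- sort(unique(t))
  taus <- taus[taus > min(t) & taus < max(t)]
  if (length(taus) == 0) {
    return(NULL)
  }
  fits <- lapply(taus, function(tau) {
    hinge <- pmax(t - tau, 0)
    fit <- stats::lm(y ~ t + hinge)
    list(tau = tau, fit = fit, rss = sum(stats::resid(fit)^2))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  cf <- stats::coef(best$fit)
  cf[is.na(cf)] <- 0
  list(
    model = "piecewise",
    intercept = unname(cf[1]),
    slope = unname(cf[2]),
    breakpoint = best$tau,
    slope_late = unname(cf[2] + cf[3]),
    fitted = unname(stats::fitted(best$fit)),
    rss = best$rss,
    n_par = 4L
  )
}

.bic <- function(rss, n, n_par) {
  n * log(pmax(rss, 1e-300) / n) + n_par * log(n)
}

#' Classify the degradation kinetics of one intensity-vs-time series
#'
#' Fits a linear and a continuous two-segment piecewise-linear model
#' (breakpoint searched over interior time points) and assigns one of four
#' kinetics types: `"I"` (linear increase), `"II"` (linear decrease),
#' `"III"` (piecewise: slow change then a steeper late segment) or
#' `"steady"` (no essential change; correction factor of 1 downstream).
#' The piecewise model is preferred only when it improves the BIC over the
#' linear one and the late slope is at least `slope_ratio` times steeper
#' than the early slope. A series is steady when the RSD of its fitted
#' values is below `steady_rsd` percent (the stability criterion; requires
#' a positive-mean series, i.e. raw peak areas).
#'
#' @param times Observation times (minutes), strictly increasing.
#' @param values Intensities at those times.
#' @param steady_rsd Steady threshold: fitted-range RSD in percent.
#' @param slope_ratio Required late/early slope magnitude ratio for the
#'   piecewise call.
#' @return A list of class `kinetics_class`: `kinetics_type`, `model`,
#'   `intercept`, `slope`, `breakpoint`, `slope_late`, `r_squared`,
#'   `rsd_fitted`.
#' @export
classify_kinetics <- function(times, values, steady_rsd = 10, slope_ratio = 2) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  n <- length(values)
  lin <- .fit_linear(times, values)
  choice <- lin
  if (n >= 4) {
    pw <- .fit_piecewise(times, values)
    if (!is.null(pw) &&
      .bic(pw$rss, n, pw$n_par) < .bic(lin$rss, n, lin$n_par) &&
      abs(pw$slope_late) >= slope_ratio * abs(pw$slope)) {
      choice <- pw
    }
  }
  tss <- sum((values - mean(values))^2)
  r2 <- if (tss > 0) 1 - choice$rss / tss else 0
  mean_fit <- mean(choice$fitted)
  rsd_fit <- if (mean_fit > 0) stats::sd(choice$fitted) / mean_fit * 100 else NA_real_
  type <- if (!is.na(rsd_fit) && rsd_fit < steady_rsd) {
    "steady"
  } else if (choice$model == "piecewise") {
    "III"
  } else if (choice$slope > 0) {
    "I"
  } else {
    "II"
  }
  structure(
    list(
      kinetics_type = type,
      model = choice$model,
      intercept = choice$intercept,
      slope = choice$slope,
      breakpoint = choice$breakpoint,
      slope_late = choice$slope_late,
      r_squared = r2,
      rsd_fitted = rsd_fit
    ),
    class = "kinetics_class"
  )
}

#' Fit per-analyte degradation-kinetics models
#'
#' Combines the cluster structure of the QC series with per-analyte
#' regression: the cluster of each feature (from [cluster_qc_series()] on
#' the scaled series) fixes the model family -- linear versus piecewise,
#' read off the cluster centroid -- while the model parameters are fit on
#' the feature's own raw QC intensities. A feature whose fitted values have
#' an RSD below `steady_rsd` percent is labelled steady regardless of
#' family.
#'
#' @param features Wide feature tibble.
#' @param schedule Schedule tibble.
#' @param clusters Optional `qc_clusters` object; computed with the given
#'   `k`, `metric`, `seed`, `n_init` when absent.
#' @param k,metric,seed,n_init Passed to [cluster_qc_series()].
#' @param steady_rsd Steady threshold (fitted-range RSD, percent).
#' @param slope_ratio Late/early slope ratio for the piecewise call.
#' @return A tibble of class `kinetics_fits`, one row per feature:
#'   `feature_id`, `cluster`, `kinetics_type`, `model`, `intercept`,
#'   `slope`, `breakpoint`, `slope_late`, `r_squared`, `rsd_percent` (raw
#'   QC series RSD), `rsd_fitted`. QC times are carried in attribute
#'   `"qc_times"`.
#' @export
fit_kinetics <- function(features, schedule, clusters = NULL, k = 5,
                         metric = c("euclidean", "dtw", "dba"), seed = 1L,
                         n_init = 10, steady_rsd = 10, slope_ratio = 2) {
  metric <- match.arg(metric)
  qc <- qc_series(features, schedule)
  if (is.null(clusters)) {
    clusters <- cluster_qc_series(qc,
      k = min(k, nrow(qc$values)),
      metric = metric, seed = seed, n_init = n_init
    )
  }
  # model family per cluster, read off the (scaled) centroid shape
  family <- vapply(seq_len(nrow(clusters$centroids)), function(j) {
    cl <- classify_kinetics(qc$times, clusters$centroids[j, ],
      steady_rsd = steady_rsd, slope_ratio = slope_ratio
    )
    cl$model
  }, character(1))

  rows <- purrr::map(seq_len(nrow(qc$values)), function(i) {
    y <- qc$values[i, ]
    lab <- unname(clusters$cluster[i])
    fam <- family[lab]
    lin <- .fit_linear(qc$times, y)
    choice <- lin
    if (fam == "piecewise" && length(y) >= 4) {
      pw <- .fit_piecewise(qc$times, y)
      if (!is.null(pw)) choice <- pw
    }
    tss <- sum((y - mean(y))^2)
    mean_fit <- mean(choice$fitted)
    rsd_fit <- if (mean_fit > 0) stats::sd(choice$fitted) / mean_fit * 100 else NA_real_
    type <- if (!is.na(rsd_fit) && rsd_fit < steady_rsd) {
      "steady"
    } else if (choice$model == "piecewise") {
      "III"
    } else if (choice$slope > 0) {
      "I"
    } else {
      "II"
    }
    tibble::tibble(
      feature_id = rownames(qc$values)[i],
      cluster = lab,
      kinetics_type = type,
      model = choice$model,
      intercept = choice$intercept,
      slope = choice$slope,
      breakpoint = choice$breakpoint,
      slope_late = choice$slope_late,
      r_squared = if (tss > 0) 1 - choice$rss / tss else 0,
      rsd_percent = rsd_percent(y),
      rsd_fitted = rsd_fit
    )
  }) |> purrr::list_rbind()
  attr(rows, "qc_times") <- qc$times
  class(rows) <- c("kinetics_fits", class(rows))
  rows
}

# Predicted QC intensity of a fitted kinetics model at arbitrary times.
.predict_kinetics <- function(fit_row, times) {
  if (fit_row$model == "piecewise" && !is.na(fit_row$breakpoint)) {
    tau <- fit_row$breakpoint
    early <- fit_row$intercept + fit_row$slope * pmin(times, tau)
    late <- pmax(times - tau, 0) * fit_row$slope_late
    early + late
  } else {
    fit_row$intercept + fit_row$slope * times
  }
}
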