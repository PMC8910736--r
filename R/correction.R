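#' Time-indexed correction factors from fitted kinetics
#'
#' For each analyte with a non-steady kinetics fit, the correction factor of
#' a run injected at time t is `f(t_ref) / f(t)`, where `f` is the fitted
#' QC intensity curve on the raw scale. Multiplying a peak area by its
#' factor removes the modelled contribution of derivative degradation and
#' solvent evaporation, referencing every run to the state at `t_ref`
#' (default: the first QC injection, the closest observation to the true
#' abundance for degrading derivatives). Steady analytes get factors of 1.
#' Factors are clamped to `clamp` with a warning; an analyte whose fitted
#' curve is non-positive at any run time is flagged uncorrectable and left
#' unchanged (all factors 1) with a warning.
#'
#' @param fits A `kinetics_fits` tibble from [fit_kinetics()].
#' @param schedule Schedule tibble (factors are produced for every run).
#' @param t_ref Reference time in minutes; default first QC time.
#' @param clamp Length-2 numeric, allowed factor range.
#' @return A tibble of class `correction_factors`: `feature_id`, `run_id`,
#'   `time_min`, `factor`, `clamped`, `uncorrectable`; `t_ref` is stored as
#'   an attribute.
#' @export
correction_factors <- function(fits, schedule, t_ref = NULL, clamp = c(0.2, 5)) {
  schedule <- validate_schedule(schedule)
  stopifnot(length(clamp) == 2, clamp[1] > 0, clamp[2] > clamp[1])
  if (is.null(t_ref)) {
    qc_times <- schedule$time_min[schedule$class == "qc"]
    t_ref <- if (length(qc_times) > 0) min(qc_times) else min(schedule$time_min)
  }
  out <- purrr::map(seq_len(nrow(fits)), function(i) {
    row <- fits[i, ]
    base <- tibble::tibble(
      feature_id = row$feature_id,
      run_id = schedule$run_id,
      time_min = schedule$time_min
    )
    if (row$kinetics_type == "steady") {
      return(dplyr::mutate(base, factor = 1, clamped = FALSE, uncorrectable = FALSE))
    }
    pred <- .predict_kinetics(row, schedule$time_min)
    pred_ref <- .predict_kinetics(row, t_ref)
    if (any(pred <= 0) || pred_ref <= 0) {
      warning(
        "Fitted kinetics of ", row$feature_id,
        " is non-positive within the batch window; left uncorrected"
      )
      return(dplyr::mutate(base, factor = 1, clamped = FALSE, uncorrectable = TRUE))
    }
    f <- pred_ref / pred
    clamped <- f < clamp[1] | f > clamp[2]
    if (any(clamped)) {
      warning(
        "Correction factors of ", row$feature_id, " clamped to [",
        clamp[1], ", ", clamp[2], "] for ", sum(clamped), " run(s)"
      )
    }
    dplyr::mutate(base,
      factor = pmin(pmax(f, clamp[1]), clamp[2]),
      clamped = clamped, uncorrectable = FALSE
    )
  }) |> purrr::list_rbind()
  attr(out, "t_ref") <- t_ref
  class(out) <- c("correction_factors", class(out))
  out
}

#' Apply correction factors to a feature table
#'
#' Corrected intensity = raw intensity x factor; missing intensities stay
#' missing. A (feature, run) pair without a factor is an error naming the
#' pair.
#'
#' @param features Wide feature tibble.
#' @param factors A `correction_factors` tibble.
#' @return The corrected wide feature tibble (same shape as `features`).
#' @export
apply_correction <- function(features, factors) {
  run_cols <- setdiff(
    names(features),
    c(.meta_cols, "calc_mz", "error_ppm", "rcc_formula")
  )
  needed <- tidyr::expand_grid(
    feature_id = features$feature_id,
    run_id = run_cols
  )
  have <- dplyr::semi_join(needed, factors, by = c("feature_id", "run_id"))
  if (nrow(have) < nrow(needed)) {
    miss <- dplyr::anti_join(needed, factors, by = c("feature_id", "run_id"))
    stop(
      "No correction factor for ", nrow(miss), " (feature, run) pair(s), e.g. ",
      miss$feature_id[1], " / ", miss$run_id[1],
      call. = FALSE
    )
  }
  fmat <- factors |>
    dplyr::filter(.data$run_id %in% run_cols) |>
    tidyr::pivot_wider(
      id_cols = "feature_id", names_from = "run_id", values_from = "factor"
    )
  fmat <- fmat[match(features$feature_id, fmat$feature_id), ]
  out <- features
  for (rc in run_cols) {
    out[[rc]] <- features[[rc]] * fmat[[rc]]
  }
  out
}

#' Full QC-based stability correction of a feature table
#'
#' One-call orchestration of the correction stage: extract and scale the QC
#' series, cluster them by kinetics shape, fit per-analyte kinetics models,
#' derive time-indexed correction factors and apply them to every run.
#'
#' @param features Wide feature tibble (after intensity filtering).
#' @param schedule Schedule tibble.
#' @param k Number of kinetics clusters (default 5).
#' @param metric Clustering metric, see [cluster_qc_series()].
#' @param seed,n_init k-means restart control.
#' @param steady_rsd Steady threshold (fitted-range RSD, percent).
#' @param clamp Correction-factor clamp range.
#' @param t_ref Reference time; default first QC injection.
#' @return A list of class `rcc_correction`: `corrected` (feature tibble),
#'   `fits` (`kinetics_fits`), `factors` (`correction_factors`), `clusters`
#'   (`qc_clusters`), `qc` (`qc_series_set`), and `params`.
#' @export
correct_features <- function(features, schedule, k = 5,
                             metric = c("euclidean", "dtw", "dba"),
                             seed = 1L, n_init = 10, steady_rsd = 10,
                             clamp = c(0.2, 5), t_ref = NULL) {
  metric <- match.arg(metric)
  schedule <- validate_schedule(schedule)
  qc <- qc_series(features, schedule)
  clusters <- cluster_qc_series(qc,
    k = min(k, nrow(qc$values)),
    metric = metric, seed = seed, n_init = n_init
  )
  kept <- features[features$feature_id %in% rownames(qc$values), , drop = FALSE]
  fits <- fit_kinetics(kept, schedule,
    clusters = clusters, steady_rsd = steady_rsd
  )
  factors <- correction_factors(fits, schedule, t_ref = t_ref, clamp = clamp)
  corrected <- apply_correction(kept, factors)

  qc_runs <- schedule$run_id[schedule$class == "qc"]
  rsd_after <- vapply(seq_len(nrow(corrected)), function(i) {
    rsd_percent(as.numeric(corrected[i, qc_runs, drop = TRUE]))
  }, numeric(1))
  fits$rsd_corrected <- rsd_after

  structure(
    list(
      corrected = corrected,
      fits = fits,
      factors = factors,
      clusters = clusters,
      qc = qc,
      params = list(
        k = k, metric = metric, seed = seed, n_init = n_init,
        steady_rsd = steady_rsd, clamp = clamp,
        t_ref = attr(factors, "t_ref")
      )
    ),
    class = "rcc_correction"
  )
}

#' @export
print.rcc_correction <- function(x, ...) {
  cat(
    "<rcc_correction>", nrow(x$fits), "features |", x$params$k, "clusters (",
    x$params$metric, ") | kinetics:",
    paste(names(table(x$fits$kinetics_type)),
      table(x$fits$kinetics_type),
      sep = ":", collapse = ", "
    ),
    "\n  median QC RSD raw ->",.fmt_pct(stats::median(x$fits$rsd_percent)),
    "corrected ->", .fmt_pct(stats::median(x$fits$rsd_corrected)), "\n"
  )
  invisible(x)
}

.fmt_pct <- function(x) paste0(format(x, digits = 3), "%")

#' Write the correction report as TSV
#'
#' One row per feature: cluster, kinetics type, model parameters, RSD before
#' and after self-correction, plus (wide) the per-run correction factors.
#'
#' @param correction An `rcc_correction` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correction_report <- function(correction, path) {
  wide_factors <- correction$factors |>
    tidyr::pivot_wider(
      id_cols = "feature_id", names_from = "run_id",
      values_from = "factor", names_prefix = "factor_"
    )
  report <- dplyr::left_join(correction$fits, wide_factors, by = "feature_id")
  readr::write_tsv(report, path)
  invisible(path)
}
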