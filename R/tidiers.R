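#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stability-correction result
#'
#' @param x An `rcc_correction` object.
#' @param ... Unused.
#' @return The per-feature kinetics-fit tibble (cluster, kinetics type,
#'   model parameters, QC RSD before and after self-correction).
#' @exportS3Method generics::tidy
tidy.rcc_correction <- function(x, ...) {
  tibble::as_tibble(x$fits)
}

#' One-row summary of a stability-correction result
#'
#' @param x An `rcc_correction` object.
#' @param ... Unused.
#' @return A one-row tibble: feature and cluster counts, kinetics-type
#'   counts, median QC RSD before/after, clamped and uncorrectable counts.
#' @exportS3Method generics::glance
glance.rcc_correction <- function(x, ...) {
  tab <- table(factor(x$fits$kinetics_type, levels = c("I", "II", "III", "steady")))
  tibble::tibble(
    n_features = nrow(x$fits),
    k = x$params$k,
    metric = x$params$metric,
    n_type_I = unname(tab["I"]),
    n_type_II = unname(tab["II"]),
    n_type_III = unname(tab["III"]),
    n_steady = unname(tab["steady"]),
    median_rsd_raw = stats::median(x$fits$rsd_percent),
    median_rsd_corrected = stats::median(x$fits$rsd_corrected),
    n_clamped = length(unique(x$factors$feature_id[x$factors$clamped])),
    n_uncorrectable = length(unique(x$factors$feature_id[x$factors$uncorrectable]))
  )
}

#' Tidy a QC-series clustering
#'
#' @param x A `qc_clusters` object.
#' @param ... Unused.
#' @return A tibble with `feature_id` and `cluster`.
#' @exportS3Method generics::tidy
tidy.qc_clusters <- function(x, ...) {
  tibble::tibble(
    feature_id = names(x$cluster) %||% as.character(seq_along(x$cluster)),
    cluster = unname(x$cluster)
  )
}

#' One-row summary of a QC-series clustering
#'
#' @param x A `qc_clusters` object.
#' @param ... Unused.
#' @return A one-row tibble: number of clusters, metric, within-cluster
#'   objective, smallest and largest cluster size.
#' @exportS3Method generics::glance
glance.qc_clusters <- function(x, ...) {
  tibble::tibble(
    k = length(x$sizes),
    metric = x$metric,
    objective = x$objective,
    min_size = min(x$sizes),
    max_size = max(x$sizes)
  )
}

#' Tidy a differential-abundance result
#'
#' @param x A `differential_results` tibble.
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @exportS3Method generics::tidy
tidy.differential_results <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "differential_results")
  tibble::as_tibble(out)
}

#' One-row summary of a differential-abundance result
#'
#' @param x A `differential_results` tibble.
#' @param ... Unused.
#' @return A one-row tibble: features tested, number significant, up/down
#'   counts among the significant, alpha and adjustment used.
#' @exportS3Method generics::glance
glance.differential_results <- function(x, ...) {
  sig <- x[x$significant, ]
  tibble::tibble(
    n_tested = nrow(x),
    n_significant = nrow(sig),
    n_up = sum(sig$direction == "up"),
    n_down = sum(sig$direction == "down"),
    alpha = attr(x, "alpha"),
    adjust = attr(x, "adjust")
  )
}
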