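#' Plot scaled QC series by kinetics cluster
#'
#' Spaghetti plot of the MinMax-scaled QC time series, faceted by cluster,
#' with the cluster centroid overlaid -- the usual visual check that the
#' clusters correspond to distinct degradation-kinetics shapes.
#'
#' @param object An `rcc_correction` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rcc_correction <- function(object, ...) {
  qc <- object$qc
  labels <- tidy(object$clusters)
  long <- tibble::as_tibble(qc$scaled, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "run_id", values_to = "scaled") |>
    dplyr::mutate(time_min = rep(qc$times, times = nrow(qc$scaled))) |>
    dplyr::left_join(labels, by = "feature_id")
  cent <- tibble::as_tibble(object$clusters$centroids) |>
    dplyr::mutate(cluster = dplyr::row_number()) |>
    tidyr::pivot_longer(-"cluster", values_to = "scaled") |>
    dplyr::mutate(time_min = rep(qc$times, times = nrow(object$clusters$centroids)))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$scaled)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$feature_id),
      alpha = 0.25, colour = "grey50"
    ) +
    ggplot2::geom_line(
      data = cent, colour = "firebrick", linewidth = 1
    ) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Injection time (min)", y = "Scaled peak area",
      title = "QC degradation kinetics by cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential-abundance results
#'
#' @param object A `differential_results` tibble.
#' @param ... Unused.
#' @return A ggplot object (signed log2 fold change vs -log10 p).
#' @exportS3Method ggplot2::autoplot
autoplot.differential_results <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      signed_log2_fc = ifelse(.data$direction == "down", -1, 1) *
        log2(.data$fold_change)
    )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$signed_log2_fc, -log10(.data$p_value),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "alpha")), linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change (treated / control)", y = "-log10 p",
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of hierarchically clustered significant features
#'
#' @param object An `rcc_hclust` object from [hcluster_features()].
#' @param ... Unused.
#' @return A ggplot tile map, rows in dendrogram leaf order.
#' @exportS3Method ggplot2::autoplot
autoplot.rcc_hclust <- function(object, ...) {
  df <- tibble::as_tibble(object$matrix, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "run_id", values_to = "z") |>
    dplyr::mutate(
      feature_id = factor(.data$feature_id, levels = rev(rownames(object$matrix))),
      run_id = factor(.data$run_id, levels = names(object$classes))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$run_id, .data$feature_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-group intensity density plots
#'
#' The normality screen used before the t-test: kernel density of the
#' (optionally log2) intensities of the most abundant features, by sample
#' class. Informational only -- no feature is excluded on its basis.
#'
#' @param features Wide feature tibble.
#' @param schedule Schedule tibble.
#' @param n_top Number of most abundant features to show.
#' @param log2 Plot log2 intensities.
#' @return A ggplot object.
#' @export
plot_intensity_density <- function(features, schedule, n_top = 50, log2 = TRUE) {
  schedule <- validate_schedule(schedule)
  long <- feature_long(features, schedule) |>
    dplyr::filter(.data$class %in% c("control", "treated"))
  keep <- long |>
    dplyr::summarise(m = mean(.data$intensity, na.rm = TRUE), .by = "feature_id") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    dplyr::slice_head(n = n_top)
  df <- dplyr::semi_join(long, keep, by = "feature_id") |>
    dplyr::mutate(value = if (log2) base::log2(.data$intensity) else .data$intensity)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, colour = .data$class)) +
    ggplot2::geom_density() +
    ggplot2::labs(
      x = if (log2) "log2 peak area" else "peak area", y = "density",
      title = paste("Intensity distribution, top", n_top, "features")
    ) +
    ggplot2::theme_minimal()
}
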