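#' Two-sample pooled-variance (Student) t-test
#'
#' The equal-variance two-sided t-test with `n1 + n2 - 2` degrees of
#' freedom, written out explicitly so it can be checked against an
#' independent implementation.
#'
#' @param x,y Numeric vectors, each with at least two finite values.
#' @return A list with `t_stat`, `df` and `p_value`.
#' @examples
#' t_test_pooled(c(1, 2, 3), c(4, 5, 6))
#' @export
t_test_pooled <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    stop("Each group needs at least two finite values", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- if (se == 0) 0 else (mean(x) - mean(y)) / se
  df <- n1 + n2 - 2
  list(
    t_stat = t_stat,
    df = df,
    p_value = if (se == 0) 1 else 2 * stats::pt(-abs(t_stat), df)
  )
}

#' Fold change between two group means
#'
#' Reported as a ratio >= 1 with the direction carried separately (`"up"`
#' if the treated mean exceeds the control mean, `"down"` if below,
#' `"none"` on an exact tie), matching the up/down-arrow notation of
#' annotation tables.
#'
#' @param mean_control,mean_treated Positive group means.
#' @return A list with `fold_change` (>= 1) and `direction`.
#' @examples
#' fold_change(100, 270) # 2.7, up
#' @export
fold_change <- function(mean_control, mean_treated) {
  if (any(!is.finite(c(mean_control, mean_treated))) ||
    mean_control <= 0 || mean_treated <= 0) {
    stop("Group means must be positive and finite", call. = FALSE)
  }
  list(
    fold_change = max(mean_treated / mean_control, mean_control / mean_treated),
    direction = if (mean_treated > mean_control) {
      "up"
    } else if (mean_treated < mean_control) {
      "down"
    } else {
      "none"
    }
  )
}

#' Differential-abundance table (control vs treated)
#'
#' Per-feature pooled-variance t-test and fold change on (corrected) sample
#' intensities. No multiple-testing correction is applied by default; an
#' optional Benjamini-Hochberg adjustment is available behind `adjust`
#' (when on, significance is called on the adjusted p). A Shapiro-Wilk
#' p-value on the pooled within-group-centred intensities is reported for
#' information only; no feature is excluded on its basis. Features with
#' fewer than two finite values in either group, or with a non-positive
#' group mean, are skipped with a warning.
#'
#' @param features Wide feature tibble of corrected intensities.
#' @param schedule Schedule tibble (`control` / `treated` classes are used).
#' @param alpha Significance level; a feature is significant at `p <= alpha`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param log2 If `TRUE`, the t-test runs on log2 intensities (fold changes
#'   are always ratios of natural-scale means).
#' @return A tibble of class `differential_results`, one row per testable
#'   feature: `feature_id`, `mean_control`, `mean_treated`, `fold_change`,
#'   `direction`, `t_stat`, `p_value`, `p_adj` (if adjusted), `significant`,
#'   `shapiro_p`.
#' @export
differential_table <- function(features, schedule, alpha = 0.05,
                               adjust = c("none", "BH"), log2 = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(alpha >= 0, alpha <= 1)
  schedule <- validate_schedule(schedule)
  ctrl_runs <- schedule$run_id[schedule$class == "control"]
  trt_runs <- schedule$run_id[schedule$class == "treated"]
  if (length(ctrl_runs) < 2 || length(trt_runs) < 2) {
    stop("Need at least two control and two treated runs", call. = FALSE)
  }
  skipped <- character(0)
  rows <- purrr::map(seq_len(nrow(features)), function(i) {
    x <- as.numeric(features[i, ctrl_runs, drop = TRUE])
    y <- as.numeric(features[i, trt_runs, drop = TRUE])
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2 || mean(x) <= 0 || mean(y) <= 0) {
      skipped <<- c(skipped, features$feature_id[i])
      return(NULL)
    }
    tx <- if (log2) log2(x) else x
    ty <- if (log2) log2(y) else y
    tt <- t_test_pooled(tx, ty)
    fc <- fold_change(mean(x), mean(y))
    centred <- c(tx - mean(tx), ty - mean(ty))
    sw <- if (length(centred) >= 3 && stats::sd(centred) > 0) {
      tryCatch(stats::shapiro.test(centred)$p.value, error = function(e) NA_real_)
    } else {
      NA_real_
    }
    tibble::tibble(
      feature_id = features$feature_id[i],
      mean_control = mean(x),
      mean_treated = mean(y),
      fold_change = fc$fold_change,
      direction = fc$direction,
      t_stat = tt$t_stat,
      p_value = tt$p_value,
      shapiro_p = sw
    )
  }) |> purrr::list_rbind()
  if (length(skipped) > 0) {
    warning(
      length(skipped), " feature(s) skipped (too few finite values or ",
      "non-positive mean): ", paste(utils::head(skipped, 5), collapse = ", "),
      if (length(skipped) > 5) ", ..." else ""
    )
  }
  if (nrow(rows) == 0) {
    return(structure(rows, class = c("differential_results", class(rows))))
  }
  if (adjust == "BH") {
    rows$p_adj <- stats::p.adjust(rows$p_value, method = "BH")
    rows$significant <- rows$p_adj <= alpha
  } else {
    rows$significant <- rows$p_value <= alpha
  }
  rows <- dplyr::relocate(rows, "shapiro_p", .after = dplyr::last_col())
  attr(rows, "alpha") <- alpha
  attr(rows, "adjust") <- adjust
  class(rows) <- c("differential_results", class(rows))
  rows
}

#' Hierarchical clustering of significant features
#'
#' Rows (features) are autoscaled (z-score), then clustered by Euclidean
#' distance and Ward linkage ("ward.D2"), as in the usual metabolomics
#' heatmap workflow. Requires at least two significant features; otherwise
#' returns `NULL` with a message.
#'
#' @param results A `differential_results` tibble.
#' @param features Wide feature tibble with the intensities to display.
#' @param schedule Schedule tibble; only control/treated sample runs enter
#'   the heatmap.
#' @return A list of class `rcc_hclust`: `hclust` (the feature dendrogram),
#'   `matrix` (z-scored features x runs, rows in leaf order), `classes`
#'   (run classes). `NULL` when fewer than two significant features.
#' @export
hcluster_features <- function(results, features, schedule) {
  schedule <- validate_schedule(schedule)
  sig <- results$feature_id[results$significant]
  if (length(sig) < 2) {
    message("Fewer than two significant features; clustering skipped")
    return(NULL)
  }
  runs <- schedule$run_id[schedule$class %in% c("control", "treated")]
  mat <- as.matrix(features[match(sig, features$feature_id), runs, drop = FALSE])
  rownames(mat) <- sig
  z <- t(scale(t(mat)))
  z[is.nan(z)] <- 0
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  structure(
    list(
      hclust = hc,
      matrix = z[hc$order, , drop = FALSE],
      classes = stats::setNames(
        schedule$class[match(runs, schedule$run_id)], runs
      )
    ),
    class = "rcc_hclust"
  )
}

#' Leaf relative water content
#'
#' `LRWC (%) = (fresh - dry) * 100 / fresh`.
#'
#' @param fresh_weight,dry_weight Weights in grams; `fresh_weight > 0` and
#'   `dry_weight <= fresh_weight` (vectorized).
#' @return LRWC in percent.
#' @examples
#' lrwc(2, 1) # 50
#' @export
lrwc <- function(fresh_weight, dry_weight) {
  if (any(fresh_weight <= 0)) stop("fresh_weight must be positive", call. = FALSE)
  if (any(dry_weight > fresh_weight)) {
    stop("dry_weight cannot exceed fresh_weight", call. = FALSE)
  }
  if (any(dry_weight < 0)) stop("dry_weight cannot be negative", call. = FALSE)
  (fresh_weight - dry_weight) * 100 / fresh_weight
}
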