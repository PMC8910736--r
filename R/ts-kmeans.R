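# Distances from every series (rows of mat) to one centroid.
.dist_to_centroid <- function(mat, centroid, metric, window = NULL) {
  switch(metric,
    euclidean = sqrt(rowSums(sweep(mat, 2, centroid)^2)),
    dtw = ,
    dba = .dtw_dist_many(mat, centroid, window)
  )
}

#' k-means clustering of QC degradation-kinetics series
#'
#' Partitions MinMax-scaled QC time series into `k` clusters of similar
#' kinetics shape. Three metrics are supported: plain Euclidean distance,
#' DTW distance with arithmetic-mean centroid update, and DTW with DBA
#' centroid update. Initial centroids are `k` distinct series drawn under
#' the seed; the best of `n_init` restarts by within-cluster sum of squared
#' distances is kept, which makes the result deterministic for a fixed
#' seed.
#'
#' @param series A `qc_series_set` (its scaled matrix is used), or a numeric
#'   matrix with one pre-scaled series per row.
#' @param k Number of clusters, `1 <= k <=` number of series.
#' @param metric `"euclidean"`, `"dtw"` or `"dba"`.
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts.
#' @param max_iter Assignment/update iterations per restart.
#' @param window Optional Sakoe-Chiba band for the DTW metrics.
#' @return A list of class `qc_clusters`: `cluster` (named integer vector of
#'   labels), `centroids` (k x length matrix), `metric`, `objective`
#'   (within-cluster sum of squared distances), `sizes`.
#' @export
cluster_qc_series <- function(series, k = 5, metric = c("euclidean", "dtw", "dba"),
                              seed = 1L, n_init = 10, max_iter = 50,
                              window = NULL) {
  metric <- match.arg(metric)
  mat <- if (inherits(series, "qc_series_set")) series$scaled else as.matrix(series)
  n <- nrow(mat)
  stopifnot(k >= 1)
  if (k > n) stop("k exceeds the number of series (", n, ")", call. = FALSE)

  run_once <- function() {
    centroids <- mat[sample.int(n, k), , drop = FALSE]
    labels <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      d <- vapply(
        seq_len(k),
        function(j) .dist_to_centroid(mat, centroids[j, ], metric, window),
        numeric(n)
      )
      d <- matrix(d, nrow = n)
      new_labels <- max.col(-d, ties.method = "first")
      # re-seed empty clusters with the series farthest from its centroid
      for (j in seq_len(k)) {
        if (!any(new_labels == j)) {
          far <- which.max(d[cbind(seq_len(n), new_labels)])
          centroids[j, ] <- mat[far, ]
          new_labels[far] <- j
        }
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (j in seq_len(k)) {
        members <- mat[labels == j, , drop = FALSE]
        centroids[j, ] <- if (metric == "dba" && nrow(members) > 1) {
          as.numeric(dba_barycenter(members, n_iter = 5, window = window))
        } else {
          colMeans(members)
        }
      }
    }
    d_final <- vapply(
      seq_len(k),
      function(j) .dist_to_centroid(mat, centroids[j, ], metric, window),
      numeric(n)
    )
    d_final <- matrix(d_final, nrow = n)[cbind(seq_len(n), labels)]
    list(labels = labels, centroids = centroids, objective = sum(d_final^2))
  }

  best <- withr::with_seed(seed, {
    fits <- lapply(seq_len(n_init), function(i) run_once())
    fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  })
  structure(
    list(
      cluster = stats::setNames(best$labels, rownames(mat)),
      centroids = best$centroids,
      metric = metric,
      objective = best$objective,
      sizes = tabulate(best$labels, nbins = k)
    ),
    class = "qc_clusters"
  )
}

#' @export
print.qc_clusters <- function(x, ...) {
  cat(
    "<qc_clusters>", length(x$sizes), "clusters (", x$metric, "metric ), sizes:",
    paste(x$sizes, collapse = ", "),
    "| objective:", format(x$objective, digits = 6), "\n"
  )
  invisible(x)
}
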