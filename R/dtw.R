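#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with squared-difference local cost; the
#' square root of the accumulated cost along the optimal monotone warping
#' path is returned, so on equal-length series without warping it reduces to
#' the Euclidean distance. An optional Sakoe-Chiba band restricts the path
#' to `|i - j| <= window`.
#'
#' @param a,b Numeric series (non-empty).
#' @param window Optional non-negative integer band half-width; `NULL` for
#'   unconstrained warping.
#' @return Non-negative distance.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)) # 0: warping absorbs the repeat
#' @export
dtw_distance <- function(a, b, window = NULL) {
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) stop("DTW needs non-empty series", call. = FALSE)
  if (!is.null(window)) {
    stopifnot(window >= 0)
    if (window < abs(n - m)) window <- abs(n - m)
  }
  sqrt(.dtw_accumulate(a, b, window)[n, m])
}

# Accumulated-cost matrix of squared differences; shared by the distance and
# the barycenter (which needs the backtracked path).
.dtw_accumulate <- function(a, b, window = NULL) {
  n <- length(a)
  m <- length(b)
  D <- matrix(Inf, n, m)
  for (i in seq_len(n)) {
    js <- if (is.null(window)) seq_len(m) else {
      seq(max(1L, i - window), min(m, i + window))
    }
    for (j in js) {
      cost <- (a[i] - b[j])^2
      best <- if (i == 1 && j == 1) {
        0
      } else {
        min(
          if (i > 1) D[i - 1, j] else Inf,
          if (j > 1) D[i, j - 1] else Inf,
          if (i > 1 && j > 1) D[i - 1, j - 1] else Inf
        )
      }
      D[i, j] <- cost + best
    }
  }
  D
}

# DTW distances from every row of `mat` to a single reference series,
# computed in one DP sweep with vectorized cell updates (the assignment step
# of the time-series k-means calls this many times).
.dtw_dist_many <- function(mat, ref, window = NULL) {
  n <- nrow(mat)
  L <- ncol(mat)
  M <- length(ref)
  if (!is.null(window) && window < abs(L - M)) window <- abs(L - M)
  D <- array(Inf, dim = c(M, L, n))
  for (i in seq_len(M)) {
    js <- if (is.null(window)) seq_len(L) else seq(max(1L, i - window), min(L, i + window))
    for (j in js) {
      cost <- (ref[i] - mat[, j])^2
      best <- if (i == 1 && j == 1) {
        rep(0, n)
      } else {
        pmin(
          if (i > 1) D[i - 1, j, ] else rep(Inf, n),
          if (j > 1) D[i, j - 1, ] else rep(Inf, n),
          if (i > 1 && j > 1) D[i - 1, j - 1, ] else rep(Inf, n)
        )
      }
      D[i, j, ] <- cost + best
    }
  }
  sqrt(D[M, L, ])
}

# Optimal warping path as a 2-column matrix of (i, j) index pairs.
.dtw_path <- function(a, b, window = NULL) {
  D <- .dtw_accumulate(a, b, window)
  i <- length(a)
  j <- length(b)
  path <- list(c(i, j))
  while (i > 1 || j > 1) {
    choices <- rbind(
      if (i > 1 && j > 1) c(i - 1, j - 1, D[i - 1, j - 1]) else NULL,
      if (i > 1) c(i - 1, j, D[i - 1, j]) else NULL,
      if (j > 1) c(i, j - 1, D[i, j - 1]) else NULL
    )
    pick <- choices[which.min(choices[, 3]), ]
    i <- pick[1]
    j <- pick[2]
    path[[length(path) + 1]] <- c(i, j)
  }
  do.call(rbind, rev(path))
}

#' DTW barycenter averaging (DBA)
#'
#' Iterative centroid of a set of equal-length series under the DTW
#' distance: each series is aligned to the current centroid by DTW, the
#' series points mapped onto each centroid coordinate are averaged, and the
#' procedure repeats. The DBA objective (sum of squared DTW distances to the
#' centroid) is non-increasing over iterations; iteration stops early at a
#' fixed point.
#'
#' @param series A numeric matrix (one series per row) or a list of
#'   equal-length numeric vectors.
#' @param n_iter Maximum number of update iterations.
#' @param init Optional initial centroid; defaults to the element-wise mean.
#' @param window Optional Sakoe-Chiba band (see [dtw_distance()]).
#' @return The centroid as a numeric vector, with the per-iteration
#'   objective in attribute `"objective"`.
#' @export
dba_barycenter <- function(series, n_iter = 10, init = NULL, window = NULL) {
  if (is.list(series)) series <- do.call(rbind, series)
  stopifnot(is.matrix(series), nrow(series) >= 1, n_iter >= 1)
  centroid <- if (is.null(init)) colMeans(series) else init
  objective <- numeric(0)
  for (iter in seq_len(n_iter)) {
    sums <- numeric(length(centroid))
    counts <- integer(length(centroid))
    for (r in seq_len(nrow(series))) {
      path <- .dtw_path(centroid, series[r, ], window)
      # accumulate per centroid coordinate; a path may map several series
      # points onto the same coordinate, so plain indexed assignment would
      # drop all but the last contribution
      for (p in seq_len(nrow(path))) {
        i <- path[p, 1]
        sums[i] <- sums[i] + series[r, path[p, 2]]
        counts[i] <- counts[i] + 1L
      }
    }
    new_centroid <- sums / pmax(counts, 1L)
    obj <- sum(vapply(
      seq_len(nrow(series)),
      function(r) dtw_distance(new_centroid, series[r, ], window)^2,
      numeric(1)
    ))
    objective <- c(objective, obj)
    if (isTRUE(all.equal(new_centroid, centroid, tolerance = 1e-12))) {
      centroid <- new_centroid
      break
    }
    centroid <- new_centroid
  }
  attr(centroid, "objective") <- objective
  centroid
}
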