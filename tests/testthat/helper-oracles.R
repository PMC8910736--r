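# Independent oracles, deliberately written without reusing package internals.

# Exhaustive DTW: minimum accumulated squared cost over every monotone
# warping path, by plain recursion (fine for series of length <= 6).
brute_force_dtw <- function(a, b) {
  rec <- function(i, j) {
    cost <- (a[i] - b[j])^2
    if (i == 1 && j == 1) {
      return(cost)
    }
    prev <- Inf
    if (i > 1) prev <- min(prev, rec(i - 1, j))
    if (j > 1) prev <- min(prev, rec(i, j - 1))
    if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
    cost + prev
  }
  sqrt(rec(length(a), length(b)))
}

# Independent composition enumeration with its own mass constants: full
# nested loops over the element box, scaffold minima enforced, ppm rescored
# from scratch.
brute_force_compositions <- function(mz_obs, tol_ppm, c_max = 25, h_max = 40,
                                     n_max = 5, o_max = 10, p_max = 1, s_max = 1) {
  am <- c(
    C = 12, H = 1.00782503207, N = 14.0030740048,
    O = 15.9949146196, P = 30.97376163, S = 31.971071
  )
  res <- character(0)
  for (C in 15:c_max) {
    for (H in 16:h_max) {
      for (N in 3:n_max) {
        for (O in 3:o_max) {
          for (P in 0:p_max) {
            for (S in 0:s_max) {
              m <- C * am["C"] + H * am["H"] + N * am["N"] + O * am["O"] +
                P * am["P"] + S * am["S"] - 0.0005485799
              if (abs((m - mz_obs) / m * 1e6) <= tol_ppm) {
                res <- c(res, paste0(
                  "C", C, "H", H, "N", N, "O", O,
                  if (P > 0) paste0("P", if (P > 1) P else "") else "",
                  if (S > 0) paste0("S", if (S > 1) S else "") else ""
                ))
              }
            }
          }
        }
      }
    }
  }
  sort(res)
}

# Small wide feature table with explicit intensities.
toy_features <- function(intensities, ids = NULL) {
  n <- nrow(intensities)
  tibble::tibble(
    feature_id = ids %||% sprintf("F%02d", seq_len(n)),
    rt = seq(2, 3, length.out = n),
    mz = rep(348.1554, n),
    composition = rep("C17H22N3O5", n)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(intensities))
}

# Random neutral carbonyl formula (at least one C and one O).
random_carbonyl <- function() {
  c(
    C = sample(1:12, 1), H = sample(2:24, 1),
    O = sample(1:4, 1), N = sample(0:1, 1)
  )
}

`%||%` <- rlang::`%||%`
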