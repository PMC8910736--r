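qc_grid <- c(0, 255, 510, 765, 1020, 1275)

test_that("kinetics classifier labels clean shapes correctly", {
  up <- classify_kinetics(qc_grid, 1000 + 2 * qc_grid)
  expect_identical(up$kinetics_type, "I")
  expect_equal(up$slope, 2)

  down <- classify_kinetics(qc_grid, 5000 - 3 * qc_grid)
  expect_identical(down$kinetics_type, "II")

  flat <- classify_kinetics(qc_grid, rep(1e6, 6) * (1 + c(1, -1, 2, -2, 1, -1) * 1e-3))
  expect_identical(flat$kinetics_type, "steady")
})

test_that("piecewise kinetics recover a planted breakpoint near 1000 min", {
  b <- generate_batch(
    n_features = 12, class_counts = c(III = 12), noise_cv = 0.02, seed = 8
  )
  qc <- qc_series(b$features, b$schedule)
  for (i in seq_len(12)) {
    cl <- classify_kinetics(qc$times, qc$values[i, ])
    expect_identical(cl$kinetics_type, "III")
    # breakpoint search is restricted to the QC grid: the planted breakpoint
    # (900-1100 min) must be recovered within one QC interval (255 min)
    expect_lte(abs(cl$breakpoint - b$truth$breakpoint[i]), 255)
    expect_lt(cl$slope_late, 0)
  }
})

test_that("per-analyte fits follow the cluster family and flag steady features", {
  b <- generate_batch(
    n_features = 30, class_counts = c(I = 8, II = 10, steady = 12),
    noise_cv = 0.03, seed = 5
  )
  fits <- fit_kinetics(b$features, b$schedule, k = 3, seed = 1)
  truth <- b$truth$kinetics_class[match(fits$feature_id, b$truth$feature_id)]
  expect_identical(fits$kinetics_type[truth == "steady"], rep("steady", 12))
  expect_identical(fits$kinetics_type[truth == "I"], rep("I", 8))
  expect_identical(fits$kinetics_type[truth == "II"], rep("II", 10))
})

test_that("correction factors follow the closed form and its edge cases", {
  sched <- tibble::tibble(
    run_id = c("QC01", "S01", "QC02"),
    time_min = c(0, 500, 750),
    class = c("qc", "control", "qc")
  )
  lin <- tibble::tibble(
    feature_id = "F1", cluster = 1L, kinetics_type = "II", model = "linear",
    intercept = 1000, slope = -1, breakpoint = NA_real_, slope_late = NA_real_,
    r_squared = 1, rsd_percent = 40, rsd_fitted = 40
  )
  fac <- correction_factors(lin, sched)
  # f(t) = 1000 - t, t_ref = 0: factor 1 at t_ref, 1000/500 = 2 at t = 500
  expect_equal(fac$factor[fac$run_id == "QC01"], 1)
  expect_equal(fac$factor[fac$run_id == "S01"], 2)

  zero <- dplyr::mutate(lin, slope = 0, kinetics_type = "II")
  expect_equal(correction_factors(zero, sched)$factor, rep(1, 3))

  steady <- dplyr::mutate(lin, kinetics_type = "steady")
  expect_equal(correction_factors(steady, sched)$factor, rep(1, 3))

  # steep decay hits the clamp with a warning
  steep <- dplyr::mutate(lin, intercept = 1000, slope = -1.3)
  expect_warning(fac2 <- correction_factors(steep, sched), "clamped")
  expect_lte(max(fac2$factor), 5)

  # curve non-positive inside the batch: uncorrectable, factors 1
  neg <- dplyr::mutate(lin, intercept = 300, slope = -1)
  expect_warning(fac3 <- correction_factors(neg, sched), "non-positive")
  expect_equal(fac3$factor, rep(1, 3))
  expect_true(all(fac3$uncorrectable))
})

test_that("applying factors is exact multiplication with strict pairing", {
  sched <- tibble::tibble(
    run_id = c("QC01", "S01", "QC02", "S02"),
    time_min = c(0, 100, 255, 300),
    class = c("qc", "control", "qc", "treated")
  )
  feats <- toy_features(matrix(1e5, nrow = 2, ncol = 4,
    dimnames = list(NULL, sched$run_id)
  ))
  fac <- tidyr::expand_grid(feature_id = feats$feature_id, run_id = sched$run_id) |>
    dplyr::mutate(factor = 2)
  out <- apply_correction(feats, fac)
  expect_equal(as.numeric(out$S01), c(2e5, 2e5))

  ones <- dplyr::mutate(fac, factor = 1)
  expect_equal(apply_correction(feats, ones), feats)

  expect_error(
    apply_correction(feats, fac[fac$run_id != "S02", ]),
    "S02"
  )
})
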