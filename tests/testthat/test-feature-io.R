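schedule4 <- tibble::tibble(
  run_id = c("QC01", "S01", "S02", "QC02"),
  time_min = c(0, 21.25, 42.5, 255),
  class = c("qc", "control", "treated", "qc")
)

test_that("feature tables round-trip through TSV and CSV", {
  feats <- toy_features(matrix(
    c(2e5, 1e5, 3e5, 5e4, 2e4, 6e4, 1e6, 2e6, 9e5, 8e5, 7e5, 1.1e6),
    nrow = 3, byrow = TRUE,
    dimnames = list(NULL, schedule4$run_id)
  ))
  for (ext in c(".tsv", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_feature_table(feats, path)
    back <- read_feature_table(path, schedule4)
    expect_equal(back, feats)
  }
})

test_that("unparseable cells become NA with a warning; orphan runs are an error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c(
    "feature_id\trt\tmz\tcomposition\tQC01\tS01\tS02\tQC02",
    "F1\t2.0\t348.1554\tC17H22N3O5\t1e5\tbogus\t2e5\t3e5"
  ), path)
  expect_warning(back <- read_feature_table(path, schedule4), "could not be parsed")
  expect_true(is.na(back$S01))
  expect_equal(back$S02, 2e5)

  # header missing a scheduled run is rejected naming it
  readr::write_lines(c(
    "feature_id\trt\tmz\tQC01\tS01\tS02",
    "F1\t2.0\t348.1554\t1e5\t2e5\t3e5"
  ), path)
  expect_error(read_feature_table(path, schedule4), "QC02")
})

test_that("intensity filter keeps features whose QC maximum clears the gate", {
  qc_maxima <- c(5e4, 2e5, 1.2e5)
  feats <- toy_features(matrix(
    c(
      qc_maxima[1] / 2, 1e6, 1e6, qc_maxima[1],
      qc_maxima[2], 1e2, 1e2, qc_maxima[2] / 2,
      qc_maxima[3] / 4, 1e6, 1e6, qc_maxima[3]
    ),
    nrow = 3, byrow = TRUE, dimnames = list(NULL, schedule4$run_id)
  ))
  kept <- filter_by_intensity(feats, schedule4)
  expect_identical(kept$feature_id, c("F02", "F03")) # 2 of 3 survive, order kept
  # threshold 0 keeps everything; empty input returns empty
  expect_identical(nrow(filter_by_intensity(feats, schedule4, 0)), 3L)
  expect_identical(nrow(filter_by_intensity(feats[0, ], schedule4)), 0L)
  # idempotent
  expect_equal(filter_by_intensity(kept, schedule4), kept)
})

test_that("schedules are validated and round-trip through CSV", {
  expect_error(validate_schedule(schedule4[, 1:2]), "lacks column")
  bad <- schedule4
  bad$time_min <- rev(bad$time_min)
  expect_error(validate_schedule(bad), "strictly increasing")
  bad2 <- schedule4
  bad2$class[1] <- "blank"
  expect_error(validate_schedule(bad2), "Unknown run class")
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(schedule4, path)
  expect_equal(read_schedule(path), schedule4)
})

test_that("exact-mass annotation recovers planted compositions", {
  b <- generate_batch(
    n_features = 6, class_counts = c(steady = 6), noise_cv = 0, seed = 3
  )
  # restrict the search box to CHN3O compositions: at <= 3 ppm several
  # P-bearing formulas are legitimate isobaric alternatives
  ann <- annotate_features(
    b$features,
    tol_ppm = 3, element_bounds = c(N = 3, P = 0, S = 0)
  )
  expect_identical(ann$composition, b$truth$cation_formula)
  expect_identical(ann$rcc_formula, b$truth$rcc_formula)
  expect_true(all(abs(ann$error_ppm) <= 3))
})
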