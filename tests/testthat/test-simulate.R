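test_that("schedules place QCs at 255-minute increments over 24 h", {
  s <- make_schedule(seed = 1)
  qc_times <- s$time_min[s$class == "qc"]
  expect_equal(qc_times, seq(0, 1275, by = 255))
  expect_identical(sum(s$class == "control"), 7L)
  expect_identical(sum(s$class == "treated"), 7L)
  expect_lte(max(s$time_min), 1440)
  # determinism
  expect_identical(make_schedule(seed = 3), make_schedule(seed = 3))
  # runs_per_qc = 1: every sample run is bracketed by QCs
  s1 <- make_schedule(n_samples = 4, runs_per_qc = 1, span_min = 200, seed = 2)
  samp_rows <- which(s1$class != "qc")
  expect_true(all(diff(samp_rows) >= 2))
  expect_true(all(s1$class[samp_rows - 1] == "qc"))
  expect_error(make_schedule(n_samples = 3), "%%")
})

test_that("generated batches are deterministic and respect planted structure", {
  a <- generate_batch(n_features = 10, class_counts = c(II = 5, steady = 5), seed = 6)
  b <- generate_batch(n_features = 10, class_counts = c(II = 5, steady = 5), seed = 6)
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  expect_error(generate_batch(n_features = 10, class_counts = c(II = 4)), "sum")

  # noise off + steady + no fold change: each feature is constant across runs
  flat <- generate_batch(
    n_features = 4, class_counts = c(steady = 4), noise_cv = 0, seed = 7
  )
  run_cols <- flat$schedule$run_id
  spread <- apply(as.matrix(flat$features[, run_cols]), 1, function(x) diff(range(x)))
  expect_equal(unname(spread), rep(0, 4))
})

test_that("planted class II QC series match the analytic RSD of the ramp", {
  b <- generate_batch(
    n_features = 6, class_counts = c(II = 6), noise_cv = 0, seed = 9
  )
  qc <- qc_series(b$features, b$schedule)
  t_end <- max(b$schedule$time_min)
  for (i in seq_len(6)) {
    d <- b$truth$amplitude[b$truth$feature_id == rownames(qc$values)[i]]
    line <- 1 - d * qc$times / t_end
    expect_equal(
      rsd_percent(qc$values[i, ]),
      stats::sd(line) / mean(line) * 100,
      tolerance = 1e-8
    )
  }
})

test_that("batch files land in the formats the readers consume", {
  dir <- withr::local_tempdir()
  b <- generate_batch(n_features = 5, class_counts = c(I = 2, steady = 3), seed = 10)
  write_batch(b, dir)
  sched <- read_schedule(file.path(dir, "schedule.csv"))
  feats <- read_feature_table(file.path(dir, "features.tsv"), sched)
  expect_equal(feats$feature_id, b$features$feature_id)
  expect_equal(
    as.matrix(feats[, sched$run_id]),
    as.matrix(b$features[, sched$run_id]),
    tolerance = 1e-6
  )
  specs <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_true(all(vapply(
    specs$spectrum, function(s) annotate_ms2(s)$is_chh_derivative, logical(1)
  )))
})
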