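test_that("self-correction flattens the QC series of drifting features", {
  b <- generate_batch(
    n_features = 60, class_counts = c(I = 10, II = 30, III = 10, steady = 10),
    noise_cv = 0.05, seed = 12
  )
  corr <- correct_features(b$features, b$schedule, k = 4, seed = 1)
  fits <- corr$fits
  truth <- b$truth$kinetics_class[match(fits$feature_id, b$truth$feature_id)]
  drifting <- truth %in% c("I", "II", "III") & fits$kinetics_type != "steady"
  # RSD after correction is smaller than before for drifting features
  expect_true(mean(fits$rsd_corrected[drifting] < fits$rsd_percent[drifting]) >= 0.95)
  # and corrected QC series end up near the stability criterion
  expect_lt(stats::median(fits$rsd_corrected[drifting]), 10)
})

test_that("steady features pass through the correction unchanged", {
  b <- generate_batch(
    n_features = 20, class_counts = c(steady = 20), noise_cv = 0.05, seed = 13
  )
  corr <- correct_features(b$features, b$schedule, k = 2, seed = 1)
  expect_true(all(corr$fits$kinetics_type == "steady"))
  expect_true(all(corr$factors$factor == 1))
  expect_equal(corr$corrected, b$features[, names(corr$corrected)])
})

test_that("correction recovers planted fold changes biased by drift", {
  fc <- c(F001 = 2.5, F002 = 2.0, F003 = 1 / 2.2)
  b <- generate_batch(
    n_features = 40, class_counts = c(II = 25, steady = 15),
    fold_changes = fc, noise_cv = 0.05, seed = 14
  )
  corr <- correct_features(b$features, b$schedule, k = 2, seed = 1)
  res <- differential_table(corr$corrected, b$schedule)
  est <- res$fold_change[match(names(fc), res$feature_id)]
  expect_equal(est, unname(pmax(fc, 1 / fc)), tolerance = 0.1)
  expect_identical(
    res$direction[match(names(fc), res$feature_id)],
    c("up", "up", "down")
  )
})

test_that("tidy and glance summarize a correction", {
  b <- generate_batch(
    n_features = 15, class_counts = c(II = 10, steady = 5), seed = 15
  )
  corr <- correct_features(b$features, b$schedule, k = 2, seed = 1)
  td <- generics::tidy(corr)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 15L)
  gl <- generics::glance(corr)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_features, 15L)
  expect_lt(gl$median_rsd_corrected, gl$median_rsd_raw)
})
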