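test_that("diagnostic ions and neutral losses are annotated from CID spectra", {
  # dioxovaleric-acid derivative spectrum: 262 diagnostic, -H2O and -CO2 losses
  sp <- ms2_spectrum(388.15, c(370.1, 344.1, 262.2), c(100, 15.7, 18.6))
  ann <- annotate_ms2(sp)
  expect_true(ann$is_chh_derivative)
  expect_equal(ann$matched_diagnostic_ions, 262.2)
  expect_setequal(ann$matched_neutral_losses$loss, c("H2O", "CO2"))
  expect_equal(
    ann$matched_neutral_losses$fragment_mz[ann$matched_neutral_losses$loss == "H2O"],
    370.1
  )

  # m/z 244.1 alone suffices
  sp2 <- ms2_spectrum(372.19, c(244.1, 354.2), c(30, 100))
  expect_true(annotate_ms2(sp2)$is_chh_derivative)

  # nothing near any target
  sp3 <- ms2_spectrum(300.0, 100.0, 50)
  ann3 <- annotate_ms2(sp3)
  expect_false(ann3$is_chh_derivative)
  expect_length(ann3$matched_diagnostic_ions, 0)
  expect_identical(nrow(ann3$matched_neutral_losses), 0L)

  # empty peak list is a valid no-match result, not an error
  empty <- ms2_spectrum(300.0, numeric(0), numeric(0))
  expect_false(annotate_ms2(empty)$is_chh_derivative)
})

test_that("composition containing the scaffold flags a derivative without diagnostics", {
  sp <- ms2_spectrum(300.0, 100.0, 50)
  ann <- annotate_ms2(sp, composition = "C17H22N3O5", observed_mz = 348.1555)
  expect_true(ann$is_chh_derivative)
  expect_equal(ann$rcc_neutral_formula, "C3H6O3")
  expect_equal(round(ann$ppm_error, 1), -0.3)
})

test_that("synthetic spectra close the loop with the annotator", {
  sp <- synth_ms2("C3H6O3", losses = "H2O")
  expect_equal(sp$precursor_mz, monoisotopic_mass("C17H22N3O5", charge = 1))
  expect_true(any(abs(sp$peaks$mz - 244.1) < 1e-9))
  expect_true(any(abs(sp$peaks$mz - 262.1) < 1e-9))
  expect_true(any(abs(sp$peaks$mz - (sp$precursor_mz - 18.011)) < 1e-9))

  withr::with_seed(5, {
    for (i in 1:20) {
      rcc <- format_formula(random_carbonyl())
      expect_true(annotate_ms2(synth_ms2(rcc))$is_chh_derivative)
    }
  })
  expect_error(synth_ms2("C3H6O3", losses = "XYZ"), "Unknown neutral loss")
})

test_that("MGF files round-trip through the reader and writer", {
  specs <- list(
    synth_ms2("C3H6O3", losses = c("H2O", "CO2"), title = "glyceraldehyde"),
    synth_ms2("CH2O", title = "formaldehyde")
  )
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(specs, path)
  back <- read_mgf(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$title, c("glyceraldehyde", "formaldehyde"))
  expect_equal(back$precursor_mz, vapply(specs, `[[`, numeric(1), "precursor_mz"),
    tolerance = 1e-8
  )
  expect_equal(back$spectrum[[1]]$peaks$mz, specs[[1]]$peaks$mz, tolerance = 1e-5)
  expect_equal(back$spectrum[[1]]$peaks$intensity, specs[[1]]$peaks$intensity,
    tolerance = 1e-2
  )
})
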