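test_that("hydrazone derivatization arithmetic matches the annotation table", {
  expect_equal(derivative_from_rcc("CH2O"), "C15H18N3O3")
  expect_equal(derivative_from_rcc("C3H6O3"), "C17H22N3O5")
  expect_equal(derivative_from_rcc("C5H6O4"), "C19H22N3O6")
  expect_equal(rcc_from_derivative("C17H22N3O5"), "C3H6O3")
  expect_equal(rcc_from_derivative("C22H28N3O4"), "C8H12O2")
  expect_error(derivative_from_rcc("C2H6"), "carbonyl")
  expect_error(rcc_from_derivative("C5H6O4"), "scaffold")
})

test_that("derivatization and its inverse are exact mutual inverses", {
  reg <- rcc_registry()
  expect_identical(rcc_from_derivative(derivative_from_rcc(reg$rcc_formula)), reg$rcc_formula)
  withr::with_seed(11, {
    for (i in 1:200) {
      rcc <- format_formula(random_carbonyl())
      expect_identical(rcc_from_derivative(derivative_from_rcc(rcc)), rcc)
    }
  })
})

test_that("registry compositions reproduce their cation masses", {
  reg <- rcc_registry()
  expect_true(all(reg$cation_mz > monoisotopic_mass("C15H17N3O2", charge = 1)))
  expect_equal(
    reg$cation_mz,
    monoisotopic_mass(derivative_from_rcc(reg$rcc_formula), charge = 1)
  )
})

test_that("composition search finds the known cation and respects tolerance", {
  hits <- candidate_compositions(348.1554, tol_ppm = 3)
  expect_true("C17H22N3O5" %in% hits$formula)
  expect_identical(hits$formula[1], "C17H22N3O5") # best by |ppm|
  expect_true(all(abs(hits$ppm) <= 3))
  # below the scaffold mass nothing can match
  expect_identical(nrow(candidate_compositions(100, tol_ppm = 3)), 0L)
})

test_that("composition search agrees with brute-force enumeration", {
  for (mz in c(348.1554, 388.1503, 316.1656)) {
    hits <- candidate_compositions(
      mz,
      tol_ppm = 3,
      element_bounds = c(C = 25, H = 40, N = 5, O = 10, P = 1, S = 1)
    )
    expect_setequal(hits$formula, brute_force_compositions(mz, 3))
    # independent re-scoring of the reported ppm errors
    expect_equal(
      hits$ppm,
      (monoisotopic_mass(hits$formula, charge = 1) - mz) /
        monoisotopic_mass(hits$formula, charge = 1) * 1e6,
      tolerance = 1e-9
    )
  }
})
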