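# Neutral CHH (7-(diethylamino)coumarin-3-carbohydrazide), C14H17N3O3.
# Hydrazone formation condenses CHH with a carbonyl and releases one water;
# protonation then adds one H. The net atoms added to the neutral RCC to
# reach the derivative cation are therefore C14H16N3O2 (the "scaffold").
.chh_counts <- c(C = 14L, H = 17L, N = 3L, O = 3L)
.water_counts <- c(H = 2L, O = 1L)
.scaffold_counts <- c(C = 14L, H = 16L, N = 3L, O = 2L)

.counts_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  out[out > 0]
}

.counts_sub <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] - as.integer(b)
  if (any(out < 0)) {
    stop("Subtraction would give negative element counts", call. = FALSE)
  }
  out[out > 0]
}

#' CHH derivative cation of a reactive carbonyl compound
#'
#' Applies the hydrazone derivatization arithmetic: the neutral RCC gains
#' CHH (C14H17N3O3), loses one water, and is protonated, i.e. the cation
#' composition is `rcc + C14H16N3O2` with charge +1 (the H count of the
#' result includes the ionizing proton).
#'
#' @param rcc Neutral RCC formula, string or named count vector. Character
#'   vectors are processed element-wise.
#' @return Cation formula string(s) in Hill notation.
#' @examples
#' derivative_from_rcc("C3H6O3") # glyceraldehyde -> C17H22N3O5
#' @export
derivative_from_rcc <- function(rcc) {
  one <- function(f) {
    counts <- .as_counts(f)
    if (is.na(counts["C"]) || counts["C"] < 1 ||
      is.na(counts["O"]) || counts["O"] < 1) {
      stop(
        "Not a carbonyl compound (needs at least one C and one O): '",
        if (is.character(f)) f else format_formula(counts), "'",
        call. = FALSE
      )
    }
    format_formula(.counts_add(counts, .scaffold_counts))
  }
  if (is.character(rcc) && length(rcc) > 1L) {
    vapply(rcc, one, character(1), USE.NAMES = FALSE)
  } else {
    one(rcc)
  }
}

#' Neutral RCC behind a CHH derivative cation
#'
#' Exact inverse of [derivative_from_rcc()]: strips the C14H16N3O2 scaffold
#' atoms from the protonated hydrazone cation.
#'
#' @param cation Derivative cation formula, string or named count vector.
#'   Character vectors are processed element-wise.
#' @return Neutral RCC formula string(s).
#' @examples
#' rcc_from_derivative("C17H22N3O5") # -> C3H6O3 (glyceraldehyde)
#' @export
rcc_from_derivative <- function(cation) {
  one <- function(f) {
    counts <- .as_counts(f)
    sc <- .scaffold_counts
    have <- stats::setNames(rep(0L, length(sc)), names(sc))
    have[intersect(names(counts), names(sc))] <-
      counts[intersect(names(counts), names(sc))]
    if (any(have < sc)) {
      stop(
        "Not a CHH derivative: '",
        if (is.character(f)) f else format_formula(counts),
        "' does not contain the C14H16N3O2 scaffold atoms",
        call. = FALSE
      )
    }
    rcc <- .counts_sub(counts, sc)
    if (is.na(rcc["C"]) || rcc["C"] < 1 || is.na(rcc["O"]) || rcc["O"] < 1) {
      stop("Residual formula after scaffold removal is not a carbonyl",
        call. = FALSE
      )
    }
    format_formula(rcc)
  }
  if (is.character(cation) && length(cation) > 1L) {
    vapply(cation, one, character(1), USE.NAMES = FALSE)
  } else {
    one(cation)
  }
}

#' Default per-element count caps for composition search
#'
#' The box is the smallest one containing every derivative composition in
#' the built-in registry, including the phosphorus-bearing lipid-derived
#' carbonyl (C40H79N4O7P).
#'
#' @return Named integer vector of maximum element counts.
#' @export
default_element_bounds <- function() {
  c(C = 45L, H = 90L, N = 5L, O = 10L, P = 1L, S = 1L)
}

#' Candidate cation compositions for an observed m/z
#'
#' Exhaustively enumerates protonated-cation elemental compositions within a
#' ppm tolerance of an observed m/z, restricted to formulas that contain the
#' CHH hydrazone scaffold atoms (at least C15, H16, N3, O3; P and S
#' optional). This is the annotation gate for prospective RCC derivatives:
#' only compositions consistent with the (diethylamino)coumarin moiety are
#' admitted.
#'
#' @param observed_mz Observed m/z in Da (single value).
#' @param tol_ppm Mass tolerance in ppm (default 3).
#' @param element_bounds Named integer vector of per-element maxima; see
#'   [default_element_bounds()].
#' @return A tibble with columns `formula`, `mz` (calculated cation m/z) and
#'   `ppm` (signed error via [ppm_error()]), sorted by `abs(ppm)`. Zero rows
#'   when nothing matches.
#' @examples
#' candidate_compositions(348.1554)
#' @export
candidate_compositions <- function(observed_mz, tol_ppm = 3,
                                   element_bounds = default_element_bounds()) {
  stopifnot(length(observed_mz) == 1L, observed_mz > 0, tol_ppm > 0)
  bounds <- default_element_bounds()
  bounds[names(element_bounds)] <- as.integer(element_bounds)
  lo <- observed_mz * (1 - tol_ppm * 1e-6)
  hi <- observed_mz * (1 + tol_ppm * 1e-6)
  m <- .atomic_masses

  grid <- expand.grid(
    N = 3:bounds[["N"]],
    O = 3:bounds[["O"]],
    P = 0:bounds[["P"]],
    S = 0:bounds[["S"]],
    C = 15:bounds[["C"]]
  )
  res <- purrr::pmap_dfr(grid, function(N, O, P, S, C) {
    base <- C * m[["C"]] + N * m[["N"]] + O * m[["O"]] +
      P * m[["P"]] + S * m[["S"]] - .electron_mass
    h_min <- max(16L, as.integer(ceiling((lo - base) / m[["H"]] - 1e-9)))
    h_max <- min(bounds[["H"]], as.integer(floor((hi - base) / m[["H"]] + 1e-9)))
    if (h_min > h_max) {
      return(NULL)
    }
    H <- h_min:h_max
    mz <- base + H * m[["H"]]
    tibble::tibble(
      formula = vapply(
        H,
        function(h) {
          format_formula(c(C = C, H = h, N = N, O = O, P = P, S = S))
        },
        character(1)
      ),
      mz = mz,
      ppm = ppm_error(observed_mz, mz)
    )
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(
      formula = character(0), mz = numeric(0), ppm = numeric(0)
    ))
  }
  dplyr::arrange(res, abs(.data$ppm))
}

#' Built-in registry of assigned RCC derivatives
#'
#' The CHH derivatives with a structure assignment from the differential
#' table of the source study: compound name, neutral RCC formula, derivative
#' cation composition and its calculated m/z. Used as a draw pool by the
#' synthetic batch generator and as a round-trip fixture.
#'
#' @return A tibble with columns `compound`, `rcc_formula`, `cation_formula`
#'   and `cation_mz`.
#' @export
rcc_registry <- function() {
  reg <- tibble::tribble(
    ~compound, ~rcc_formula,
    "glyceraldehyde", "C3H6O3",
    "4,5-dioxovaleric acid", "C5H6O4",
    "formaldehyde", "CH2O",
    "propanal", "C3H6O",
    "4-hydroxy-5-hexenal", "C6H10O2",
    "hydroxy-2,4-octadienal", "C8H12O2",
    "methacrolein", "C4H6O",
    "3-hydroxy-pentanal", "C5H10O2",
    "8-oxo-4-hydroxy-6-octenal", "C8H12O3",
    "9-oxo-2,4-nonadienoic acid", "C9H12O3",
    "9-oxo-2,6-dihydroxy-1-nonenal", "C9H14O4",
    "4-hydroxy-11-oxo-2-undecenoic acid", "C11H18O4",
    "butanal", "C4H8O",
    "7-hydroxy-heptanal", "C7H14O2",
    "2,4-heptadienal", "C7H10O",
    "10-oxo-4-hydroxy-decanal", "C10H18O3",
    "pentanal", "C5H10O",
    "hexanal", "C6H12O",
    "methylglyoxal", "C3H4O2",
    "glyoxal", "C2H2O2",
    "malondialdehyde", "C3H4O2",
    "4-hydroxy-2-nonenal", "C9H16O2",
    "acrolein", "C3H4O"
  )
  reg$cation_formula <- derivative_from_rcc(reg$rcc_formula)
  reg$cation_mz <- monoisotopic_mass(reg$cation_formula, charge = 1L)
  reg
}
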