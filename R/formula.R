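# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
.atomic_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

# Mass of the electron in Da; subtracted once per positive charge so that
# cation m/z refers to the actual ion, not the neutral-atom sum.
.electron_mass <- 0.00054857990

#' Parse an elemental formula in Hill notation
#'
#' Turns a formula string such as `"C17H22N3O5"` into a named integer vector
#' of element counts. Only the elements C, H, N, O, P and S are accepted;
#' these cover CHH (7-(diethylamino)coumarin-3-carbohydrazide) derivatives of
#' the reactive carbonyl compounds this package deals with, including
#' phospholipid-derived carbonyls.
#'
#' @param formula A single formula string in Hill notation.
#' @return Named integer vector of element counts (zero-count elements
#'   dropped). The empty string parses to an empty vector.
#' @examples
#' parse_formula("C17H22N3O5")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (formula == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  tokens <- stringr::str_match_all(formula, "([A-Z][a-z]?)(\\d*)")[[1]]
  tokens <- tokens[tokens[, 1] != "", , drop = FALSE]
  if (paste0(tokens[, 1], collapse = "") != formula) {
    stop("Cannot parse formula string: '", formula, "'", call. = FALSE)
  }
  elements <- tokens[, 2]
  unknown <- setdiff(elements, names(.atomic_masses))
  if (length(unknown) > 0) {
    stop(
      "Unknown element symbol(s): ", paste(unknown, collapse = ", "),
      " in formula '", formula, "'",
      call. = FALSE
    )
  }
  counts <- as.integer(ifelse(tokens[, 3] == "", 1L, tokens[, 3]))
  out <- tapply(counts, factor(elements, levels = names(.atomic_masses)), sum)
  out <- out[!is.na(out) & out > 0]
  stats::setNames(as.integer(out), names(out))
}

#' Format element counts as a Hill-notation formula string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' this matches how compositions are conventionally printed in MS annotation
#' tables.
#'
#' @param counts Named integer vector of element counts.
#' @return A single formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return("")
  }
  rest <- sort(setdiff(names(counts), c("C", "H")))
  ord <- c(intersect(c("C", "H"), names(counts)), rest)
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

.as_counts <- function(formula) {
  if (is.character(formula)) parse_formula(formula) else {
    stopifnot(is.numeric(formula), !is.null(names(formula)))
    unknown <- setdiff(names(formula), names(.atomic_masses))
    if (length(unknown) > 0) {
      stop("Unknown element symbol(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(formula < 0)) stop("Element counts must be non-negative", call. = FALSE)
    formula
  }
}

#' Monoisotopic mass or m/z of an elemental formula
#'
#' Sums monoisotopic atomic masses and subtracts one electron mass per unit
#' of positive charge, so that for a protonated cation (whose H count must
#' already include the ionizing proton) the result is the m/z actually
#' observed on the instrument.
#'
#' @param formula Formula string in Hill notation (e.g. `"C17H22N3O5"`), or a
#'   named count vector as returned by [parse_formula()]. May be a character
#'   vector; the result is vectorized along it.
#' @param charge Integer charge, `0` (neutral) or `1` (protonated cation).
#' @return Numeric vector of masses in Da (m/z for `charge = 1`).
#' @examples
#' monoisotopic_mass("C17H22N3O5", charge = 1) # CHH-glyceraldehyde cation
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(formula, charge = 0L) {
  stopifnot(length(charge) == 1L, charge %in% c(0L, 1L))
  one <- function(f) {
    counts <- .as_counts(f)
    sum(.atomic_masses[names(counts)] * counts) - charge * .electron_mass
  }
  if (is.character(formula) && length(formula) > 1L) {
    vapply(formula, one, numeric(1), USE.NAMES = FALSE)
  } else {
    one(formula)
  }
}

#' Relative mass error in parts per million
#'
#' Computed as `(calculated - observed) / calculated * 1e6`. With this sign
#' convention an observed m/z above the calculated value gives a negative
#' error, matching how annotation tables for CHH derivatives report it.
#'
#' @param observed_mz,calculated_mz Positive m/z values in Da (vectorized).
#' @return Numeric vector of ppm errors (not rounded; round to 1 decimal for
#'   reporting).
#' @examples
#' ppm_error(388.1507, 388.1503)
#' @export
ppm_error <- function(observed_mz, calculated_mz) {
  if (any(observed_mz <= 0) || any(calculated_mz <= 0)) {
    stop("m/z values must be positive", call. = FALSE)
  }
  (calculated_mz - observed_mz) / calculated_mz * 1e6
}
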