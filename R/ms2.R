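# Diagnostic fragment ions of CHH hydrazones: m/z 244.1 (loss of the RCC
# plus the hydrazine moiety, -N2H4) and m/z 262.1 (loss of the RCC plus the
# amino group, -NH2). Either signal marks an RCC derivative.
.diagnostic_ions <- c(244.1, 262.1)

.neutral_losses <- function() {
  tibble::tribble(
    ~loss, ~loss_mass,
    "H2O", 18.011,
    "NH2", 16.019,
    "N2H4", 32.037,
    "CO2", 43.990,
    "CH2O2", 46.005
  )
}

#' Construct an MS/MS spectrum
#'
#' @param precursor_mz Precursor m/z in Da.
#' @param mz Fragment m/z values (Da).
#' @param intensity Fragment intensities; rescaled so the base peak is 100.
#' @param title Optional spectrum title.
#' @param frag_tol Tolerance (Da) allowed for fragments nominally above the
#'   precursor (isotope/rounding slack).
#' @return An object of class `ms2_spectrum`: a list with `title`,
#'   `precursor_mz` and a `peaks` tibble (`mz`, `intensity`).
#' @export
ms2_spectrum <- function(precursor_mz, mz, intensity, title = "",
                         frag_tol = 0.3) {
  stopifnot(
    length(precursor_mz) == 1L, precursor_mz > 0,
    length(mz) == length(intensity)
  )
  if (length(mz) > 0) {
    stopifnot(all(mz > 0), all(intensity > 0))
    if (any(mz > precursor_mz + frag_tol + 1)) {
      stop("Fragment m/z above precursor m/z", call. = FALSE)
    }
    intensity <- intensity / max(intensity) * 100
  }
  structure(
    list(
      title = title,
      precursor_mz = precursor_mz,
      peaks = tibble::tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
    ),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(
    "<ms2_spectrum>", if (nzchar(x$title)) x$title else NULL,
    "precursor m/z", format(x$precursor_mz, digits = 8),
    "with", nrow(x$peaks), "peaks\n"
  )
  invisible(x)
}

#' Annotate an MS/MS spectrum as a prospective CHH derivative
#'
#' Flags the spectrum as a CHH (RCC) derivative when a fragment matches one
#' of the diagnostic coumarin ions (m/z 244.1 or 262.1) within `frag_tol`,
#' and annotates fragments that sit one known neutral loss (water, ammonia-
#' derived NH2, hydrazine, CO2, formic acid) below the precursor. Absence of
#' the 244.1 signal is never held against a spectrum: one diagnostic ion
#' suffices.
#'
#' @param spec An [ms2_spectrum()] object.
#' @param frag_tol Fragment matching tolerance in Da; the default 0.3 suits
#'   ion-trap CID spectra reported to one decimal.
#' @param composition Optional cation composition string; if supplied and it
#'   contains the hydrazone scaffold atoms, the derivative flag is set and
#'   the neutral RCC formula is reported.
#' @param observed_mz Optional observed precursor m/z used, together with
#'   `composition`, to report the annotation ppm error.
#' @return A list of class `chh_annotation`: `is_chh_derivative`,
#'   `matched_diagnostic_ions` (numeric), `matched_neutral_losses` (tibble
#'   `loss`, `loss_mass`, `fragment_mz`), `rcc_neutral_formula` (or `NA`),
#'   `ppm_error` (or `NA`).
#' @examples
#' sp <- ms2_spectrum(388.15, c(262.2, 344.1, 370.1), c(19, 16, 100))
#' annotate_ms2(sp)
#' @export
annotate_ms2 <- function(spec, frag_tol = 0.3, composition = NULL,
                         observed_mz = NULL) {
  stopifnot(inherits(spec, "ms2_spectrum"), frag_tol > 0)
  peaks <- spec$peaks
  diag_hits <- numeric(0)
  losses <- .neutral_losses()
  loss_hits <- losses[0, ]
  loss_hits$fragment_mz <- numeric(0)
  if (nrow(peaks) > 0) {
    diag_hits <- peaks$mz[vapply(
      peaks$mz,
      function(p) any(abs(p - .diagnostic_ions) <= frag_tol),
      logical(1)
    )]
    expected <- spec$precursor_mz - losses$loss_mass
    hit <- purrr::map_dfr(seq_len(nrow(losses)), function(i) {
      match <- peaks$mz[abs(peaks$mz - expected[i]) <= frag_tol]
      if (length(match) == 0) {
        return(NULL)
      }
      tibble::tibble(
        loss = losses$loss[i],
        loss_mass = losses$loss_mass[i],
        fragment_mz = match[which.min(abs(match - expected[i]))]
      )
    })
    if (nrow(hit) > 0) loss_hits <- hit
  }

  rcc <- NA_character_
  scaffold_ok <- FALSE
  if (!is.null(composition)) {
    rcc <- tryCatch(rcc_from_derivative(composition), error = function(e) NA_character_)
    scaffold_ok <- !is.na(rcc)
  }
  ppm <- NA_real_
  if (!is.null(composition) && !is.null(observed_mz) && scaffold_ok) {
    ppm <- ppm_error(observed_mz, monoisotopic_mass(composition, charge = 1L))
  }
  structure(
    list(
      is_chh_derivative = length(diag_hits) > 0 || scaffold_ok,
      matched_diagnostic_ions = unname(diag_hits),
      matched_neutral_losses = loss_hits,
      rcc_neutral_formula = rcc,
      ppm_error = ppm
    ),
    class = "chh_annotation"
  )
}

#' @export
print.chh_annotation <- function(x, ...) {
  cat(
    "<chh_annotation>",
    if (x$is_chh_derivative) "CHH derivative" else "not flagged",
    "| diagnostic ions:",
    if (length(x$matched_diagnostic_ions)) {
      paste(x$matched_diagnostic_ions, collapse = ", ")
    } else {
      "none"
    },
    "| neutral losses:",
    if (nrow(x$matched_neutral_losses)) {
      paste(x$matched_neutral_losses$loss, collapse = ", ")
    } else {
      "none"
    },
    "\n"
  )
  invisible(x)
}

#' Read MS/MS peak lists from an MGF file
#'
#' Minimal Mascot Generic Format reader: `BEGIN IONS`/`END IONS` blocks with
#' `TITLE=`, `PEPMASS=` headers and whitespace-separated `m/z intensity`
#' peak lines.
#'
#' @param path Path to an MGF file.
#' @return A tibble with one row per spectrum: `title`, `precursor_mz`, and
#'   a `spectrum` list-column of [ms2_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readr::read_lines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("Malformed MGF file: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  specs <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[(s + 1):(e - 1)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pep <- grep("^PEPMASS=", block, value = TRUE)[1]
    if (is.na(pep)) stop("MGF block without PEPMASS", call. = FALSE)
    precursor <- as.numeric(strsplit(sub("^PEPMASS=", "", pep), "\\s+")[[1]][1])
    peak_lines <- block[grepl("^\\s*[0-9]", block)]
    mzint <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"), function(p) {
      as.numeric(p[1:2])
    }))
    if (is.null(mzint)) mzint <- matrix(numeric(0), ncol = 2)
    ms2_spectrum(
      precursor_mz = precursor,
      mz = mzint[, 1], intensity = mzint[, 2],
      title = if (is.na(title)) "" else title
    )
  })
  tibble::tibble(
    title = vapply(specs, function(s) s$title, character(1)),
    precursor_mz = vapply(specs, function(s) s$precursor_mz, numeric(1)),
    spectrum = specs
  )
}

#' Write MS/MS spectra to an MGF file
#'
#' @param spectra A list of [ms2_spectrum()] objects, or the tibble returned
#'   by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (is.data.frame(spectra)) spectra <- spectra$spectrum
  lines <- purrr::map(spectra, function(s) {
    c(
      "BEGIN IONS",
      paste0("TITLE=", s$title),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 10)),
      sprintf("%.5f %.2f", s$peaks$mz, s$peaks$intensity),
      "END IONS",
      ""
    )
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}
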