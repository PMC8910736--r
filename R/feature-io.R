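.meta_cols <- c("feature_id", "rt", "mz", "composition")

#' Validate an injection schedule
#'
#' A schedule is a tibble with one row per LC-MS run: `run_id`, `time_min`
#' (injection clock time in minutes from batch start) and `class` (one of
#' `"qc"`, `"control"`, `"treated"`). Clock times must be strictly
#' increasing, and at least two QC runs are required for any stability
#' correction downstream.
#'
#' @param schedule A data frame with columns `run_id`, `time_min`, `class`.
#' @return The schedule as a tibble, invisibly validated.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  missing <- setdiff(c("run_id", "time_min", "class"), names(schedule))
  if (length(missing) > 0) {
    stop("Schedule lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  schedule <- tibble::as_tibble(schedule)
  schedule$class <- tolower(as.character(schedule$class))
  bad <- setdiff(unique(schedule$class), c("qc", "control", "treated"))
  if (length(bad) > 0) {
    stop("Unknown run class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(schedule$run_id)) {
    stop("Duplicated run_id in schedule", call. = FALSE)
  }
  if (any(diff(schedule$time_min) <= 0)) {
    stop("Schedule clock times must be strictly increasing", call. = FALSE)
  }
  if (sum(schedule$class == "qc") < 2) {
    warning("Fewer than 2 QC runs: stability correction will not be possible")
  }
  schedule
}

#' Read an injection schedule from CSV
#'
#' Expected columns: `run_id`, `time_min`, `class`.
#'
#' @param path Path to a CSV file.
#' @return A validated schedule tibble.
#' @export
read_schedule <- function(path) {
  validate_schedule(readr::read_csv(path, show_col_types = FALSE))
}

#' Write an injection schedule to CSV
#' @param schedule Schedule tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(validate_schedule(schedule), path)
  invisible(path)
}

#' Read a feature table
#'
#' Reads a features-by-runs table (TSV or CSV, decided by file extension)
#' whose first columns are `feature_id`, `rt` (minutes), `mz` (Da) and
#' optionally `composition`, followed by one peak-area column per run in the
#' schedule. Cells that cannot be parsed as numbers become explicit `NA`
#' with a warning; a header/schedule mismatch is an error naming the orphan
#' run ids on either side.
#'
#' @param path Path to the table.
#' @param schedule Schedule tibble (see [validate_schedule()]).
#' @return A wide tibble: metadata columns then one numeric column per run.
#' @export
read_feature_table <- function(path, schedule) {
  schedule <- validate_schedule(schedule)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- suppressWarnings(
    reader(path, show_col_types = FALSE, col_types = readr::cols(.default = "c"))
  )
  if (!"feature_id" %in% names(raw)) {
    stop("Feature table lacks a feature_id column", call. = FALSE)
  }
  run_cols <- setdiff(names(raw), .meta_cols)
  missing_runs <- setdiff(schedule$run_id, run_cols)
  orphan_cols <- setdiff(run_cols, schedule$run_id)
  if (length(missing_runs) > 0 || length(orphan_cols) > 0) {
    stop(
      "Feature table and schedule disagree on runs.",
      if (length(missing_runs)) {
        paste0(" Scheduled but absent from table: ", paste(missing_runs, collapse = ", "), ".")
      } else {
        ""
      },
      if (length(orphan_cols)) {
        paste0(" In table but not scheduled: ", paste(orphan_cols, collapse = ", "), ".")
      } else {
        ""
      },
      call. = FALSE
    )
  }
  out <- raw
  num_cols <- c(intersect(c("rt", "mz"), names(raw)), schedule$run_id)
  n_bad <- 0L
  for (cc in num_cols) {
    parsed <- suppressWarnings(as.numeric(out[[cc]]))
    n_bad <- n_bad + sum(is.na(parsed) & !is.na(out[[cc]]) & out[[cc]] != "")
    out[[cc]] <- parsed
  }
  if (n_bad > 0) {
    warning(n_bad, " cell(s) could not be parsed as numbers and were set to NA")
  }
  if ("rt" %in% names(out) && any(out$rt < 0, na.rm = TRUE)) {
    stop("Negative retention times in feature table", call. = FALSE)
  }
  if ("mz" %in% names(out) && any(out$mz <= 0, na.rm = TRUE)) {
    stop("Non-positive m/z in feature table", call. = FALSE)
  }
  tibble::as_tibble(out[, c(intersect(.meta_cols, names(out)), schedule$run_id)])
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()]; TSV or CSV by file extension.
#'
#' @param features Wide feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv
  } else {
    readr::write_tsv
  }
  writer(features, path)
  invisible(path)
}

#' Keep features whose QC signal clears an intensity threshold
#'
#' A feature is retained when its maximum peak area across the QC runs
#' exceeds `threshold` (default 1e5 counts, the inclusion gate for
#' prospective RCC derivatives). QC runs are used because QC injections are
#' pools of every sample, so any genuine feature is present there. Order is
#' preserved and the operation is idempotent.
#'
#' @param features Wide feature tibble.
#' @param schedule Schedule tibble.
#' @param threshold Minimum QC peak area in counts (kept if strictly above).
#' @return The filtered feature tibble.
#' @export
filter_by_intensity <- function(features, schedule, threshold = 1e5) {
  stopifnot(threshold >= 0)
  schedule <- validate_schedule(schedule)
  if (nrow(features) == 0) {
    return(features)
  }
  qc_runs <- schedule$run_id[schedule$class == "qc"]
  qc_max <- apply(
    as.matrix(features[, qc_runs, drop = FALSE]), 1,
    function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE)
  )
  features[qc_max > threshold, , drop = FALSE]
}

#' Pivot a feature table to long (one row per feature x run)
#'
#' @param features Wide feature tibble.
#' @param schedule Schedule tibble; contributes `time_min` and `class`.
#' @return Long tibble: metadata columns, `run_id`, `time_min`, `class`,
#'   `intensity`.
#' @export
feature_long <- function(features, schedule) {
  schedule <- validate_schedule(schedule)
  features |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(schedule$run_id),
      names_to = "run_id", values_to = "intensity"
    ) |>
    dplyr::left_join(schedule, by = "run_id")
}

#' Assign cation compositions to features by exact mass
#'
#' Runs the scaffold-constrained composition search on each feature m/z and
#' keeps the best candidate (smallest absolute ppm error) within tolerance.
#'
#' @param features Wide feature tibble with an `mz` column.
#' @param tol_ppm Mass tolerance in ppm (default 3).
#' @param element_bounds Per-element count caps, see [default_element_bounds()].
#' @return `features` with columns `composition`, `calc_mz`, `error_ppm` and
#'   `rcc_formula` (neutral RCC behind the derivative) filled in; features
#'   with no candidate get `NA`.
#' @export
annotate_features <- function(features, tol_ppm = 3,
                              element_bounds = default_element_bounds()) {
  ann <- purrr::map(features$mz, candidate_compositions,
    tol_ppm = tol_ppm, element_bounds = element_bounds
  )
  best <- purrr::map(ann, function(a) {
    if (nrow(a) == 0) {
      tibble::tibble(composition = NA_character_, calc_mz = NA_real_, error_ppm = NA_real_)
    } else {
      tibble::tibble(
        composition = a$formula[1], calc_mz = a$mz[1], error_ppm = a$ppm[1]
      )
    }
  }) |> purrr::list_rbind()
  features$composition <- best$composition
  features$calc_mz <- best$calc_mz
  features$error_ppm <- best$error_ppm
  features$rcc_formula <- purrr::map_chr(best$composition, function(f) {
    if (is.na(f)) {
      return(NA_character_)
    }
    tryCatch(rcc_from_derivative(f), error = function(e) NA_character_)
  })
  dplyr::relocate(
    features, dplyr::all_of(c("composition", "calc_mz", "error_ppm", "rcc_formula")),
    .after = "mz"
  )
}
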