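#' Build a synthetic injection schedule
#'
#' Emulates a single LC-MS batch: run slots every `minutes_per_run` minutes
#' across `span_min` (default 24 h, the window over which derivative
#' degradation is observed), with a pooled QC injected every `runs_per_qc`
#' runs -- QC clock times 0, 255, 510, ... minutes at the defaults. The
#' `n_samples` biological runs (even control/treated split, order
#' randomized under `seed`) are spread evenly over the remaining slots.
#' `runs_per_qc = 1` alternates QC and sample runs.
#'
#' @param n_samples Even number of biological runs (default 14, i.e. 7 per
#'   group).
#' @param runs_per_qc A QC occupies every `runs_per_qc`-th run slot.
#' @param minutes_per_run Slot duration in minutes.
#' @param span_min Batch duration in minutes.
#' @param seed Integer seed for the class randomization.
#' @return A schedule tibble (`run_id`, `time_min`, `class`).
#' @examples
#' make_schedule(seed = 1)
#' @export
make_schedule <- function(n_samples = 14, runs_per_qc = 12,
                          minutes_per_run = 21.25, span_min = 1440,
                          seed = 1L) {
  stopifnot(
    n_samples >= 2, n_samples %% 2 == 0, runs_per_qc >= 1,
    minutes_per_run > 0, span_min > minutes_per_run
  )
  n_slots <- floor(span_min / minutes_per_run) + 1
  slot_idx <- seq_len(n_slots) - 1L
  is_qc <- if (runs_per_qc == 1) {
    slot_idx %% 2L == 0L
  } else {
    slot_idx %% runs_per_qc == 0L
  }
  sample_slots <- slot_idx[!is_qc]
  if (n_samples > length(sample_slots)) {
    stop("Too many samples for the schedule (", length(sample_slots),
      " sample slots)",
      call. = FALSE
    )
  }
  take <- unique(round(seq(1, length(sample_slots), length.out = n_samples)))
  while (length(take) < n_samples) { # collisions only when slots are scarce
    take <- sort(union(take, setdiff(seq_along(sample_slots), take)[1]))
  }
  chosen <- sample_slots[take]
  classes <- withr::with_seed(
    seed,
    sample(rep(c("control", "treated"), n_samples / 2))
  )
  qc_slots <- slot_idx[is_qc]
  runs <- tibble::tibble(
    slot = c(qc_slots, chosen),
    class = c(rep("qc", length(qc_slots)), classes)
  ) |> dplyr::arrange(.data$slot)
  runs$time_min <- runs$slot * minutes_per_run
  n_qc <- sum(runs$class == "qc")
  ids <- character(nrow(runs))
  ids[runs$class == "qc"] <- sprintf("QC%02d", seq_len(n_qc))
  ids[runs$class != "qc"] <- sprintf("S%02d", seq_len(n_samples))
  runs$run_id <- ids
  validate_schedule(runs[, c("run_id", "time_min", "class")])
}

# Class sizes proportional to the reference batch (17/95/37/45 of 194),
# largest-remainder rounding so they sum exactly to n_features.
.default_class_counts <- function(n_features) {
  ref <- c(I = 17, II = 95, III = 37, steady = 45)
  raw <- ref / sum(ref) * n_features
  base <- floor(raw)
  short <- n_features - sum(base)
  if (short > 0) {
    bump <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[bump] <- base[bump] + 1
  }
  stats::setNames(as.integer(base), names(ref))
}

# Relative drift/degradation curve g(t) for one feature, g(0) = 1.
.drift_curve <- function(class, amplitude, breakpoint, end_frac, t_end) {
  force(list(class, amplitude, breakpoint, end_frac, t_end))
  switch(class,
    I = function(t) 1 + amplitude * t / t_end,
    II = function(t) 1 - amplitude * t / t_end,
    III = function(t) {
      early <- 1 - amplitude * pmin(t, breakpoint) / breakpoint
      late_slope <- (end_frac - (1 - amplitude)) / (t_end - breakpoint)
      early + pmax(t - breakpoint, 0) * late_slope
    },
    steady = function(t) rep(1, length(t))
  )
}

#' Generate a synthetic carbonyl-metabolome batch with known ground truth
#'
#' Produces a feature table with the statistical structure the correction
#' and testing stages assume: four planted QC-kinetics classes (linear
#' increase `I`, linear decrease `II`, piecewise decrease with a late drop
#' around 1000 min `III`, and `steady`), per-feature baselines log-uniform
#' in \[1e5, 1e8\] counts, optional planted group fold changes, and
#' multiplicative lognormal noise. The drift curve of a feature is shared
#' between its QC and sample runs (QC pools see the averaged group effect),
#' so the generated batch is exactly the situation the QC-based correction
#' is meant to fix.
#'
#' Per-class amplitude draws (documented in the methods vignette): class I
#' total increase 0.6-3x of baseline; class II total decay 40-90%; class
#' III 5-20% slow decay to a breakpoint drawn in 900-1100 min, then a drop
#' to 2-30% of baseline by batch end; steady features have no drift.
#'
#' @param n_features Number of features.
#' @param class_counts Named integer vector over `I`, `II`, `III`, `steady`,
#'   summing to `n_features`. Default: proportional to the reference batch
#'   composition 17/95/37/45 (exactly those counts at `n_features = 194`).
#' @param fold_changes `NULL` (all 1), or a numeric vector of
#'   treated/control ratios -- either named by feature id (`F001`, ...) or
#'   of length `n_features`.
#' @param class_override,amplitude_override Optional named vectors (by
#'   feature id) pinning the kinetics class and/or drift amplitude of
#'   specific features, e.g. to plant a differential feature on a strongly
#'   decaying derivative. Overrides are applied after the random class and
#'   amplitude draws, so the rest of the batch is unchanged for a given
#'   seed.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 disables noise).
#' @param seed Integer seed; fixed seed gives a bit-identical batch.
#' @param schedule Optional schedule tibble; default [make_schedule()] with
#'   the same seed.
#' @param rt_range Retention-time range (min) for the fake t_R draws.
#' @return A list of class `rcc_batch`: `features` (wide tibble), `schedule`
#'   and `truth` (per-feature ground truth: compound, formulas, kinetics
#'   class and parameters, baseline, fold change, direction).
#' @export
generate_batch <- function(n_features = 194,
                           class_counts = NULL,
                           fold_changes = NULL, noise_cv = 0.05, seed = 1L,
                           schedule = NULL, rt_range = c(2, 14),
                           class_override = NULL, amplitude_override = NULL) {
  if (is.null(class_counts)) class_counts <- .default_class_counts(n_features)
  stopifnot(sum(class_counts) == n_features)
  if (is.null(schedule)) {
    schedule <- make_schedule(seed = seed)
  } else {
    schedule <- validate_schedule(schedule)
  }
  ids <- sprintf("F%03d", seq_len(n_features))
  fc <- rep(1, n_features)
  names(fc) <- ids
  if (!is.null(fold_changes)) {
    stopifnot(is.numeric(fold_changes), all(fold_changes > 0))
    if (is.null(names(fold_changes))) {
      stopifnot(length(fold_changes) == n_features)
      fc[] <- fold_changes
    } else {
      bad <- setdiff(names(fold_changes), ids)
      if (length(bad) > 0) {
        stop("fold_changes names not in batch: ", paste(bad, collapse = ", "),
          call. = FALSE
        )
      }
      fc[names(fold_changes)] <- fold_changes
    }
  }

  t_end <- max(schedule$time_min)
  withr::with_seed(seed, {
    classes <- sample(rep(names(class_counts), class_counts))
    reg <- rcc_registry()
    pool_idx <- sample.int(nrow(reg), n_features, replace = TRUE)
    rcc_formula <- reg$rcc_formula[pool_idx]
    compound <- reg$compound[pool_idx]
    cation <- derivative_from_rcc(rcc_formula)
    calc_mz <- monoisotopic_mass(cation, charge = 1L)
    obs_mz <- calc_mz * (1 + stats::runif(n_features, -2e-6, 2e-6))
    rt <- stats::runif(n_features, rt_range[1], rt_range[2])
    baseline <- 10^stats::runif(n_features, 5, 8)
    amplitude <- dplyr::case_when(
      classes == "I" ~ stats::runif(n_features, 0.6, 3),
      classes == "II" ~ stats::runif(n_features, 0.4, 0.9),
      classes == "III" ~ stats::runif(n_features, 0.05, 0.2),
      TRUE ~ 0
    )
    breakpoint <- ifelse(classes == "III", stats::runif(n_features, 900, 1100), NA_real_)
    end_frac <- ifelse(classes == "III", stats::runif(n_features, 0.02, 0.3), NA_real_)
    if (!is.null(class_override)) {
      stopifnot(all(names(class_override) %in% ids))
      classes[match(names(class_override), ids)] <- class_override
    }
    if (!is.null(amplitude_override)) {
      stopifnot(all(names(amplitude_override) %in% ids))
      amplitude[match(names(amplitude_override), ids)] <- amplitude_override
    }

    sdlog <- sqrt(log(1 + noise_cv^2))
    eff <- rbind(
      qc = (1 + fc) / 2, # pooled QC sees the average of both groups
      control = rep(1, n_features),
      treated = fc
    )
    intens <- matrix(NA_real_,
      nrow = n_features, ncol = nrow(schedule),
      dimnames = list(ids, schedule$run_id)
    )
    for (i in seq_len(n_features)) {
      g <- .drift_curve(
        classes[i], amplitude[i], breakpoint[i], end_frac[i], t_end
      )
      mu <- baseline[i] * g(schedule$time_min) * eff[schedule$class, i]
      noise <- if (noise_cv > 0) {
        exp(stats::rnorm(nrow(schedule), -sdlog^2 / 2, sdlog))
      } else {
        rep(1, nrow(schedule))
      }
      intens[i, ] <- mu * noise
    }

    features <- tibble::as_tibble(cbind(
      tibble::tibble(
        feature_id = ids, rt = rt, mz = obs_mz, composition = cation
      ),
      tibble::as_tibble(intens)
    ))
    truth <- tibble::tibble(
      feature_id = ids,
      compound = compound,
      rcc_formula = rcc_formula,
      cation_formula = cation,
      kinetics_class = classes,
      amplitude = amplitude,
      breakpoint = breakpoint,
      end_frac = end_frac,
      baseline = baseline,
      fold_change = pmax(fc, 1 / fc),
      direction = dplyr::case_when(fc > 1 ~ "up", fc < 1 ~ "down", TRUE ~ "none"),
      treated_ratio = unname(fc),
      noise_cv = noise_cv
    )
    structure(
      list(features = features, schedule = schedule, truth = truth),
      class = "rcc_batch"
    )
  })
}

#' @export
print.rcc_batch <- function(x, ...) {
  cat(
    "<rcc_batch>", nrow(x$features), "features x", nrow(x$schedule), "runs (",
    sum(x$schedule$class == "qc"), "QCs ) | planted classes:",
    paste(names(table(x$truth$kinetics_class)),
      table(x$truth$kinetics_class),
      sep = ":", collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' Write a synthetic batch to disk
#'
#' Emits exactly the formats the readers consume: `features.tsv`,
#' `schedule.csv`, `ground_truth.tsv` and `spectra.mgf` (one synthetic
#' MS/MS spectrum per distinct planted RCC).
#'
#' @param batch An `rcc_batch`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_batch <- function(batch, dir) {
  stopifnot(inherits(batch, "rcc_batch"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(batch$features, file.path(dir, "features.tsv"))
  write_schedule(batch$schedule, file.path(dir, "schedule.csv"))
  readr::write_tsv(batch$truth, file.path(dir, "ground_truth.tsv"))
  uniq <- unique(batch$truth$rcc_formula)
  specs <- lapply(uniq, function(f) synth_ms2(f, title = f))
  write_mgf(specs, file.path(dir, "spectra.mgf"))
  invisible(dir)
}

#' Synthesize an MS/MS spectrum of a CHH derivative
#'
#' Builds the fragmentation pattern expected of a hydrazone derivative: the
#' two diagnostic coumarin ions at m/z 244.1 and 262.1 plus the precursor
#' minus each requested neutral loss.
#'
#' @param rcc Neutral RCC formula string.
#' @param losses Character subset of the built-in loss table
#'   (`"H2O"`, `"NH2"`, `"N2H4"`, `"CO2"`, `"CH2O2"`).
#' @param title Spectrum title.
#' @return An [ms2_spectrum()].
#' @examples
#' synth_ms2("C3H6O3", losses = "H2O")
#' @export
synth_ms2 <- function(rcc, losses = "H2O", title = "") {
  precursor <- monoisotopic_mass(derivative_from_rcc(rcc), charge = 1L)
  tab <- .neutral_losses()
  bad <- setdiff(losses, tab$loss)
  if (length(bad) > 0) {
    stop("Unknown neutral loss(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  loss_mz <- precursor - tab$loss_mass[match(losses, tab$loss)]
  ms2_spectrum(
    precursor_mz = precursor,
    mz = c(.diagnostic_ions, loss_mz),
    intensity = c(100, 40, rep(60, length(loss_mz))),
    title = title
  )
}
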