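# Functional-assay computations: phosphate standard curve, pyrophosphatase
# specific activity, percent-of-control summaries, and galactolytic capacity
# from extracellular-acidification (ECAR) traces.

ECAR_PHASES <- c("baseline", "galactose", "oligomycin", "2DG")

#' Fit the phosphate standard curve
#'
#' Ordinary least-squares line `absorbance = slope * nmol + intercept` over
#' standard wells spanning the assay's phosphate range (0.075--5 nmol,
#' absorbance read at 620 nm after molybdate colour development).
#'
#' @param points A data frame with columns `nmol` (phosphate amount) and
#'   `absorbance`, at least 3 points.
#' @return A `standard_curve` list: `slope` (absorbance per nmol),
#'   `intercept`, `r_squared`, `residuals`, `points`.
#' @examples
#' fit_standard_curve(data.frame(nmol = c(0.075, 1, 5),
#'                               absorbance = c(0.065, 0.25, 1.05)))
#' @export
fit_standard_curve <- function(points) {
  if (!all(c("nmol", "absorbance") %in% names(points))) {
    rlang::abort("`points` needs columns `nmol` and `absorbance`.")
  }
  if (nrow(points) < 3) {
    rlang::abort("At least 3 standard-curve points are required.")
  }
  fit <- stats::lm(absorbance ~ nmol, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    rlang::abort("Invalid standard curve: non-positive slope.")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$absorbance - mean(points$absorbance))^2)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
         residuals = unname(stats::residuals(fit)),
         points = tibble::as_tibble(points[, c("nmol", "absorbance")])),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> absorbance = ", signif(x$slope, 4), " * nmol + ",
      signif(x$intercept, 4), "  (R^2 = ", signif(x$r_squared, 4), ", n = ",
      nrow(x$points), ")\n", sep = "")
  invisible(x)
}

#' Pyrophosphatase specific activity from end-point absorbance
#'
#' Converts a blank-corrected 620 nm absorbance into phosphate released via
#' the standard curve and normalises by incubation time and protein amount:
#' `Pi_nmol = (A_sample - A_blank - intercept) / slope`;
#' `activity = Pi_nmol / (incubation_min * protein_mg)` in
#' nmol Pi / min / mg protein. Negative activities (absorbance below blank)
#' are reported as-is and flagged, never clamped.
#'
#' @param sample_absorbance,blank_absorbance Absorbances at 620 nm
#'   (vectorised over samples; the blank is the 0 mM PPi condition).
#' @param curve A `standard_curve`, see [fit_standard_curve()].
#' @param incubation_min Incubation time in minutes (> 0).
#' @param protein_mg Total protein in mg (> 0).
#' @return Numeric vector of specific activities with attribute `flagged`
#'   (logical, `TRUE` where the activity is negative).
#' @examples
#' cv <- fit_standard_curve(data.frame(nmol = c(0, 1, 5),
#'                                     absorbance = c(0, 0.2, 1.0)))
#' specific_activity(0.4, 0, cv, incubation_min = 10, protein_mg = 0.05)
#' @export
specific_activity <- function(sample_absorbance, blank_absorbance, curve,
                              incubation_min, protein_mg) {
  if (any(incubation_min <= 0)) rlang::abort("`incubation_min` must be > 0.")
  if (any(protein_mg <= 0)) rlang::abort("`protein_mg` must be > 0.")
  pi_nmol <- (sample_absorbance - blank_absorbance - curve$intercept) /
    curve$slope
  activity <- pi_nmol / (incubation_min * protein_mg)
  attr(activity, "flagged") <- activity < 0
  activity
}

#' Express a test value as a percentage of the control mean
#'
#' @param test_value Numeric (vectorised) value for the test condition.
#' @param control_values Numeric vector (>= 1 value) for the controls; their
#'   mean must be non-zero.
#' @return `100 * test_value / mean(control_values)`.
#' @examples
#' percent_of_control(0.21, 1.03)   # 20.4 %
#' @export
percent_of_control <- function(test_value, control_values) {
  if (length(control_values) < 1) {
    rlang::abort("At least one control value is required.")
  }
  m <- mean(control_values)
  if (!is.finite(m) || m == 0) rlang::abort("Control mean must be non-zero.")
  100 * test_value / m
}

validate_ecar_trace <- function(trace) {
  if (!all(c("phase", "ecar") %in% names(trace))) {
    rlang::abort("An ECAR trace needs columns `phase` and `ecar`.")
  }
  bad <- setdiff(unique(trace$phase), ECAR_PHASES)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown ECAR phase(s): ", paste(bad, collapse = ", ")))
  }
  invisible(trace)
}

phase_summary <- function(trace, phase, reducer) {
  x <- trace$ecar[trace$phase == phase]
  if (length(x) == 0) {
    rlang::abort(paste0("ECAR trace is missing the ", phase, " phase."))
  }
  if (reducer == "mean") mean(x) else x[length(x)]
}

#' Galactolytic capacity from an extracellular-acidification trace
#'
#' The galactose analogue of glycolytic capacity in the flux stress test:
#' the acidification attained after blocking mitochondrial ATP synthesis
#' minus the non-galactolytic background remaining after blocking the
#' pathway, i.e. `mean(ECAR over the oligomycin-phase cycles) - mean(ECAR
#' over the post-2DG cycles)`, in mpH/min.
#'
#' @param trace A data frame with columns `phase` (one of `baseline`,
#'   `galactose`, `oligomycin`, `2DG`) and `ecar` (mpH/min); the oligomycin
#'   and 2DG phases must be present.
#' @param reducer Phase summary: `"mean"` of the phase's cycles (default) or
#'   `"last"` point of the phase.
#' @return Galactolytic capacity in mpH/min.
#' @examples
#' tr <- data.frame(phase = rep(c("oligomycin", "2DG"), each = 4),
#'                  ecar = c(30, 32, 31, 31, 5, 5, 6, 4))
#' galactolytic_capacity(tr)   # 31 - 5 = 26
#' @export
galactolytic_capacity <- function(trace, reducer = c("mean", "last")) {
  reducer <- match.arg(reducer)
  validate_ecar_trace(trace)
  phase_summary(trace, "oligomycin", reducer) -
    phase_summary(trace, "2DG", reducer)
}

#' Normalise an ECAR trace to percent of baseline
#'
#' Divides every cycle's ECAR by the baseline-phase mean and scales to
#' percent, so the baseline maps to 100%. The baseline mean is stored as
#' attribute `baseline_mean` for de-normalisation.
#'
#' @param trace A data frame with columns `phase` and `ecar`; the baseline
#'   phase must be present with positive mean.
#' @return The trace with `ecar` replaced by percent-of-baseline values.
#' @export
normalize_ecar_percent <- function(trace) {
  validate_ecar_trace(trace)
  base <- trace$ecar[trace$phase == "baseline"]
  if (length(base) == 0) {
    rlang::abort("ECAR trace is missing the baseline phase.")
  }
  m <- mean(base)
  if (m <= 0) rlang::abort("Baseline ECAR mean must be positive.")
  out <- trace
  out$ecar <- trace$ecar / m * 100
  attr(out, "baseline_mean") <- m
  out
}

#' Undo percent-of-baseline ECAR normalisation
#'
#' @param trace A trace returned by [normalize_ecar_percent()] (carrying the
#'   `baseline_mean` attribute), or any percent trace plus an explicit
#'   `baseline_mean`.
#' @param baseline_mean The raw baseline mean used for normalisation.
#' @return The trace with `ecar` back on the raw mpH/min scale.
#' @export
denormalize_ecar <- function(trace, baseline_mean = attr(trace, "baseline_mean")) {
  if (is.null(baseline_mean)) {
    rlang::abort("`baseline_mean` is required to de-normalise.")
  }
  out <- trace
  out$ecar <- trace$ecar / 100 * baseline_mean
  attr(out, "baseline_mean") <- NULL
  out
}

#' Read a plate-reader absorbance table
#'
#' TSV with one well per row: `well`, `role` (`standard`, `blank` or
#' `sample`), `sample_id`, `ppi_mM`, `nmol` (phosphate amount, standards
#' only), `absorbance`, `protein_mg`, `minutes`.
#'
#' @param path Path to the plate TSV.
#' @return A tibble of wells.
#' @export
read_plate <- function(path) {
  plate <- readr::read_tsv(path, col_types = readr::cols(
    well = "c", role = "c", sample_id = "c", ppi_mM = "d", nmol = "d",
    absorbance = "d", protein_mg = "d", minutes = "d"
  ), progress = FALSE)
  if (!all(plate$role %in% c("standard", "blank", "sample"))) {
    rlang::abort("Plate roles must be standard/blank/sample.")
  }
  plate
}

#' Read an extracellular-acidification trace table
#'
#' TSV with one measuring point per row: `well`, `phase`, `cycle`,
#' `timepoint_min`, `ecar`.
#'
#' @param path Path to the flux TSV.
#' @return A tibble of measuring points.
#' @export
read_flux <- function(path) {
  trace <- readr::read_tsv(path, col_types = readr::cols(
    well = "c", phase = "c", cycle = "i", timepoint_min = "d", ecar = "d"
  ), progress = FALSE)
  validate_ecar_trace(trace)
  trace
}

#' Per-condition pyrophosphatase activities from a plate table
#'
#' Fits the standard curve from the plate's standard wells, takes the mean
#' absorbance of the blank (0 mM PPi) wells of each sample as its blank, and
#' summarises [specific_activity()] per (sample, PPi concentration):
#' replicate mean, SEM and n, with a flag when any replicate went negative.
#'
#' @param plate A plate tibble, see [read_plate()].
#' @return A list with `curve` (the fitted `standard_curve`) and
#'   `activities`, a tibble with one row per (sample_id, ppi_mM).
#' @export
ppa_activity_table <- function(plate) {
  curve <- fit_standard_curve(plate[plate$role == "standard", ])
  samples <- plate[plate$role %in% c("sample", "blank"), ]
  out <- samples |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      blank <- mean(d$absorbance[d$role == "blank"])
      if (!is.finite(blank)) {
        rlang::abort(paste0("No blank (0 mM PPi) well for sample ",
                            key$sample_id))
      }
      d <- d[d$role == "sample", ]
      act <- specific_activity(d$absorbance, blank, curve, d$minutes,
                               d$protein_mg)
      tibble::tibble(ppi_mM = d$ppi_mM, activity = as.numeric(act)) |>
        dplyr::group_by(.data$ppi_mM) |>
        dplyr::summarise(
          n_replicates = dplyr::n(),
          sem = stats::sd(.data$activity) / sqrt(dplyr::n()),
          flagged = any(.data$activity < 0),
          activity = mean(.data$activity),
          .groups = "drop"
        )
    }) |>
    dplyr::ungroup()
  list(curve = curve, activities = out)
}
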