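# Synthetic-data generator: DIMS cohorts with a known truth table, plus
# plate-reader and extracellular-flux tables, so that every pipeline stage
# is testable without instrument data.

#' Specification of a synthetic DIMS cohort
#'
#' Captures the acquisition design being emulated: 30 within-run control DBS
#' samples plus the family samples (two affected probands and one
#' heterozygous carrier), each injected in triplicate with positive/negative
#' polarity switching over m/z 70--600. Intensities carry base-10 lognormal
#' noise; observed m/z carries Gaussian ppm jitter; uniform decoy peaks model
#' unannotated signal; chosen metabolites are spiked in the probands by a
#' fold-change over the control median.
#'
#' @param n_controls Number of within-run control samples (default 30).
#' @param proband_roles Named character vector of non-control samples and
#'   their roles (default two `affected` siblings and one `carrier`).
#' @param spikes A data frame with columns `metabolite_id` and `fold_change`
#'   (> 1): metabolites elevated in every `affected` sample.
#' @param sigma_log10 SD of the per-sample base-10 lognormal intensity noise
#'   (default 0.1).
#' @param ppm_jitter_sd SD of the Gaussian m/z jitter in ppm (default 1.5).
#' @param n_decoy_peaks Unannotated decoy peaks per injection and polarity
#'   (default 200), uniform over the scan range.
#' @param adduct_presence_prob Probability that a non-primary (salt) adduct
#'   of a metabolite is present in a sample (default 0.5); the primary
#'   adducts `[M+H]+` and `[M-H]-` are always present.
#' @param seed Integer seed; a fixed seed makes the generated cohort
#'   byte-identical across runs.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_controls = 30,
                        proband_roles = c(II.1 = "affected",
                                          II.3 = "affected",
                                          I.1 = "carrier"),
                        spikes = NULL,
                        sigma_log10 = 0.1,
                        ppm_jitter_sd = 1.5,
                        n_decoy_peaks = 200,
                        adduct_presence_prob = 0.5,
                        seed = 1L) {
  if (n_controls < 2) rlang::abort("`n_controls` must be >= 2.")
  if (!is.null(spikes)) {
    if (!all(c("metabolite_id", "fold_change") %in% names(spikes))) {
      rlang::abort("`spikes` needs columns metabolite_id and fold_change.")
    }
    if (any(spikes$fold_change <= 0)) {
      rlang::abort("`fold_change` must be positive.")
    }
  }
  structure(
    list(n_controls = n_controls, proband_roles = proband_roles,
         spikes = spikes, sigma_log10 = sigma_log10,
         ppm_jitter_sd = ppm_jitter_sd, n_decoy_peaks = n_decoy_peaks,
         adduct_presence_prob = adduct_presence_prob, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic DIMS cohort with known ground truth
#'
#' Every endogenous metabolite of the reference emits its polarity-matched
#' adduct peaks (primary adducts always, salt adducts with probability
#' `adduct_presence_prob` per sample, restricted to the scan range) in each
#' of 3 injections x 2 polarities per sample. The planted per-sample summed
#' intensity of a metabolite is its cohort baseline times base-10 lognormal
#' noise; in `affected` samples, spiked metabolites are planted at the
#' control median times the fold-change. The planted intensity is split over
#' the present adducts with fixed weights, so summing matched adducts and
#' averaging injections recovers it exactly when jitter and noise are zero.
#' Decoy peaks are uniform over the scan range. Output is deterministic
#' under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param reference Metabolite reference, see [load_reference()].
#' @return A list with `peaks` (tibble in the [read_peaklists()] schema),
#'   `roles` (tibble `sample_id`, `role`), `truth` (tibble `metabolite_id`,
#'   `sample_id`, `planted_intensity`) and `spec`.
#' @export
generate_cohort <- function(spec, reference) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$spikes)) {
    unknown <- setdiff(spec$spikes$metabolite_id, reference$metabolite_id)
    if (length(unknown) > 0) {
      rlang::abort(paste0("Spike metabolite_id not in reference: ",
                          paste(unknown, collapse = ", ")))
    }
    endo_ids <- reference$metabolite_id[reference$origin_class == "endogenous"]
    not_emitting <- setdiff(spec$spikes$metabolite_id, endo_ids)
    if (length(not_emitting) > 0) {
      rlang::abort(paste0("Only endogenous metabolites emit peaks; cannot ",
                          "spike: ", paste(not_emitting, collapse = ", ")))
    }
  }
  with_seed(spec$seed, {
    adducts <- default_adducts()
    emit <- reference[reference$origin_class == "endogenous", ]
    emit <- emit[order(emit$metabolite_id), ]
    n_met <- nrow(emit)
    controls <- sprintf("C%02d", seq_len(spec$n_controls))
    roles <- tibble::tibble(
      sample_id = c(controls, names(spec$proband_roles)),
      role = c(rep("control", spec$n_controls), unname(spec$proband_roles))
    )
    n_samp <- nrow(roles)

    # cohort baselines: per-metabolite typical summed intensity (arbitrary
    # units; real DBS baselines are unknowable, so a wide lognormal is used)
    baseline <- 10^stats::rnorm(n_met, mean = 5, sd = 0.5)

    # planted per-sample intensities (metabolites x samples)
    planted <- baseline * 10^matrix(
      stats::rnorm(n_met * n_samp, 0, spec$sigma_log10),
      nrow = n_met
    )
    dimnames(planted) <- list(emit$metabolite_id, roles$sample_id)
    if (!is.null(spec$spikes)) {
      affected <- roles$sample_id[roles$role == "affected"]
      for (k in seq_len(nrow(spec$spikes))) {
        m <- spec$spikes$metabolite_id[k]
        planted[m, affected] <-
          stats::median(planted[m, controls]) * spec$spikes$fold_change[k]
      }
    }

    # adducts in scan range per metabolite; weights: primary 1, salt 0.3
    theo <- tibble::tibble(
      met = rep(seq_len(n_met), each = nrow(adducts)),
      label = rep(adducts$label, times = n_met),
      polarity = rep(adducts$polarity, times = n_met),
      mz = rep(emit$neutral_mass, each = nrow(adducts)) +
        rep(adducts$mass_shift, times = n_met)
    )
    theo <- theo[theo$mz >= SCAN_RANGE[1] & theo$mz <= SCAN_RANGE[2], ]
    theo$primary <- theo$label %in% c("[M+H]+", "[M-H]-")
    theo$weight <- ifelse(theo$primary, 1, 0.3)

    out <- vector("list", n_samp)
    for (s in seq_len(n_samp)) {
      # salt-adduct presence is decided per (metabolite, sample) so the
      # injection mean equals the planted intensity
      present <- theo$primary |
        stats::runif(nrow(theo)) < spec$adduct_presence_prob
      th <- theo[present, ]
      wsum <- rowsum(th$weight, th$met)
      w <- th$weight / wsum[as.character(th$met), 1]
      sp <- tibble::tibble(
        polarity = th$polarity, mz = th$mz,
        intensity = w * planted[th$met, s]
      )
      inj <- vector("list", 3)
      for (j in 1:3) {
        jittered <- sp$mz *
          (1 + stats::rnorm(nrow(sp), 0, spec$ppm_jitter_sd) * 1e-6)
        keep <- jittered >= SCAN_RANGE[1] & jittered <= SCAN_RANGE[2]
        signal <- tibble::tibble(
          polarity = sp$polarity[keep], mz = jittered[keep],
          intensity = sp$intensity[keep]
        )
        decoys <- tibble::tibble(
          polarity = rep(c("negative", "positive"),
                         each = spec$n_decoy_peaks),
          mz = stats::runif(2 * spec$n_decoy_peaks,
                            SCAN_RANGE[1], SCAN_RANGE[2]),
          intensity = 10^stats::rnorm(2 * spec$n_decoy_peaks, 4, 0.5)
        )
        both <- dplyr::bind_rows(signal,
                                 if (spec$n_decoy_peaks > 0) decoys)
        both$sample_id <- roles$sample_id[s]
        both$injection <- j
        inj[[j]] <- both
      }
      out[[s]] <- dplyr::bind_rows(inj)
    }
    peaks <- dplyr::bind_rows(out)
    peaks <- peaks[, c("sample_id", "injection", "polarity", "mz", "intensity")]
    peaks <- dplyr::arrange(peaks, .data$sample_id, .data$injection,
                            .data$polarity, .data$mz)
    truth <- tibble::tibble(
      metabolite_id = rep(rownames(planted), times = n_samp),
      sample_id = rep(colnames(planted), each = n_met),
      planted_intensity = as.vector(planted)
    )
    list(peaks = peaks, roles = roles, truth = truth, spec = spec)
  })
}

#' Generate a synthetic plate-reader table with known activities
#'
#' Emulates the colorimetric pyrophosphatase assay: standard-curve wells
#' spanning 0.075--5 nmol phosphate with `absorbance = intercept + slope *
#' nmol + noise`; for each activity row, a 0 mM PPi blank well at the buffer
#' background and sample wells at `background + intercept + slope *
#' (activity * minutes * protein_mg) + noise`, so [specific_activity()]
#' against the fitted curve and the blank recovers the planted activity
#' exactly when `noise_sd = 0`.
#'
#' @param activities A data frame with columns `sample_id`, `ppi_mM`,
#'   `activity` (nmol Pi/min/mg), `protein_mg`, `minutes` and optionally
#'   `n_replicates` (default 3).
#' @param slope,intercept True standard-curve parameters (slope > 0).
#' @param background Buffer background absorbance of the assay wells
#'   (default 0.02).
#' @param noise_sd SD of Gaussian absorbance noise (default 0).
#' @param seed Integer seed.
#' @return A plate tibble in the [read_plate()] schema.
#' @export
generate_plate <- function(activities, slope = 0.2, intercept = 0.05,
                           background = 0.02, noise_sd = 0, seed = 1L) {
  if (slope <= 0) rlang::abort("`slope` must be positive.")
  if (!"n_replicates" %in% names(activities)) activities$n_replicates <- 3L
  with_seed(seed, {
    std_nmol <- c(0.075, 0.15, 0.3, 0.625, 1.25, 2.5, 5)
    std <- tibble::tibble(
      well = sprintf("S%02d", seq_along(std_nmol)), role = "standard",
      sample_id = NA_character_, ppi_mM = NA_real_, nmol = std_nmol,
      absorbance = intercept + slope * std_nmol +
        stats::rnorm(length(std_nmol), 0, noise_sd),
      protein_mg = NA_real_, minutes = NA_real_
    )
    rows <- vector("list", nrow(activities))
    widx <- 0L
    for (k in seq_len(nrow(activities))) {
      a <- activities[k, ]
      pi_nmol <- a$activity * a$minutes * a$protein_mg
      nrep <- a$n_replicates
      widx <- widx + 1L
      blank <- tibble::tibble(
        well = sprintf("B%02d", widx), role = "blank",
        sample_id = a$sample_id, ppi_mM = 0, nmol = NA_real_,
        absorbance = background + stats::rnorm(1, 0, noise_sd),
        protein_mg = a$protein_mg, minutes = a$minutes
      )
      wells <- tibble::tibble(
        well = sprintf("W%02d.%d", widx, seq_len(nrep)), role = "sample",
        sample_id = a$sample_id, ppi_mM = a$ppi_mM, nmol = NA_real_,
        absorbance = background + intercept + slope * pi_nmol +
          stats::rnorm(nrep, 0, noise_sd),
        protein_mg = a$protein_mg, minutes = a$minutes
      )
      rows[[k]] <- dplyr::bind_rows(blank, wells)
    }
    dplyr::bind_rows(std, dplyr::bind_rows(rows))
  })
}

#' Generate a synthetic extracellular-acidification trace
#'
#' Four phases (baseline, galactose injection, oligomycin injection, 2-DG
#' injection) of `n_cycles` measuring points each, one cycle every 9 minutes
#' (2 min mixing + 2 min waiting + 5 min measuring), Gaussian noise around
#' the supplied phase means. Deterministic under `seed`.
#'
#' @param phase_means Numeric vector of length 4 with the true mean ECAR
#'   (mpH/min) of the phases, in assay order.
#' @param noise_sd SD of Gaussian ECAR noise (default 0).
#' @param n_cycles Measuring points per phase (default 4).
#' @param seed Integer seed.
#' @param well Well label (default "A1").
#' @return A trace tibble in the [read_flux()] schema.
#' @export
generate_flux <- function(phase_means, noise_sd = 0, n_cycles = 4, seed = 1L,
                          well = "A1") {
  if (length(phase_means) != 4) {
    rlang::abort("`phase_means` must have length 4 (one mean per phase).")
  }
  with_seed(seed, {
    phases <- rep(ECAR_PHASES, each = n_cycles)
    cycle <- rep(seq_len(n_cycles), times = 4)
    idx <- seq_along(phases)
    tibble::tibble(
      well = well, phase = phases, cycle = cycle,
      timepoint_min = idx * 9,
      ecar = rep(phase_means, each = n_cycles) +
        stats::rnorm(length(idx), 0, noise_sd)
    )
  })
}

#' Write a generated cohort to peak-list, roles and truth TSVs
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_peaklists(cohort$peaks, file.path(dir, "peaks.tsv"))
  readr::write_tsv(cohort$roles, file.path(dir, "roles.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
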