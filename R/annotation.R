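# Peak-to-metabolite annotation: ppm-window matching of observed m/z against
# theoretical adduct masses, isobar grouping, and adduct-intensity summing.

# all (metabolite, adduct) theoretical m/z rows for one polarity (or both)
theoretical_mz_table <- function(reference, adducts = default_adducts(),
                                 polarity = NULL) {
  if (nrow(reference) == 0) rlang::abort("Empty metabolite reference.")
  if (!is.null(polarity)) {
    adducts <- adducts[adducts$polarity %in% polarity, , drop = FALSE]
  }
  theo <- tibble::tibble(
    metabolite_id  = rep(reference$metabolite_id, each = nrow(adducts)),
    adduct         = rep(adducts$label, times = nrow(reference)),
    polarity       = rep(adducts$polarity, times = nrow(reference)),
    theoretical_mz = rep(reference$neutral_mass, each = nrow(adducts)) +
      rep(adducts$mass_shift, times = nrow(reference))
  )
  theo[order(theo$theoretical_mz), ]
}

# indices of (observed, theoretical) pairs with |obs - theo| / theo * 1e6 <=
# ppm_tol; theo must be sorted ascending. Interval search narrows candidates,
# the exact ppm inequality decides.
match_mz_window <- function(obs, theo, ppm_tol) {
  if (length(theo) == 0 || length(obs) == 0) {
    return(list(obs_idx = integer(), theo_idx = integer()))
  }
  delta <- ppm_tol * 1e-6
  lo <- theo * (1 - delta)
  hi <- theo * (1 + delta)
  first <- findInterval(obs, hi, left.open = TRUE)  # count of hi < obs
  last <- findInterval(obs, lo)                     # count of lo <= obs
  n <- pmax(last - first, 0L)
  obs_idx <- rep(seq_along(obs), n)
  theo_idx <- sequence(n, from = first + 1L)
  keep <- abs(obs[obs_idx] - theo[theo_idx]) / theo[theo_idx] * 1e6 <= ppm_tol
  list(obs_idx = obs_idx[keep], theo_idx = theo_idx[keep])
}

#' Match observed peaks to metabolite adduct masses
#'
#' A peak matches metabolite `m` under adduct `a` iff
#' `|observed_mz - theoretical_mz| / theoretical_mz * 1e6 <= ppm_tol`, with
#' the theoretical m/z in the denominator. A peak may match several
#' metabolites and a metabolite may collect several adduct peaks; only
#' adducts of the peak list's polarity are considered.
#'
#' @param peaks A tibble of peaks of a single polarity (columns `mz`,
#'   `intensity`, `polarity`).
#' @param reference Metabolite reference, see [load_reference()].
#' @param adducts Adduct table, see [default_adducts()].
#' @param ppm_tol Symmetric relative mass tolerance in parts per million
#'   (default 5).
#' @return A tibble of matches: `metabolite_id`, `adduct`, `mz`, `intensity`,
#'   `theoretical_mz`, `ppm_error` (signed).
#' @export
match_peaks <- function(peaks, reference, adducts = default_adducts(),
                        ppm_tol = 5) {
  if (nrow(reference) == 0) rlang::abort("Empty metabolite reference.")
  if (!is.numeric(ppm_tol) || ppm_tol <= 0) {
    rlang::abort("`ppm_tol` must be positive.")
  }
  pol <- unique(peaks$polarity)
  if (length(pol) > 1) {
    rlang::abort("`peaks` must contain a single polarity.")
  }
  theo <- theoretical_mz_table(reference, adducts, polarity = pol)
  hit <- match_mz_window(peaks$mz, theo$theoretical_mz, ppm_tol)
  tibble::tibble(
    metabolite_id  = theo$metabolite_id[hit$theo_idx],
    adduct         = theo$adduct[hit$theo_idx],
    mz             = peaks$mz[hit$obs_idx],
    intensity      = peaks$intensity[hit$obs_idx],
    theoretical_mz = theo$theoretical_mz[hit$theo_idx],
    ppm_error      = (peaks$mz[hit$obs_idx] - theo$theoretical_mz[hit$theo_idx]) /
      theo$theoretical_mz[hit$theo_idx] * 1e6
  )
}

#' Group metabolites whose adduct masses are indistinguishable
#'
#' Direct infusion resolves annotations by accurate mass alone, so
#' metabolites whose theoretical m/z agree within the ppm tolerance for every
#' shared adduct (isomers, or isobars below the tolerance) cannot be told
#' apart and are merged into one annotation group. Merging is single-linkage,
#' so near-coincident chains collapse into one group; display names are
#' joined with `" | "` in `metabolite_id` order.
#'
#' @inheritParams match_peaks
#' @return A tibble with one row per annotation group: `group_id`,
#'   `display_name`, `member_ids` (list), `n_members`, `neutral_mass`
#'   (mean of members).
#' @export
group_isobars <- function(reference, adducts = default_adducts(), ppm_tol = 5) {
  if (nrow(reference) == 0) rlang::abort("Empty metabolite reference.")
  ref <- reference[order(reference$neutral_mass), ]
  n <- nrow(ref)
  comp <- integer(n)
  comp[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      mz_a <- ref$neutral_mass[i - 1] + adducts$mass_shift
      mz_b <- ref$neutral_mass[i] + adducts$mass_shift
      within <- all(abs(mz_b - mz_a) / ((mz_a + mz_b) / 2) * 1e6 <= ppm_tol)
      comp[i] <- if (within) comp[i - 1] else comp[i - 1] + 1L
    }
  }
  groups <- lapply(split(seq_len(n), comp), function(idx) {
    members <- ref[idx, ]
    members <- members[order(members$metabolite_id), ]
    tibble::tibble(
      display_name = paste(members$name, collapse = " | "),
      member_ids   = list(members$metabolite_id),
      n_members    = nrow(members),
      neutral_mass = mean(members$neutral_mass)
    )
  })
  out <- dplyr::bind_rows(groups)
  # stable group order and ids: by the first (lowest) member id
  first_id <- purrr::map_chr(out$member_ids, 1)
  out <- out[order(first_id), ]
  out$group_id <- sprintf("AG%04d", seq_len(nrow(out)))
  out[, c("group_id", "display_name", "member_ids", "n_members", "neutral_mass")]
}

#' Sum adduct intensities into one value per annotation per sample
#'
#' For every sample and injection, the intensities of all matched adduct
#' peaks of an annotation group are summed (adducts without a matching peak
#' contribute 0); the per-sample value is then the mean (or median) over the
#' sample's triplicate injections. The result is an annotation matrix of
#' groups x samples with full per-peak provenance.
#'
#' @param samples Assembled sample runs, see [assemble_samples()].
#' @inheritParams match_peaks
#' @param reducer How triplicate injections are combined: `"mean"` (default)
#'   or `"median"`.
#' @return An `annotation_matrix` object: a list with elements `intensity`
#'   (numeric matrix, groups x samples), `groups` (see [group_isobars()]),
#'   `samples` (tibble `sample_id`, `role`), `provenance` (one row per
#'   matched peak) and the matching parameters.
#' @export
summed_intensities <- function(samples, reference, adducts = default_adducts(),
                               ppm_tol = 5, reducer = c("mean", "median")) {
  reducer <- match.arg(reducer)
  reduce_fun <- if (reducer == "mean") mean else stats::median
  groups <- group_isobars(reference, adducts, ppm_tol)
  group_of <- stats::setNames(
    rep(groups$group_id, lengths(groups$member_ids)),
    unlist(groups$member_ids)
  )
  g_index <- stats::setNames(seq_len(nrow(groups)), groups$group_id)
  mat <- matrix(0, nrow = nrow(groups), ncol = nrow(samples),
                dimnames = list(groups$group_id, samples$sample_id))
  s_index <- stats::setNames(seq_len(nrow(samples)), samples$sample_id)

  # flatten the cohort and match each polarity in one vectorised pass
  flat <- samples[, c("sample_id", "peaks")]
  flat <- tidyr::unnest(flat, "peaks")
  prov <- vector("list", 2)
  for (p in 1:2) {
    pol <- c("negative", "positive")[p]
    sub <- flat[flat$polarity == pol, ]
    if (nrow(sub) == 0) next
    theo <- theoretical_mz_table(reference, adducts, polarity = pol)
    hit <- match_mz_window(sub$mz, theo$theoretical_mz, ppm_tol)
    if (length(hit$obs_idx) == 0) next
    # a peak matching several members of one group contributes its
    # intensity once to that group's sum (counted = FALSE on duplicates)
    gi_p <- g_index[group_of[theo$metabolite_id[hit$theo_idx]]]
    counted <- !duplicated((hit$obs_idx - 1) * nrow(groups) + gi_p)
    prov[[p]] <- tibble::tibble(
      sample_id = sub$sample_id[hit$obs_idx],
      injection = sub$injection[hit$obs_idx],
      group_id = group_of[theo$metabolite_id[hit$theo_idx]],
      metabolite_id = theo$metabolite_id[hit$theo_idx],
      adduct = theo$adduct[hit$theo_idx],
      theoretical_mz = theo$theoretical_mz[hit$theo_idx],
      mz = sub$mz[hit$obs_idx],
      ppm_error = (sub$mz[hit$obs_idx] - theo$theoretical_mz[hit$theo_idx]) /
        theo$theoretical_mz[hit$theo_idx] * 1e6,
      intensity = sub$intensity[hit$obs_idx],
      counted = counted
    )
  }
  provenance <- dplyr::bind_rows(prov)

  # per-injection sums per (group, sample), then the reducer over the
  # injections each sample actually has (absent adducts contribute 0)
  inj_of <- lapply(samples$peaks, function(p) sort(unique(p$injection)))
  if (nrow(provenance) > 0) {
    cp <- provenance[provenance$counted, ]
    gi <- g_index[cp$group_id]
    si <- s_index[cp$sample_id]
    if (reducer == "mean") {
      key <- (si - 1L) * nrow(groups) + gi
      tot <- rowsum(cp$intensity, key)
      idx <- as.integer(rownames(tot))
      cell_s <- (idx - 1L) %/% nrow(groups) + 1L
      cell_g <- (idx - 1L) %% nrow(groups) + 1L
      mat[cbind(cell_g, cell_s)] <- tot[, 1] / lengths(inj_of)[cell_s]
    } else {
      # median needs the explicit per-injection values, including zeros
      for (s in seq_len(nrow(samples))) {
        injs <- inj_of[[s]]
        per_inj <- matrix(0, nrow = nrow(groups), ncol = length(injs))
        rows <- which(si == s)
        if (length(rows) > 0) {
          jj <- match(cp$injection[rows], injs)
          sums <- rowsum(cp$intensity[rows],
                         (jj - 1L) * nrow(groups) + gi[rows])
          idx <- as.integer(rownames(sums))
          per_inj[cbind((idx - 1L) %% nrow(groups) + 1L,
                        (idx - 1L) %/% nrow(groups) + 1L)] <- sums[, 1]
        }
        mat[, s] <- apply(per_inj, 1, reduce_fun)
      }
    }
  }
  if (nrow(provenance) > 0) {
    provenance <- dplyr::arrange(provenance, .data$sample_id,
                                 .data$injection, .data$group_id,
                                 .data$theoretical_mz)
  }
  structure(
    list(intensity = mat, groups = groups,
         samples = samples[, c("sample_id", "role")],
         provenance = provenance, ppm_tol = ppm_tol, reducer = reducer),
    class = "annotation_matrix"
  )
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("<annotation_matrix> ", nrow(x$intensity), " annotation groups x ",
      ncol(x$intensity), " samples (ppm_tol = ", x$ppm_tol,
      ", reducer = ", x$reducer, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.annotation_matrix <- function(x) dim(x$intensity)

# keep only the annotation groups in `keep` (logical over rows)
subset_annotation_matrix <- function(mat, keep) {
  mat$intensity <- mat$intensity[keep, , drop = FALSE]
  mat$groups <- mat$groups[keep, ]
  if (nrow(mat$provenance) > 0) {
    mat$provenance <-
      mat$provenance[mat$provenance$group_id %in% mat$groups$group_id, ]
  }
  mat
}

#' Remove annotation groups of exogenous or drug origin
#'
#' Annotation groups whose members are all of origin class `exogenous` or
#' `drug` are excluded from screening; groups mixing endogenous with
#' exogenous isomers are retained so that endogenous candidates are never
#' silently deleted.
#'
#' @param mat An `annotation_matrix`, see [summed_intensities()].
#' @param reference The metabolite reference the matrix was built from.
#' @return The filtered `annotation_matrix`.
#' @export
filter_exogenous <- function(mat, reference) {
  origin <- stats::setNames(reference$origin_class, reference$metabolite_id)
  keep <- purrr::map_lgl(mat$groups$member_ids, function(ids) {
    any(origin[ids] == "endogenous")
  })
  subset_annotation_matrix(mat, keep)
}
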