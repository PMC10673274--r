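# Shared fixtures and independent oracles for the test suite.

# exhaustive all-pairs matcher: the independent oracle for match_peaks
brute_force_match <- function(peaks, reference, adducts, ppm_tol) {
  adducts <- adducts[adducts$polarity %in% unique(peaks$polarity), ]
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(reference))) {
      for (k in seq_len(nrow(adducts))) {
        theo <- reference$neutral_mass[j] + adducts$mass_shift[k]
        ppm <- (peaks$mz[i] - theo) / theo * 1e6
        if (abs(ppm) <= ppm_tol) {
          rows[[length(rows) + 1]] <- data.frame(
            metabolite_id = reference$metabolite_id[j],
            adduct = adducts$label[k],
            mz = peaks$mz[i], intensity = peaks$intensity[i],
            theoretical_mz = theo, ppm_error = ppm
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(metabolite_id = character(), adduct = character(),
                      mz = numeric(), intensity = numeric(),
                      theoretical_mz = numeric(), ppm_error = numeric())
  }
  out[order(out$metabolite_id, out$adduct, out$mz), ]
}

# canonical sort for comparing match tables from the two routes
sort_matches <- function(m) {
  m <- as.data.frame(m)[, c("metabolite_id", "adduct", "mz", "intensity",
                            "theoretical_mz", "ppm_error")]
  m <- m[order(m$metabolite_id, m$adduct, m$mz), ]
  rownames(m) <- NULL
  m
}

# small ad-hoc reference table for unit tests
make_reference <- function(masses, origin = "endogenous",
                           pathway = NA_character_, ppi = "no",
                           prefix = "MET") {
  n <- length(masses)
  tibble::tibble(
    metabolite_id = sprintf("%s%04d", prefix, seq_len(n)),
    name = sprintf("%s %d", tolower(prefix), seq_len(n)),
    formula = NA_character_,
    neutral_mass = masses,
    pathway_map = rep_len(pathway, n),
    pathway_name = ifelse(is.na(rep_len(pathway, n)), NA_character_,
                          sprintf("Pathway of %s %d", tolower(prefix),
                                  seq_len(n))),
    origin_class = rep_len(origin, n),
    ppi_forming = rep_len(ppi, n)
  )
}

# one-sample, one-injection peak tibble
make_peaks <- function(mz, intensity = 100, sample_id = "S1", injection = 1L,
                       polarity = "negative") {
  tibble::tibble(sample_id = sample_id, injection = injection,
                 polarity = polarity, mz = mz,
                 intensity = rep_len(intensity, length(mz)))
}

# sum the per-group truth of a generated cohort, aligned to a matrix
truth_matrix <- function(cohort, mat) {
  tm <- tidyr::pivot_wider(cohort$truth, names_from = sample_id,
                           values_from = planted_intensity)
  tmx <- as.matrix(tm[, -1])
  rownames(tmx) <- tm$metabolite_id
  gm <- t(sapply(mat$groups$member_ids, function(ids) {
    ids <- intersect(ids, rownames(tmx))
    if (length(ids) == 0) return(rep(0, ncol(tmx)))
    colSums(tmx[ids, , drop = FALSE])
  }))
  colnames(gm) <- colnames(tm)[-1]
  gm[, colnames(mat$intensity), drop = FALSE]
}
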