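#' Read per-injection centroided peak lists
#'
#' Reads the canonical tab-separated peak-list exchange format: one centroided
#' peak per row with columns `sample_id`, `injection`, `polarity`, `mz`,
#' `intensity`. Peaks are grouped and sorted per (sample, injection,
#' polarity) by ascending m/z. Peaks outside the acquisition scan range
#' (m/z 70--600) are dropped with a warning; the drop count is attached as
#' attribute `n_dropped`. Reading is gzip-transparent.
#'
#' @param path Path to a TSV (optionally gz-compressed) peak-list file.
#' @return A tibble of peaks sorted by sample, injection, polarity and m/z,
#'   with attribute `n_dropped` (number of out-of-range peaks removed).
#' @seealso [write_peaklists()], [assemble_samples()]
#' @export
read_peaklists <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", injection = "i", polarity = "c",
    mz = "c", intensity = "c"
  ), progress = FALSE)
  missing <- setdiff(c("sample_id", "injection", "polarity", "mz", "intensity"),
                     names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("Peak-list file lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  mz <- suppressWarnings(as.numeric(raw$mz))
  intensity <- suppressWarnings(as.numeric(raw$intensity))
  bad <- which(is.na(mz) | is.na(intensity) | is.na(raw$injection) |
                 raw$injection < 1L |
                 !(raw$polarity %in% c("positive", "negative")) |
                 intensity < 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("Malformed peak-list row(s) at line(s) ",
                        paste(utils::head(bad, 10) + 1L, collapse = ", "),
                        " of ", path))
  }
  peaks <- tibble::tibble(
    sample_id = raw$sample_id, injection = raw$injection,
    polarity = raw$polarity, mz = mz, intensity = intensity
  )
  out_of_range <- peaks$mz < SCAN_RANGE[1] | peaks$mz > SCAN_RANGE[2]
  if (any(out_of_range)) {
    rlang::warn(paste0("Dropping ", sum(out_of_range),
                       " peak(s) outside the m/z ", SCAN_RANGE[1], "-",
                       SCAN_RANGE[2], " scan range."))
    peaks <- peaks[!out_of_range, ]
  }
  peaks <- dplyr::arrange(peaks, .data$sample_id, .data$injection,
                          .data$polarity, .data$mz)
  attr(peaks, "n_dropped") <- sum(out_of_range)
  peaks
}

#' Write per-injection peak lists
#'
#' @param peaks A peak tibble (columns `sample_id`, `injection`, `polarity`,
#'   `mz`, `intensity`).
#' @param path Output TSV path (a `.gz` suffix writes compressed).
#' @return `path`, invisibly.
#' @export
write_peaklists <- function(peaks, path) {
  cols <- c("sample_id", "injection", "polarity", "mz", "intensity")
  readr::write_tsv(peaks[, cols], path, progress = FALSE)
  invisible(path)
}

#' Assemble peak lists into sample runs with roles
#'
#' Groups per-injection peak lists into one run per sample and attaches the
#' study role of each sample (within-run `control`, `affected` proband, or
#' heterozygous `carrier`). A complete run has 3 injections x 2 polarities =
#' 6 peak lists; incomplete runs are flagged, not dropped, and are later
#' analysed with the injections present.
#'
#' @param peaks Peak tibble as returned by [read_peaklists()].
#' @param roles Either a named character vector (`c(sample_id = role)`) or a
#'   tibble with columns `sample_id` and `role`. Every sample in `peaks`
#'   must have a role, and every sample named in `roles` must have at least
#'   one peak list.
#' @return A nested tibble with one row per sample: `sample_id`, `role`,
#'   `n_peaklists`, `complete` and a `peaks` list-column.
#' @export
assemble_samples <- function(peaks, roles) {
  if (!is.data.frame(roles)) {
    roles <- tibble::tibble(sample_id = names(roles), role = unname(roles))
  }
  if (!all(roles$role %in% c("control", "affected", "carrier"))) {
    rlang::abort("roles must be one of control/affected/carrier.")
  }
  ids <- unique(peaks$sample_id)
  missing_role <- setdiff(ids, roles$sample_id)
  if (length(missing_role) > 0) {
    rlang::abort(paste0("No role given for sample(s): ",
                        paste(missing_role, collapse = ", ")))
  }
  empty <- setdiff(roles$sample_id, ids)
  if (length(empty) > 0) {
    rlang::abort(paste0("Sample(s) with zero peak lists: ",
                        paste(empty, collapse = ", ")))
  }
  nested <- tidyr::nest(peaks, peaks = -"sample_id")
  out <- dplyr::left_join(nested, roles, by = "sample_id")
  out$n_peaklists <- purrr::map_dbl(out$peaks, function(p) {
    nrow(unique(p[, c("injection", "polarity")]))
  })
  out$complete <- purrr::map_lgl(out$peaks, function(p) {
    keys <- unique(p[, c("injection", "polarity")])
    length(unique(keys$injection)) == 3L &&
      all(table(keys$polarity) == 3L) &&
      all(c("positive", "negative") %in% keys$polarity)
  })
  out <- out[, c("sample_id", "role", "n_peaklists", "complete", "peaks")]
  dplyr::arrange(out, .data$sample_id)
}
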