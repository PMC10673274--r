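# Z-score screening against within-run controls and the Table-style report
# with pathway and PPi-formation flags.

#' Z-score of a patient intensity against within-run controls
#'
#' `Z = (patient intensity - mean of control intensities) / SD of control
#' intensities`, with the sample standard deviation (n - 1 denominator) by
#' default. When the controls have zero spread the Z-score is undefined and
#' `NA` is returned with a warning, never +/-Inf.
#'
#' @param patient_intensity Numeric (vectorised): summed intensity of the
#'   patient sample(s).
#' @param control_intensities Numeric vector of length >= 2: summed
#'   intensities of the within-run control samples.
#' @param sd_method `"sample"` (n - 1, default) or `"population"` (n).
#' @return Numeric vector of Z-scores (dimensionless).
#' @examples
#' zscore(14, c(8, 10, 12))   # 2
#' @export
zscore <- function(patient_intensity, control_intensities,
                   sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  n <- length(control_intensities)
  if (n < 2) rlang::abort("At least 2 control intensities are required.")
  m <- mean(control_intensities)
  s <- stats::sd(control_intensities)
  if (sd_method == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0) {
    rlang::warn("Control SD is zero; Z-score undefined (NA).")
    return(rep(NA_real_, length(patient_intensity)))
  }
  (patient_intensity - m) / s
}

#' Per-annotation Z-score table against within-run controls
#'
#' Computes, for every annotation group, the Z-score of each non-control
#' sample against the within-run control samples of the annotation matrix,
#' together with the per-row control summary. Rows whose controls have zero
#' spread carry `NA` Z-scores (undefined), reported with a single warning.
#'
#' @param mat An `annotation_matrix`, see [summed_intensities()] /
#'   [filter_exogenous()].
#' @param sd_method Passed to [zscore()].
#' @param log10_transform If `TRUE`, intensities are `log10(x + 1)`
#'   transformed before Z-scoring. Off by default: the screening formula is
#'   defined on raw summed intensities.
#' @return A tibble with one row per annotation group: `group_id`,
#'   `display_name`, `member_ids`, `control_mean`, `control_sd`,
#'   `n_control`, then one Z column per non-control sample (named by
#'   `sample_id`).
#' @export
zscore_table <- function(mat, sd_method = c("sample", "population"),
                         log10_transform = FALSE) {
  sd_method <- match.arg(sd_method)
  x <- mat$intensity
  if (log10_transform) x <- log10(x + 1)
  is_control <- mat$samples$role == "control"
  if (sum(is_control) < 2) {
    rlang::abort("At least 2 control samples are required for Z-scoring.")
  }
  ctrl <- x[, is_control, drop = FALSE]
  other <- x[, !is_control, drop = FALSE]
  m <- rowMeans(ctrl)
  s <- apply(ctrl, 1, stats::sd)
  if (sd_method == "population") {
    s <- s * sqrt((ncol(ctrl) - 1) / ncol(ctrl))
  }
  undef <- !is.finite(s) | s == 0
  if (any(undef)) {
    rlang::warn(paste0(sum(undef), " annotation group(s) have zero control ",
                       "SD; their Z-scores are undefined (NA)."))
  }
  z <- sweep(other, 1, m, "-") / ifelse(undef, NA_real_, s)
  out <- tibble::tibble(
    group_id = mat$groups$group_id,
    display_name = mat$groups$display_name,
    member_ids = mat$groups$member_ids,
    control_mean = m, control_sd = ifelse(undef, NA_real_, s),
    n_control = ncol(ctrl)
  )
  for (j in seq_len(ncol(other))) out[[colnames(other)[j]]] <- z[, j]
  attr(out, "sample_cols") <- colnames(other)
  out
}

#' Keep annotations elevated in every designated affected individual
#'
#' Retains the rows whose Z-score is strictly greater than `threshold` in
#' all `affected_ids` (the dual-proband elevation filter). Rows with an
#' undefined (`NA`) Z-score in any affected individual are dropped.
#'
#' @param ztable A tibble with one numeric Z column per individual, e.g.
#'   from [zscore_table()] or [reported_zscores()].
#' @param affected_ids Character vector of affected individuals' sample ids;
#'   each must be a column of `ztable`.
#' @param threshold Elevation cutoff on the Z-score (default 2.0, strict
#'   comparison).
#' @return The retained rows of `ztable`.
#' @export
filter_elevated <- function(ztable, affected_ids, threshold = 2.0) {
  unknown <- setdiff(affected_ids, names(ztable))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown affected sample id(s): ",
                        paste(unknown, collapse = ", ")))
  }
  z <- as.matrix(ztable[, affected_ids, drop = FALSE])
  keep <- rowSums(z > threshold) == length(affected_ids)
  keep[is.na(keep)] <- FALSE
  ztable[keep, ]
}

#' Label retained annotations with pathways and PPi-formation flags
#'
#' Builds the final screen report: each retained annotation group is labelled
#' with the pathway map(s)/name(s) of its members (section `pathway-mapped`
#' if any member has a pathway map, else `unmapped`) and flagged `"+"` for
#' PPi formation iff any member record has `ppi_forming = yes`.
#'
#' @param retained Retained rows from [filter_elevated()]; must carry a
#'   `member_ids` list-column.
#' @param reference Metabolite reference, see [load_reference()].
#' @return A `screen_report` tibble: `compound`, the Z columns of
#'   `retained`, `affected_pathway`, `hmdb_id`, `kegg_id`, `ppi_formation`
#'   (`"+"` / `"-"`), `section`.
#' @export
annotate_pathways <- function(retained, reference) {
  if (!"member_ids" %in% names(retained)) {
    rlang::abort("`retained` must carry a `member_ids` list-column.")
  }
  idx <- stats::setNames(seq_len(nrow(reference)), reference$metabolite_id)
  per_group <- purrr::map(retained$member_ids, function(ids) {
    rec <- reference[idx[ids], ]
    maps <- unique(unlist(strsplit(rec$pathway_map[!is.na(rec$pathway_map)], ",")))
    names_ <- unique(rec$pathway_name[!is.na(rec$pathway_name)])
    list(
      kegg_id = if (length(maps)) paste(maps, collapse = ", ") else NA_character_,
      affected_pathway = if (length(names_)) paste(names_, collapse = " | ")
                         else NA_character_,
      ppi = if (any(rec$ppi_forming == "yes")) "+" else "-",
      section = if (length(maps)) "pathway-mapped" else "unmapped"
    )
  })
  zcols <- names(retained)[vapply(retained, is.numeric, logical(1))]
  zcols <- setdiff(zcols, c("control_mean", "control_sd", "n_control"))
  out <- tibble::tibble(
    compound = retained$display_name,
    member_ids = retained$member_ids
  )
  for (col in zcols) out[[col]] <- retained[[col]]
  out$affected_pathway <- purrr::map_chr(per_group, "affected_pathway")
  out$hmdb_id <- purrr::map_chr(retained$member_ids, paste, collapse = " | ")
  out$kegg_id <- purrr::map_chr(per_group, "kegg_id")
  out$ppi_formation <- purrr::map_chr(per_group, "ppi")
  out$section <- purrr::map_chr(per_group, "section")
  class(out) <- c("screen_report", class(out))
  out
}

#' Run the full dried-blood-spot screening pipeline
#'
#' Deterministic composition of the pipeline stages: assemble samples,
#' annotate and sum adduct intensities, exclude exogenous/drug annotations,
#' Z-score non-control samples against the within-run controls, keep
#' annotations elevated (Z > `threshold`) in every affected individual, and
#' label the survivors with pathways and PPi-formation flags.
#'
#' @param peaks Peak tibble, see [read_peaklists()].
#' @param reference Metabolite reference, see [load_reference()].
#' @param roles Sample roles, see [assemble_samples()].
#' @param affected_ids Sample ids of the affected individuals used by the
#'   elevation filter. Carrier samples are Z-scored and reported but never
#'   used for filtering.
#' @param ppm_tol,adducts,reducer Passed to [summed_intensities()].
#' @param threshold Passed to [filter_elevated()].
#' @param sd_method,log10_transform Passed to [zscore_table()].
#' @return A `screen_result` list: `report` (the [annotate_pathways()]
#'   table), `ztable` (full Z-score table), `matrix` (the filtered
#'   `annotation_matrix`) and `params`.
#' @export
run_screen <- function(peaks, reference, roles, affected_ids,
                       ppm_tol = 5, threshold = 2.0,
                       adducts = default_adducts(),
                       reducer = c("mean", "median"),
                       sd_method = c("sample", "population"),
                       log10_transform = FALSE) {
  reducer <- match.arg(reducer)
  sd_method <- match.arg(sd_method)
  samples <- assemble_samples(peaks, roles)
  mat <- summed_intensities(samples, reference, adducts, ppm_tol, reducer)
  mat <- filter_exogenous(mat, reference)
  ztable <- zscore_table(mat, sd_method, log10_transform)
  retained <- filter_elevated(ztable, affected_ids, threshold)
  report <- annotate_pathways(retained, reference)
  structure(
    list(report = report, ztable = ztable, matrix = mat,
         params = list(ppm_tol = ppm_tol, threshold = threshold,
                       affected_ids = affected_ids, reducer = reducer,
                       sd_method = sd_method,
                       log10_transform = log10_transform)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x$ztable), " annotation groups screened, ",
      nrow(x$report), " elevated (Z > ", x$params$threshold, " in ",
      paste(x$params$affected_ids, collapse = ", "), ")\n", sep = "")
  cat("  sections: ", sum(x$report$section == "pathway-mapped"),
      " pathway-mapped / ", sum(x$report$section == "unmapped"),
      " unmapped; PPi-forming: ", sum(x$report$ppi_formation == "+"),
      "\n", sep = "")
  invisible(x)
}
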