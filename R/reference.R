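#' Default adduct definitions for singly charged DIMS ions
#'
#' The five adduct species used for annotation: protonated/deprotonated
#' molecules plus the single sodium, potassium and chloride adducts. Mass
#' shifts are fixed constants in Da added to the neutral monoisotopic mass to
#' obtain the ion m/z (all species singly charged).
#'
#' @return A tibble with columns `label`, `polarity` (`"positive"` /
#'   `"negative"`), `mass_shift` (Da) and `charge` (+1 / -1).
#' @examples
#' default_adducts()
#' @export
default_adducts <- function() {
  tibble::tibble(
    label      = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-", "[M+Cl]-"),
    polarity   = c("positive", "positive", "positive", "negative", "negative"),
    mass_shift = c(1.007276, 22.989218, 38.963158, -1.007276, 34.968853),
    charge     = c(1L, 1L, 1L, -1L, -1L)
  )
}

#' Theoretical m/z of a metabolite adduct
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (vectorised, must be
#'   positive).
#' @param adduct Adduct label, e.g. `"[M-H]-"`.
#' @param adducts Adduct definition table, see [default_adducts()].
#' @return Numeric vector of m/z values, `neutral_mass + mass_shift`.
#' @examples
#' compute_adduct_mz(180.063388, "[M-H]-")   # galactose, deprotonated
#' @export
compute_adduct_mz <- function(neutral_mass, adduct,
                              adducts = default_adducts()) {
  if (!is.numeric(neutral_mass) || any(!is.finite(neutral_mass)) ||
      any(neutral_mass <= 0)) {
    rlang::abort("`neutral_mass` must be positive and finite.")
  }
  i <- match(adduct, adducts$label)
  if (length(i) != 1L || is.na(i)) {
    rlang::abort(paste0("Unknown adduct label: ",
                        paste(setdiff(adduct, adducts$label), collapse = ", ")))
  }
  neutral_mass + adducts$mass_shift[i]
}

.reference_cols <- c("metabolite_id", "name", "neutral_mass", "pathway_map",
                     "pathway_name", "origin_class", "ppi_forming")

#' Load a metabolite reference table
#'
#' Reads the tab-separated metabolite reference (the stand-in for an
#' HMDB/KEGG extract): one metabolite per row with accession-like id, name,
#' neutral monoisotopic mass, optional pathway map/name, origin class and
#' PPi-formation flag. Rows are validated and returned in stable order by
#' `metabolite_id`.
#'
#' @param path Path to a TSV file with a header naming at least the columns
#'   `metabolite_id`, `name`, `neutral_mass`, `pathway_map`, `pathway_name`,
#'   `origin_class`, `ppi_forming`. Empty `pathway_map` / `pathway_name`
#'   fields encode a missing pathway.
#' @return A tibble of validated metabolite records sorted by
#'   `metabolite_id`.
#' @seealso [dbs_reference()] for the packaged reference, [write_reference()].
#' @export
load_reference <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  missing <- setdiff(.reference_cols, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("Reference file lacks required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  mass <- suppressWarnings(as.numeric(raw$neutral_mass))
  bad <- which(is.na(mass) & nzchar(raw$neutral_mass) | !nzchar(raw$neutral_mass))
  if (length(bad) > 0) {
    rlang::abort(paste0("Non-numeric neutral_mass on line(s) ",
                        paste(bad + 1L, collapse = ", "),
                        " of ", path))
  }
  if (any(mass <= 0 | mass >= 2000)) {
    bad <- which(mass <= 0 | mass >= 2000)
    rlang::abort(paste0("neutral_mass outside (0, 2000) Da on line(s) ",
                        paste(bad + 1L, collapse = ", ")))
  }
  dup <- unique(raw$metabolite_id[duplicated(raw$metabolite_id)])
  if (length(dup) > 0) {
    rlang::abort(paste0("Duplicate metabolite_id: ",
                        paste(dup, collapse = ", ")))
  }
  if (!all(raw$origin_class %in% c("endogenous", "exogenous", "drug"))) {
    rlang::abort("origin_class must be one of endogenous/exogenous/drug.")
  }
  if (!all(raw$ppi_forming %in% c("yes", "no", "unknown"))) {
    rlang::abort("ppi_forming must be one of yes/no/unknown.")
  }
  ref <- tibble::tibble(
    metabolite_id = raw$metabolite_id,
    name          = raw$name,
    formula       = if ("formula" %in% names(raw)) {
      ifelse(nzchar(raw$formula), raw$formula, NA_character_)
    } else NA_character_,
    neutral_mass  = mass,
    pathway_map   = ifelse(nzchar(raw$pathway_map), raw$pathway_map, NA_character_),
    pathway_name  = ifelse(nzchar(raw$pathway_name), raw$pathway_name, NA_character_),
    origin_class  = raw$origin_class,
    ppi_forming   = raw$ppi_forming
  )
  no_map <- ref$ppi_forming == "yes" & is.na(ref$pathway_map)
  if (any(no_map)) {
    rlang::abort(paste0("ppi_forming = yes requires a pathway_map: ",
                        paste(ref$metabolite_id[no_map], collapse = ", ")))
  }
  dplyr::arrange(ref, .data$metabolite_id)
}

#' Write a metabolite reference table
#'
#' Inverse of [load_reference()]: missing pathway fields are written as empty
#' strings so that a written table re-loads field-for-field.
#'
#' @param reference A reference tibble as returned by [load_reference()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  out <- reference
  for (col in c("formula", "pathway_map", "pathway_name")) {
    if (col %in% names(out)) out[[col]] <- ifelse(is.na(out[[col]]), "", out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Packaged dried-blood-spot metabolite reference
#'
#' The bundled reference used throughout the package: the 19 metabolite
#' annotations elevated in both affected siblings of the PPA1-deficiency
#' family (neutral monoisotopic masses computed from their elemental
#' formulas), plus 50 synthetic decoy metabolites with mixed origin classes.
#' The decoys are synthetic constructs for pipeline testing, not real
#' database entries; their ids are prefixed `DECOY`.
#'
#' @return A validated reference tibble, see [load_reference()].
#' @export
dbs_reference <- function() {
  load_reference(system.file("extdata", "reference_dbs.tsv",
                             package = "metaboscreen", mustWork = TRUE))
}

#' Reported per-individual Z-scores of the PPA1-deficiency family screen
#'
#' The published screening result shipped as a fixture: 19 metabolite
#' annotations with Z-scores for the heterozygous father (I.1) and the two
#' affected siblings (II.1, II.3), together with pathway, HMDB/KEGG ids and
#' the PPi-formation flag. The table is returned in the shape expected by
#' [filter_elevated()] and [annotate_pathways()]: one Z column per
#' individual, plus a `member_ids` list-column with the HMDB accessions of
#' each annotation group.
#'
#' @return A tibble with columns `display_name`, `member_ids` (list), `I.1`,
#'   `II.1`, `II.3`, `affected_pathway`, `hmdb_id`, `kegg_id`,
#'   `ppi_formation`, `section`.
#' @export
reported_zscores <- function() {
  path <- system.file("extdata", "reported_zscores.tsv",
                      package = "metaboscreen", mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    compound = "c", z_I.1 = "d", z_II.1 = "d", z_II.3 = "d",
    affected_pathway = "c", hmdb_id = "c", kegg_id = "c",
    ppi_formation = "c", section = "c"
  ), progress = FALSE)
  tibble::tibble(
    display_name = raw$compound,
    member_ids   = strsplit(raw$hmdb_id, " | ", fixed = TRUE),
    I.1  = raw$z_I.1,
    II.1 = raw$z_II.1,
    II.3 = raw$z_II.3,
    affected_pathway = raw$affected_pathway,
    hmdb_id = raw$hmdb_id,
    kegg_id = raw$kegg_id,
    ppi_formation = raw$ppi_formation,
    section = raw$section
  )
}
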