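#' Read a long-format fermentation table
#'
#' Canonical schema: comma-separated UTF-8 with header columns
#' `donor_id`, `condition`, `substrate`, `scfa_type`,
#' `concentration_mM`. Deposited datasets with other column names can be
#' mapped via `col_map`. Substrate and SCFA labels are case-folded to
#' lower case (any change is reported via a message — readers never
#' repair silently); if no `total` rows are present they are derived as
#' the per-substrate sum of the three acids (also reported).
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping canonical
#'   column name -> column name in the file.
#' @param derive_total Derive `total` rows when absent (default TRUE).
#' @return Validated fermentation tibble.
#' @export
read_fermentation <- function(path, col_map = NULL, derive_total = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  canonical <- c("donor_id", "condition", "substrate", "scfa_type",
                 "concentration_mM")
  if (!is.null(col_map)) {
    present <- intersect(names(col_map), canonical)
    for (nm in present) {
      if (!col_map[[nm]] %in% names(raw)) {
        abort(sprintf("col_map: column '%s' (for '%s') not in file.",
                      col_map[[nm]], nm), class = "fibersynergy_schema_error")
      }
    }
    raw <- dplyr::rename(raw, !!!setNames(as.list(unname(col_map[present])),
                                          present))
  }
  missing <- setdiff(canonical, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("fermentation file is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "fibersynergy_schema_error")
  }
  tbl <- dplyr::select(raw, dplyr::all_of(canonical))
  tbl$donor_id <- as.character(tbl$donor_id)
  tbl$condition <- as.character(tbl$condition)

  folded_sub <- tolower(tbl$substrate)
  folded_scfa <- tolower(tbl$scfa_type)
  if (any(folded_sub != tbl$substrate) || any(folded_scfa != tbl$scfa_type)) {
    inform("read_fermentation: case-folded substrate/scfa_type labels to lower case.")
  }
  tbl$substrate <- folded_sub
  tbl$scfa_type <- folded_scfa

  unknown <- setdiff(unique(tbl$scfa_type), SCFA_TYPES)
  if (length(unknown) > 0L) {
    inform(sprintf("read_fermentation: unrecognised scfa_type label(s): %s.",
                   paste(unknown, collapse = ", ")))
  }
  bad <- which(!is.finite(tbl$concentration_mM) | tbl$concentration_mM < 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "negative or non-finite concentration_mM at data row(s): %s.",
      paste(head(bad, 5), collapse = ", ")
    ), class = "fibersynergy_validation_error")
  }
  dup <- duplicated(tbl[, c("donor_id", "substrate", "scfa_type")])
  if (any(dup)) {
    abort(sprintf("duplicated (donor, substrate, scfa_type) at data row(s): %s.",
                  paste(head(which(dup), 5), collapse = ", ")),
          class = "fibersynergy_validation_error")
  }
  if (derive_total && !"total" %in% tbl$scfa_type) {
    inform("read_fermentation: no 'total' rows found; deriving total = acetate + propionate + butyrate.")
    totals <- tbl |>
      dplyr::filter(.data$scfa_type %in% SCFA_ACIDS) |>
      dplyr::summarise(
        concentration_mM = sum(.data$concentration_mM),
        .by = c("donor_id", "condition", "substrate")
      ) |>
      dplyr::mutate(scfa_type = "total", .before = "concentration_mM")
    tbl <- dplyr::bind_rows(tbl, totals)
  }
  tbl
}

#' Write a fermentation table as CSV
#'
#' @param ferm Fermentation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fermentation <- function(ferm, path) {
  assert_columns(ferm, c("donor_id", "condition", "substrate", "scfa_type",
                         "concentration_mM"), "fermentation table")
  readr::write_csv(ferm, path)
  invisible(path)
}

#' Read a taxa count table (TSV, taxon-id first column)
#'
#' @param path TSV file path.
#' @return Count tibble (`taxon` first column, one integer column per
#'   sample). Duplicated taxon ids, non-integer or negative cells, and
#'   empty tables are errors.
#' @export
read_taxa_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) abort("no taxa: the count table is empty.")
  names(raw)[1] <- "taxon"
  m <- taxa_matrix(raw)    # validates integer >= 0, unique taxa
  storage.mode(m) <- "integer"
  taxa_tibble(m)
}

#' Write a taxa count table as TSV
#'
#' @param counts Count tibble or taxa x samples matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(counts, path) {
  if (is.matrix(counts)) counts <- taxa_tibble(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read and write sample metadata (TSV)
#'
#' Metadata has columns `sample_id`, `donor_id`, `timepoint`
#' (`baseline`/`post`) and optionally `synergy_label`.
#'
#' @param path TSV path.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(meta, c("sample_id", "donor_id", "timepoint"), "metadata")
  if (anyDuplicated(meta$sample_id)) {
    abort("metadata sample_ids must be unique.",
          class = "fibersynergy_validation_error")
  }
  bad <- setdiff(unique(meta$timepoint), c("baseline", "post"))
  if (length(bad) > 0L) {
    inform(sprintf("read_sample_metadata: unrecognised timepoint label(s): %s.",
                   paste(bad, collapse = ", ")))
  }
  meta
}

#' @rdname read_sample_metadata
#' @param meta Metadata tibble.
#' @export
write_sample_metadata <- function(meta, path) {
  assert_columns(meta, c("sample_id", "donor_id", "timepoint"), "metadata")
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Cross-check donors between fermentation data and sample metadata
#'
#' Reports donors present in only one of the two inputs; downstream
#' stages proceed on the intersection. An empty intersection is fatal.
#'
#' @param ferm Fermentation tibble.
#' @param meta Sample metadata tibble.
#' @return List: `shared`, `fermentation_only`, `metadata_only`
#'   (character vectors of donor ids).
#' @export
validate_join <- function(ferm, meta) {
  assert_columns(ferm, "donor_id", "fermentation table")
  assert_columns(meta, "donor_id", "metadata")
  fd <- unique(as.character(ferm$donor_id))
  md <- unique(as.character(meta$donor_id))
  shared <- intersect(fd, md)
  if (length(shared) == 0L) {
    abort("no donors shared between fermentation data and metadata.",
          class = "fibersynergy_join_error")
  }
  list(
    shared = sort(shared),
    fermentation_only = sort(setdiff(fd, md)),
    metadata_only = sort(setdiff(md, fd))
  )
}
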