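#' Alpha diversity per sample
#'
#' Shannon entropy (natural log by default), observed richness and
#' Pielou evenness for every sample column of a taxa count table.
#' Evenness is `shannon / log(richness)` and is undefined (NA) for
#' single-taxon samples; all-zero samples are an error. Shannon is
#' computed on relative abundances, so it is invariant under count
#' rescaling; no rarefaction is applied.
#'
#' @param counts Taxa count table: tibble with taxon-id first column, or
#'   an integer matrix (taxa x samples) with rownames.
#' @param metadata Optional sample metadata tibble (`sample_id`,
#'   `donor_id`, `timepoint`) joined onto the result.
#' @param base Logarithm base; default `exp(1)` (nats).
#' @return Tibble: `sample_id`, (`donor_id`, `timepoint` if metadata
#'   given), `shannon`, `richness`, `evenness`.
#' @examples
#' m <- matrix(c(5L, 5L, 5L, 1L, 1L, 2L), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' alpha_diversity(m)
#' @export
alpha_diversity <- function(counts, metadata = NULL, base = exp(1)) {
  m <- taxa_matrix(counts)
  empty <- colSums(m) == 0
  if (any(empty)) {
    abort(sprintf("empty sample(s) with no positive counts: %s.",
                  paste(colnames(m)[empty], collapse = ", ")))
  }
  shannon <- as.numeric(vegan::diversity(t(m), index = "shannon", base = base))
  richness <- as.integer(vegan::specnumber(t(m)))
  evenness <- ifelse(richness >= 2, shannon / log(richness, base = base), NA_real_)
  out <- tibble::tibble(
    sample_id = colnames(m),
    shannon = shannon, richness = richness, evenness = evenness
  )
  if (!is.null(metadata)) {
    assert_columns(metadata, "sample_id", "metadata")
    out <- dplyr::left_join(
      out,
      dplyr::select(metadata, dplyr::any_of(c("sample_id", "donor_id",
                                              "timepoint"))),
      by = "sample_id"
    ) |>
      dplyr::relocate(dplyr::any_of(c("donor_id", "timepoint")),
                      .after = "sample_id")
  }
  out
}

#' Change in alpha diversity between baseline and post-fermentation
#'
#' Pairs each donor's baseline and post-fermentation diversity records
#' and returns the difference (post minus baseline) per metric. A
#' missing evenness at either timepoint propagates to a missing delta.
#' Donors lacking either timepoint are dropped with a warning; a donor
#' with duplicated records at a timepoint is an error.
#'
#' @param diversity Tibble from [alpha_diversity()] including `donor_id`
#'   and `timepoint` columns with values `baseline` and `post`.
#' @return Tibble: `donor_id`, `delta_shannon`, `delta_richness`,
#'   `delta_evenness`.
#' @export
delta_diversity <- function(diversity) {
  assert_columns(diversity, c("donor_id", "timepoint", "shannon", "richness",
                              "evenness"), "diversity table")
  bad <- setdiff(unique(diversity$timepoint), c("baseline", "post"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown timepoint label(s): %s.", paste(bad, collapse = ", ")))
  }
  dup <- diversity |>
    dplyr::count(.data$donor_id, .data$timepoint) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicated diversity records for donor(s): %s.",
                  paste(unique(dup$donor_id), collapse = ", ")))
  }
  wide <- diversity |>
    dplyr::select("donor_id", "timepoint", "shannon", "richness", "evenness") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("shannon", "richness", "evenness"))
  for (col in c("shannon_baseline", "shannon_post", "richness_baseline",
                "richness_post", "evenness_baseline", "evenness_post")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  incomplete <- is.na(wide$shannon_baseline) | is.na(wide$shannon_post)
  if (any(incomplete)) {
    warn(sprintf("dropping donor(s) missing a timepoint: %s.",
                 paste(wide$donor_id[incomplete], collapse = ", ")))
    wide <- wide[!incomplete, ]
  }
  tibble::tibble(
    donor_id = wide$donor_id,
    delta_shannon = wide$shannon_post - wide$shannon_baseline,
    delta_richness = wide$richness_post - wide$richness_baseline,
    delta_evenness = wide$evenness_post - wide$evenness_baseline
  )
}

#' Donor-level diversity feature table
#'
#' Reshapes per-sample diversity records into one row per donor with
#' columns `<metric>_<baseline|post|delta>` — the feature layout the
#' synergy correlation grid consumes.
#'
#' @inheritParams delta_diversity
#' @return Wide tibble keyed by `donor_id`.
#' @export
diversity_features <- function(diversity) {
  assert_columns(diversity, c("donor_id", "timepoint"), "diversity table")
  wide <- diversity |>
    dplyr::select("donor_id", "timepoint", "shannon", "richness", "evenness") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("shannon", "richness", "evenness"))
  deltas <- suppressWarnings(delta_diversity(diversity))
  dplyr::left_join(wide, deltas, by = "donor_id") |>
    dplyr::rename_with(~ sub("^delta_(.*)$", "\\1_delta", .x))
}
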