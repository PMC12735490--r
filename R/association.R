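#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value
#' is exact (full rank-permutation null) for n <= 9 without ties and
#' asymptotic otherwise. Cells with fewer than `n_min` complete pairs,
#' or with a constant input, are returned missing with a reason rather
#' than as zero.
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @param n_min Minimum number of complete pairs.
#' @return One-row tibble: `rho`, `p`, `n`, `reason` (NA when defined).
#' @examples
#' spearman_test(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_test <- function(x, y, n_min = 3L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < n_min) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          reason = sprintf("n < %d", n_min)))
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          reason = "constant input"))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 9L && !ties
  ht <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact, continuity = FALSE)
  )
  tibble::tibble(rho = unname(ht$estimate), p = ht$p.value, n = n,
                 reason = NA_character_)
}

#' Correlation grid between synergy percentages and donor features
#'
#' One Spearman cell per (SCFA type, feature column): retained synergy
#' percentages are aligned with donor-level features, donors are dropped
#' pairwise per cell (filtering makes synergy availability
#' cell-specific), and significance is annotated per cell at `alpha`.
#' No multiplicity adjustment is applied by default, matching the
#' per-cell annotation style of correlation heatmaps; `adjust = "bh"`
#' applies BH across all defined cells.
#'
#' @param synergy Synergy tibble from [compute_synergy()].
#' @param features Tibble with `donor_id` plus numeric feature columns
#'   (e.g. from [diversity_features()] or [scfa_features()]).
#' @param feature_cols Optional character vector restricting the feature
#'   columns; defaults to every numeric column.
#' @param alpha Per-cell significance level.
#' @param adjust `"none"` (default) or `"bh"`.
#' @param n_min Minimum complete pairs per cell.
#' @return Tibble of class `scfa_corgrid`: `scfa_type`, `feature`,
#'   `rho`, `p`, `n`, `significant`, `reason`.
#' @export
correlation_grid <- function(synergy, features, feature_cols = NULL,
                             alpha = 0.05, adjust = c("none", "bh"),
                             n_min = 3L) {
  adjust <- match.arg(adjust)
  assert_columns(synergy, c("donor_id", "scfa_type", "synergy_pct",
                            "filter_status"), "synergy table")
  assert_columns(features, "donor_id", "features")
  if (is.null(feature_cols)) {
    feature_cols <- names(features)[vapply(features, is.numeric, TRUE)]
  }
  if (length(feature_cols) == 0L) abort("no numeric feature columns found.")
  syn_wide <- synergy |>
    dplyr::filter(.data$filter_status == "retained") |>
    dplyr::select("donor_id", "scfa_type", "synergy_pct") |>
    tidyr::pivot_wider(names_from = "scfa_type", values_from = "synergy_pct")
  joined <- dplyr::inner_join(syn_wide, features, by = "donor_id")
  if (nrow(joined) == 0L) abort("no overlapping donors between synergy and features.")
  types <- intersect(SCFA_TYPES, names(syn_wide))

  grid <- tidyr::expand_grid(scfa_type = types, feature = feature_cols)
  cells <- purrr::pmap(grid, function(scfa_type, feature) {
    spearman_test(joined[[scfa_type]], joined[[feature]], n_min = n_min)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  if (adjust == "bh") {
    ok <- !is.na(out$p)
    out$p[ok] <- adjust_pvalues(out$p[ok], "bh")
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  class(out) <- c("scfa_corgrid", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}

#' Donor-level absolute SCFA feature table
#'
#' Observed mixture concentrations per donor and SCFA type, reshaped to
#' one column per SCFA (`<scfa>_mM`) for use as correlation-grid
#' features against synergy percentages.
#'
#' @param synergy Synergy tibble from [compute_synergy()].
#' @return Wide tibble keyed by `donor_id`.
#' @export
scfa_features <- function(synergy) {
  assert_columns(synergy, c("donor_id", "scfa_type", "observed_mM"),
                 "synergy table")
  synergy |>
    dplyr::select("donor_id", "scfa_type", "observed_mM") |>
    tidyr::pivot_wider(names_from = "scfa_type", values_from = "observed_mM",
                       names_glue = "{scfa_type}_mM")
}

#' Long-to-square reshaping of a correlation grid
#'
#' @param grid A `scfa_corgrid` from [correlation_grid()].
#' @param value Which cell value to spread: `"rho"` or `"p"`.
#' @return Tibble with one row per SCFA type, one column per feature.
#' @export
cor_matrix <- function(grid, value = c("rho", "p")) {
  value <- match.arg(value)
  tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(grid), "scfa_type", "feature",
                  dplyr::all_of(value)),
    names_from = "feature", values_from = dplyr::all_of(value)
  )
}
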