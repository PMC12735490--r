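#' Broom-style tidiers for fibersynergy result objects
#'
#' `tidy()` returns the per-item results as a plain tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x A result object (`scfa_da`, `cooc_network`, `taxa_cor`,
#'   `scfa_corgrid`, `ferm_sim`).
#' @param ... Unused.
#' @name fibersynergy-tidiers
NULL

#' @rdname fibersynergy-tidiers
#' @export
tidy.scfa_da <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname fibersynergy-tidiers
#' @export
glance.scfa_da <- function(x, ...) {
  n <- attr(x, "n_per_group")
  tibble::tibble(
    n_taxa = nrow(x),
    n_tested = sum(x$status == "tested"),
    n_structural_zero = sum(x$status == "structural_zero"),
    n_significant = sum(x$significant, na.rm = TRUE),
    max_lfc = suppressWarnings(max(x$lfc, na.rm = TRUE)),
    n_synergy = unname(n["synergy"]),
    n_no_synergy = unname(n["no_synergy"]),
    alpha = attr(x, "alpha")
  )
}

#' @rdname fibersynergy-tidiers
#' @export
tidy.cooc_network <- function(x, ...) x$edges

#' @rdname fibersynergy-tidiers
#' @export
glance.cooc_network <- function(x, ...) {
  n <- nrow(x$nodes)
  e <- nrow(x$edges)
  tibble::tibble(
    stratum = x$stratum %||% NA_character_,
    n_nodes = n, n_edges = e,
    n_positive = sum(x$edges$sign == "positive"),
    n_negative = sum(x$edges$sign == "negative"),
    density = if (n > 1) e / (n * (n - 1) / 2) else NA_real_,
    mean_degree = if (n > 0) mean(x$nodes$degree) else NA_real_
  )
}

#' @rdname fibersynergy-tidiers
#' @export
tidy.taxa_cor <- function(x, ...) {
  ut <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    taxon1 = x$taxa[ut[, 1]], taxon2 = x$taxa[ut[, 2]],
    rho = x$rho[ut], p = x$p[ut], n = x$n_samples
  )
}

#' @rdname fibersynergy-tidiers
#' @export
tidy.scfa_corgrid <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname fibersynergy-tidiers
#' @export
glance.ferm_sim <- function(x, ...) {
  tibble::tibble(
    n_donors = dplyr::n_distinct(x$fermentation$donor_id),
    n_conditions = dplyr::n_distinct(x$fermentation$condition),
    n_records = nrow(x$fermentation),
    mean_delta_pct = mean(x$truth$delta_pct),
    sd_delta_pct = sd(x$truth$delta_pct)
  )
}
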