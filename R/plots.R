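#' Synergy distributions by condition and SCFA type
#'
#' Boxplots of retained synergy percentages, faceted by SCFA type, with
#' a dashed reference line at zero (the additive expectation).
#'
#' @param synergy Synergy tibble from [compute_synergy()].
#' @return A ggplot object.
#' @export
plot_synergy <- function(synergy) {
  assert_columns(synergy, c("condition", "scfa_type", "synergy_pct",
                            "filter_status"), "synergy table")
  kept <- dplyr::filter(synergy, .data$filter_status == "retained")
  ggplot2::ggplot(kept, ggplot2::aes(x = .data$condition,
                                     y = .data$synergy_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.6) +
    ggplot2::facet_wrap(~scfa_type) +
    ggplot2::labs(x = NULL, y = "Synergy (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_synergy Observed vs expected mixture concentrations
#'   per condition and SCFA type, with donor-pairing segments.
#' @export
plot_observed_expected <- function(synergy) {
  assert_columns(synergy, c("donor_id", "condition", "scfa_type",
                            "observed_mM", "expected_mM"), "synergy table")
  long <- synergy |>
    tidyr::pivot_longer(c("observed_mM", "expected_mM"),
                        names_to = "kind", values_to = "mM") |>
    dplyr::mutate(kind = sub("_mM$", "", .data$kind))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kind, y = .data$mM)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$donor_id),
                       alpha = 0.4, colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kind), size = 1.5) +
    ggplot2::facet_grid(scfa_type ~ condition, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "SCFA (mM)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a synergy-feature correlation grid
#'
#' @param object A `scfa_corgrid` from [correlation_grid()].
#' @param ... Unused.
#' @return A ggplot tile plot; significant cells are starred.
#' @export
autoplot.scfa_corgrid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(df$significant %in% TRUE, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$scfa_type,
                                   fill = .data$rho)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = "Synergy (%)", fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Log fold-change bar plot for differential abundance results
#'
#' @param object A `scfa_da` from [differential_abundance()].
#' @param only_significant Show only BH-significant taxa (default TRUE).
#' @param ... Unused.
#' @return A ggplot object: bars of natural-log fold change with
#'   standard-error whiskers; positive values mean enrichment in the
#'   synergy group.
#' @export
autoplot.scfa_da <- function(object, only_significant = TRUE, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$status == "tested")
  if (only_significant) df <- dplyr::filter(df, .data$significant %in% TRUE)
  df$taxon <- factor(df$taxon, levels = df$taxon[order(df$lfc)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc, y = .data$taxon)) +
    ggplot2::geom_col(fill = "seagreen", alpha = 0.7) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lfc - .data$se, xmax = .data$lfc + .data$se),
      height = 0.3
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Log fold change (synergy vs no synergy)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Quick layout plot of a co-occurrence network
#'
#' @param object A `cooc_network`.
#' @param ... Unused.
#' @return A ggplot object: Fruchterman-Reingold layout, edge colour by
#'   sign, node size by degree.
#' @export
autoplot.cooc_network <- function(object, ...) {
  if (nrow(object$nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  set_lay <- igraph::layout_with_fr(object$graph)
  lay <- tibble::tibble(taxon = object$nodes$taxon,
                        x = set_lay[, 1], y = set_lay[, 2],
                        degree = object$nodes$degree)
  seg <- object$edges |>
    dplyr::left_join(dplyr::select(lay, "taxon", x0 = "x", y0 = "y"),
                     by = c(from = "taxon")) |>
    dplyr::left_join(dplyr::select(lay, "taxon", x1 = "x", y1 = "y"),
                     by = c(to = "taxon"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      colour = "grey25"
    ) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#B2182B", negative = "#2166AC")
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$stratum, colour = "edge sign",
                  size = "degree")
}
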