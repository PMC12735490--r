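#' Taxa-taxa Spearman correlation matrices within a stratum
#'
#' Spearman rank correlations (average ranks for ties) between taxa over
#' relative abundances across the samples of one stratum, with a
#' two-sided p-value per pair. Taxa are prevalence-filtered first.
#'
#' @param counts Taxa count table (tibble or taxa x samples matrix).
#' @param min_samples Minimum samples required in the stratum (default 5).
#' @param prevalence_min Taxa present in fewer than this fraction of
#'   samples are dropped before correlation (default 0.2).
#' @return List of class `taxa_cor`: `rho` and `p` (symmetric matrices,
#'   unit/zero diagonal), `n_samples`, `taxa`.
#' @export
taxa_correlation_matrix <- function(counts, min_samples = 5L,
                                    prevalence_min = 0.2) {
  m <- taxa_matrix(counts)
  if (ncol(m) < min_samples) {
    abort(sprintf("stratum has %d samples; at least %d required.",
                  ncol(m), min_samples))
  }
  m <- m[rowMeans(m > 0) >= prevalence_min, , drop = FALSE]
  if (nrow(m) < 2L) abort("fewer than 2 taxa pass the prevalence filter.")
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  k <- nrow(rel)
  rho <- cor(t(rel), method = "spearman")
  p <- matrix(0, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- suppressWarnings(
        cor.test(rel[i, ], rel[j, ], method = "spearman", exact = FALSE)
      )
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = p, n_samples = ncol(m), taxa = rownames(m)),
            class = "taxa_cor")
}

#' Network construction thresholds
#'
#' @param rho_min Minimum absolute Spearman rho for an edge (default 0.6,
#'   the usual co-occurrence practice).
#' @param alpha Significance level on BH-adjusted edge q-values.
#' @param drop_isolated Drop nodes with no retained edge (default TRUE).
#' @return List of class `network_config`.
#' @export
network_config <- function(rho_min = 0.6, alpha = 0.05, drop_isolated = TRUE) {
  assert_scalar_number(alpha, "alpha", min = 0)
  if (!is.numeric(rho_min) || length(rho_min) != 1L) {
    abort("`rho_min` must be a single number.")
  }
  structure(list(rho_min = rho_min, alpha = alpha,
                 drop_isolated = isTRUE(drop_isolated)),
            class = "network_config")
}

#' Build a signed co-occurrence network from correlation matrices
#'
#' An edge joins two taxa when the BH-adjusted p-value across all taxon
#' pairs is below `alpha` and `|rho| >= rho_min`; its sign is the sign
#' of rho. Node degree is the count of incident retained edges.
#'
#' @param tc A `taxa_cor` from [taxa_correlation_matrix()].
#' @param cfg A [network_config()].
#' @param stratum Optional stratum label carried on the network.
#' @param family Optional named vector taxon -> family label, stored as a
#'   node attribute.
#' @return List of class `cooc_network`: `edges` (tibble `from`, `to`,
#'   `rho`, `p`, `q`, `sign`), `nodes` (tibble `taxon`, `degree`,
#'   `strength` = summed `|rho|`, optional `family`), `graph` (igraph),
#'   `stratum`, `config`.
#' @export
build_network <- function(tc, cfg = network_config(), stratum = NULL,
                          family = NULL) {
  if (!inherits(tc, "taxa_cor")) abort("`tc` must come from taxa_correlation_matrix().")
  k <- length(tc$taxa)
  ut <- which(upper.tri(tc$rho), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = tc$taxa[ut[, 1]], to = tc$taxa[ut[, 2]],
    rho = tc$rho[ut], p = tc$p[ut]
  )
  edges$q <- if (nrow(edges) > 0) adjust_pvalues(edges$p, "bh") else numeric(0)
  edges <- dplyr::filter(edges, .data$q < cfg$alpha,
                         abs(.data$rho) >= cfg$rho_min)
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")

  deg <- setNames(rep(0L, k), tc$taxa)
  strength <- setNames(rep(0, k), tc$taxa)
  for (i in seq_len(nrow(edges))) {
    deg[edges$from[i]] <- deg[edges$from[i]] + 1L
    deg[edges$to[i]] <- deg[edges$to[i]] + 1L
    strength[edges$from[i]] <- strength[edges$from[i]] + abs(edges$rho[i])
    strength[edges$to[i]] <- strength[edges$to[i]] + abs(edges$rho[i])
  }
  nodes <- tibble::tibble(taxon = tc$taxa, degree = unname(deg),
                          strength = unname(strength))
  if (!is.null(family)) {
    nodes$family <- unname(family[nodes$taxon])
  }
  if (cfg$drop_isolated) nodes <- dplyr::filter(nodes, .data$degree > 0L)

  graph <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  structure(list(edges = edges, nodes = nodes, graph = graph,
                 stratum = stratum, config = cfg),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf(
    "<cooc_network%s: %d nodes, %d edges (%d positive, %d negative)>\n",
    if (!is.null(x$stratum)) paste0(" ", x$stratum) else "",
    nrow(x$nodes), nrow(x$edges),
    sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")
  ))
  invisible(x)
}

#' Degree centrality and hub taxa
#'
#' Ranks nodes by centrality (degree by default, betweenness optional)
#' and returns the top `k`. Ties are broken by summed absolute edge rho
#' (strength), then lexicographically by taxon id, so rankings are
#' deterministic.
#'
#' @param net A `cooc_network`.
#' @param k Number of hubs to return.
#' @param centrality `"degree"` or `"betweenness"`.
#' @return Tibble `taxon`, `degree`, `strength`, (`betweenness`,)
#'   `rank`; empty for an empty network.
#' @export
centrality_and_hubs <- function(net, k = 5L,
                                centrality = c("degree", "betweenness")) {
  centrality <- match.arg(centrality)
  if (!inherits(net, "cooc_network")) abort("`net` must be a cooc_network.")
  nodes <- net$nodes
  if (nrow(nodes) == 0L) {
    return(tibble::tibble(taxon = character(), degree = integer(),
                          strength = double(), rank = integer()))
  }
  if (centrality == "betweenness") {
    btw <- igraph::betweenness(net$graph,
                               weights = 1 / abs(igraph::E(net$graph)$rho))
    nodes$betweenness <- unname(btw[nodes$taxon])
    key <- nodes$betweenness
  } else {
    key <- nodes$degree
  }
  ord <- order(-key, -nodes$strength, nodes$taxon)
  nodes <- nodes[ord, ]
  nodes$rank <- seq_len(nrow(nodes))
  head(nodes, k)
}

#' Export a co-occurrence network
#'
#' Writes GraphML (Cytoscape-importable, with node attributes `degree`,
#' `strength`, optional `family`, and edge attributes `rho`, `p`, `q`,
#' `sign`) or a tab-separated edge list with the same edge columns.
#' [import_network()] round-trips either format losslessly up to edge
#' order.
#'
#' @param net A `cooc_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (!inherits(net, "cooc_network")) abort("`net` must be a cooc_network.")
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path)
  }
  invisible(path)
}

#' Import a co-occurrence network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param cfg Thresholds to record on the imported network (not
#'   re-applied; edges are taken as stored).
#' @return A `cooc_network`.
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv"),
                           cfg = network_config()) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- tibble::tibble(
      taxon = va$name,
      degree = as.integer(va$degree),
      strength = as.numeric(va$strength)
    )
    if (!is.null(va$family)) nodes$family <- va$family
    el <- igraph::as_edgelist(g, names = TRUE)
    ea <- igraph::edge_attr(g)
    edges <- tibble::tibble(
      from = el[, 1], to = el[, 2],
      rho = as.numeric(ea$rho %||% numeric(0)),
      p = as.numeric(ea$p %||% numeric(0)),
      q = as.numeric(ea$q %||% numeric(0)),
      sign = as.character(ea$sign %||% character(0))
    )
  } else {
    edges <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               from = "c", to = "c", rho = "d",
                               p = "d", q = "d", sign = "c"
                             ))
    taxa <- sort(unique(c(edges$from, edges$to)))
    deg <- setNames(rep(0L, length(taxa)), taxa)
    strength <- setNames(rep(0, length(taxa)), taxa)
    for (i in seq_len(nrow(edges))) {
      deg[edges$from[i]] <- deg[edges$from[i]] + 1L
      deg[edges$to[i]] <- deg[edges$to[i]] + 1L
      strength[edges$from[i]] <- strength[edges$from[i]] + abs(edges$rho[i])
      strength[edges$to[i]] <- strength[edges$to[i]] + abs(edges$rho[i])
    }
    nodes <- tibble::tibble(taxon = taxa, degree = unname(deg),
                            strength = unname(strength))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = as.data.frame(nodes))
  }
  structure(list(edges = edges, nodes = nodes, graph = g,
                 stratum = NULL, config = cfg),
            class = "cooc_network")
}
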