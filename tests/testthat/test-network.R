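test_that("taxa correlation matrices are symmetric with unit diagonal", {
  sim <- simulate_taxa_counts(taxa_config(n_taxa = 12, seed = 2))
  tc <- taxa_correlation_matrix(sim$counts, prevalence_min = 0)
  expect_equal(tc$rho, t(tc$rho))
  expect_equal(tc$p, t(tc$p))
  expect_equal(unname(diag(tc$rho)), rep(1, nrow(tc$rho)))
  expect_error(taxa_correlation_matrix(sim$counts[, 1:4]), "at least 5")
})

test_that("a shared latent factor shows up as strong positive rank correlation", {
  sim <- simulate_latent_taxa(
    n_taxa = 10, n_samples = 50,
    loadings = c(taxon_01 = 0.95, taxon_02 = 0.95), seed = 13
  )
  tc <- taxa_correlation_matrix(sim$counts, prevalence_min = 0)
  expect_gt(tc$rho["taxon_01", "taxon_02"], 0.8)
})

test_that("independent taxa produce near-nominal edge significance", {
  withr::with_seed(37, {
    n_sig <- 0; n_tot <- 0
    for (rep in 1:20) {
      sim <- simulate_latent_taxa(
        n_taxa = 10, n_samples = 60,
        loadings = c(taxon_01 = 0.5), seed = 1000 + rep
      )
      tc <- taxa_correlation_matrix(sim$counts, prevalence_min = 0)
      ut <- upper.tri(tc$p)
      n_sig <- n_sig + sum(tc$p[ut] < 0.05)
      n_tot <- n_tot + sum(ut)
    }
    # a lone factor member is background; all pairs are near-independent
    expect_lt(abs(n_sig / n_tot - 0.05), 0.035)
  })
})

test_that("network construction applies the q and rho thresholds", {
  taxa <- paste0("t", 1:4)
  rho <- diag(4); dimnames(rho) <- list(taxa, taxa)
  p <- matrix(1, 4, 4, dimnames = list(taxa, taxa)); diag(p) <- 0
  net0 <- build_network(make_taxa_cor(rho, p))
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$nodes), 0)

  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[3, 4] <- rho[4, 3] <- -0.7
  rho[1, 3] <- rho[3, 1] <- 0.4          # strong p but weak rho
  p[1, 2] <- p[2, 1] <- 1e-8
  p[3, 4] <- p[4, 3] <- 1e-6
  p[1, 3] <- p[3, 1] <- 1e-9
  net <- build_network(make_taxa_cor(rho, p))
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("positive", "negative"))
  expect_identical(net$edges$sign, ifelse(net$edges$rho >= 0,
                                          "positive", "negative"))
  # impossible rho threshold empties any network
  net_imp <- build_network(make_taxa_cor(rho, p),
                           network_config(rho_min = 1.01))
  expect_equal(nrow(net_imp$edges), 0)
})

test_that("tightening thresholds never adds edges, and degrees sum to 2E", {
  sim <- simulate_latent_taxa(seed = 3)
  tc <- taxa_correlation_matrix(sim$counts)
  loose <- build_network(tc, network_config(rho_min = 0.4, alpha = 0.1))
  tight_rho <- build_network(tc, network_config(rho_min = 0.7, alpha = 0.1))
  tight_a <- build_network(tc, network_config(rho_min = 0.4, alpha = 0.001))
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(tight_rho) %in% key(loose)))
  expect_true(all(key(tight_a) %in% key(loose)))
  expect_equal(sum(loose$nodes$degree), 2 * nrow(loose$edges))
})

test_that("networks are invariant under sample reordering", {
  sim <- simulate_latent_taxa(seed = 5)
  shuffled <- sim$counts[, c(1, withr::with_seed(1, sample(100) + 1))]
  n1 <- build_network(taxa_correlation_matrix(sim$counts))
  n2 <- build_network(taxa_correlation_matrix(shuffled))
  expect_equal(dplyr::arrange(n1$edges, from, to),
               dplyr::arrange(n2$edges, from, to))
})

test_that("a planted module is recovered with all-positive edges", {
  members <- sprintf("taxon_%02d", 1:6)
  sim <- simulate_latent_taxa(
    n_taxa = 14, n_samples = 100,
    loadings = setNames(rep(0.9, 6), members), seed = 8
  )
  net <- build_network(taxa_correlation_matrix(sim$counts))
  within <- net$edges$from %in% members & net$edges$to %in% members
  expect_equal(sum(within), 15)          # all 6-choose-2 pairs
  expect_true(all(net$edges$sign[within] == "positive"))
})

test_that("hub ranking follows degree with deterministic tie-breaks", {
  taxa <- c("hub", paste0("leaf", 1:5))
  rho <- diag(6); dimnames(rho) <- list(taxa, taxa)
  p <- matrix(1, 6, 6, dimnames = list(taxa, taxa)); diag(p) <- 0
  for (i in 2:6) {
    rho["hub", taxa[i]] <- rho[taxa[i], "hub"] <- 0.8
    p["hub", taxa[i]] <- p[taxa[i], "hub"] <- 1e-8
  }
  net <- build_network(make_taxa_cor(rho, p))
  hubs <- centrality_and_hubs(net, k = 6)
  expect_identical(hubs$taxon[1], "hub")
  expect_equal(hubs$degree[1], 5L)
  expect_true(all(hubs$degree[-1] == 1L))

  # two disjoint triangles: all degree 2; ties break by strength then id
  t2 <- paste0("x", 1:6)
  rho2 <- diag(6); dimnames(rho2) <- list(t2, t2)
  p2 <- matrix(1, 6, 6, dimnames = list(t2, t2)); diag(p2) <- 0
  tri <- list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  w <- c(0.9, 0.9, 0.9, 0.7, 0.7, 0.7)
  for (k in seq_along(tri)) {
    i <- tri[[k]][1]; j <- tri[[k]][2]
    rho2[i, j] <- rho2[j, i] <- w[k]
    p2[i, j] <- p2[j, i] <- 1e-8
  }
  net2 <- build_network(make_taxa_cor(rho2, p2))
  h2 <- centrality_and_hubs(net2, k = 6)
  expect_true(all(h2$degree == 2L))
  # first triangle has larger strength; within it, lexicographic order
  expect_identical(h2$taxon, c("x1", "x2", "x3", "x4", "x5", "x6"))

  nm <- list(c("a", "b"), c("a", "b"))
  empty <- build_network(make_taxa_cor(
    matrix(c(1, 0, 0, 1), 2, dimnames = nm),
    matrix(1, 2, 2, dimnames = nm)
  ))
  expect_equal(nrow(centrality_and_hubs(empty)), 0)
})

test_that("network export round-trips through GraphML and edge TSV", {
  sim <- simulate_latent_taxa(seed = 10)
  net <- build_network(taxa_correlation_matrix(sim$counts))
  expect_gt(nrow(net$edges), 0)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  ord <- function(e) dplyr::arrange(e, from, to)
  expect_equal(ord(back$edges), ord(net$edges), tolerance = 1e-9)
  expect_equal(dplyr::arrange(back$nodes, taxon),
               dplyr::arrange(net$nodes, taxon), tolerance = 1e-9)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_tsv")
  back2 <- import_network(tsv, "edge_tsv")
  expect_equal(ord(back2$edges), ord(net$edges), tolerance = 1e-12)

  # empty networks still export valid files
  nm <- list(c("a", "b"), c("a", "b"))
  e <- build_network(make_taxa_cor(
    matrix(c(1, 0, 0, 1), 2, dimnames = nm),
    matrix(1, 2, 2, dimnames = nm)
  ))
  export_network(e, gml, "graphml")
  expect_equal(nrow(import_network(gml, "graphml")$edges), 0)
  expect_error(export_network(net, tsv, "dot"), "should be one of")
})

test_that("glance summarises a network's topology", {
  sim <- simulate_latent_taxa(seed = 12)
  net <- build_network(taxa_correlation_matrix(sim$counts), stratum = "demo")
  g <- glance(net)
  expect_equal(g$n_edges, nrow(net$edges))
  expect_equal(g$stratum, "demo")
  expect_equal(g$n_positive + g$n_negative, g$n_edges)
})
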