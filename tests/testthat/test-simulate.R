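test_that("zero-effect, zero-noise generation makes the mixture exactly additive", {
  sim <- simulate_fermentation(ferm_config(synergy_mean = 0, synergy_sd = 0,
                                           noise_sd = 0, seed = 11))
  syn <- compute_synergy(sim$fermentation)
  acids <- syn$scfa_type != "total"
  expect_true(all(syn$synergy_pct[acids] == 0))
  # totals are derived sums, so the identity holds to floating-point rounding
  expect_lt(max(abs(syn$synergy_pct[!acids])), 1e-9)
})

test_that("seeded generation is bit-reproducible and seeds matter", {
  a <- simulate_fermentation(ferm_config(seed = 5))
  b <- simulate_fermentation(ferm_config(seed = 5))
  c <- simulate_fermentation(ferm_config(seed = 6))
  expect_identical(a$fermentation, b$fermentation)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$fermentation, c$fermentation))

  ta <- simulate_taxa_counts(taxa_config(seed = 5))
  tb <- simulate_taxa_counts(taxa_config(seed = 5))
  tc_ <- simulate_taxa_counts(taxa_config(seed = 6))
  expect_identical(ta$counts, tb$counts)
  expect_false(identical(ta$counts, tc_$counts))
})

test_that("generated tables satisfy the structural invariants", {
  sim <- simulate_fermentation(ferm_config(noise_sd = 3, seed = 2))
  ferm <- sim$fermentation
  expect_true(all(ferm$concentration_mM >= 0))
  # one record per donor x substrate x scfa type (printed condition
  # sizes: 10 + 10 + 7 + 7 donors)
  expect_equal(nrow(ferm), 34 * 5 * 4)
  expect_equal(anyDuplicated(ferm[, c("donor_id", "substrate", "scfa_type")]), 0L)
  # totals equal the sum of the three acids
  tot <- ferm |>
    tidyr::pivot_wider(names_from = scfa_type, values_from = concentration_mM)
  expect_lt(max(abs(tot$total - (tot$acetate + tot$propionate + tot$butyrate))),
            1e-9)
})

test_that("injected synergy is recovered exactly without noise and in mean with noise", {
  sim <- simulate_fermentation(ferm_config(noise_sd = 0, seed = 17))
  syn <- compute_synergy(sim$fermentation)
  j <- dplyr::inner_join(syn, sim$truth,
                         by = c("donor_id", "condition", "scfa_type"))
  expect_lt(max(abs(j$synergy_pct - j$delta_pct)), 1e-9)

  # Monte-Carlo: 500 donors, injected 30 +/- 20, light noise
  cfg <- ferm_config(conditions = c(HC = 125L, PD = 125L, CD = 125L, UC = 125L),
                     synergy_mean = 30, synergy_sd = 20, noise_sd = 0.1,
                     seed = 99)
  syn <- compute_synergy(simulate_fermentation(cfg)$fermentation)
  est <- mean(syn$synergy_pct[syn$scfa_type == "total"], na.rm = TRUE)
  expect_lt(abs(est - 30), 2 * 20 / sqrt(500))
})

test_that("per-acid synergy draws are independent when requested", {
  cfg <- ferm_config(per_scfa_delta = TRUE, noise_sd = 0, seed = 4)
  sim <- simulate_fermentation(cfg)
  wide <- tidyr::pivot_wider(sim$truth, names_from = scfa_type,
                             values_from = delta_pct)
  expect_false(isTRUE(all.equal(wide$acetate, wide$butyrate)))
})

test_that("taxa generator plants the requested fold change", {
  # plant on a minor taxon so compositional renormalisation does not
  # attenuate the realised fold
  cfg <- taxa_config(n_taxa = 40,
                     n_samples_per_group = c(synergy = 200L, no_synergy = 200L),
                     enriched_taxa = c(taxon_35 = 4),
                     library_meanlog = log(2e5), seed = 12)
  sim <- simulate_taxa_counts(cfg)
  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$taxon
  rel <- sweep(m, 2, colSums(m), "/")
  grp <- sim$metadata$synergy_label
  ratio <- mean(rel["taxon_35", grp == "synergy"]) /
    mean(rel["taxon_35", grp == "no_synergy"])
  expect_lt(abs(ratio - 4), 0.5)
})

test_that("taxa generator null case keeps groups exchangeable", {
  cfg <- taxa_config(n_taxa = 20,
                     n_samples_per_group = c(synergy = 150L, no_synergy = 150L),
                     seed = 8)
  sim <- simulate_taxa_counts(cfg)
  m <- as.matrix(sim$counts[, -1])
  rel <- sweep(m, 2, colSums(m), "/")
  grp <- sim$metadata$synergy_label
  # expected relative abundance of abundant taxa equal across groups
  top <- order(rowMeans(rel), decreasing = TRUE)[1:5]
  ratios <- rowMeans(rel[top, grp == "synergy"]) /
    rowMeans(rel[top, grp == "no_synergy"])
  expect_true(all(abs(ratios - 1) < 0.15))
  expect_true(all(m >= 0) && all(m == round(m)))
})

test_that("generator configs reject invalid fields by name", {
  expect_error(ferm_config(fibers = c("a", "b", "c")), "fibers")
  expect_error(ferm_config(noise_sd = -1), "noise_sd")
  expect_error(ferm_config(synergy_sd = -2), "synergy_sd")
  expect_error(ferm_config(conditions = c(HC = 0)), "donor count")
  expect_error(taxa_config(n_taxa = 1), "n_taxa")
  expect_error(taxa_config(n_samples_per_group = c(synergy = 1L, no_synergy = 5L)),
               "n_samples_per_group")
  expect_error(taxa_config(enriched_taxa = c(t1 = -2)), "enriched_taxa")
})

test_that("explicit group assignment drives the taxa simulator", {
  groups <- tibble::tibble(donor_id = sprintf("d%d", 1:6),
                           synergy_label = rep(c("synergy", "no_synergy"), 3))
  sim <- simulate_taxa_counts(taxa_config(n_taxa = 10, groups = groups,
                                          timepoint = "baseline", seed = 1))
  expect_setequal(sim$metadata$donor_id, groups$donor_id)
  expect_identical(unique(sim$metadata$timepoint), "baseline")
  expect_equal(sum(sim$metadata$synergy_label == "synergy"), 3)
})

test_that("latent-factor taxa share high rank correlation, background does not", {
  sim <- simulate_latent_taxa(n_taxa = 12, n_samples = 80,
                              loadings = c(taxon_01 = 0.9, taxon_02 = 0.9),
                              seed = 21)
  tc <- taxa_correlation_matrix(sim$counts, prevalence_min = 0)
  expect_gt(tc$rho["taxon_01", "taxon_02"], 0.6)
  off <- tc$rho["taxon_05", "taxon_09"]
  expect_lt(abs(off), 0.4)
})
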