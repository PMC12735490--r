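test_that("paired tests honour identity, suppression and antisymmetry", {
  x <- c(5, 7, 9, 6)
  idt <- paired_test(x, x)
  expect_equal(idt$statistic, 0)
  expect_equal(idt$p_raw, 1)

  sup <- paired_test(c(1, 2), c(3, 4))
  expect_true(sup$suppressed)
  expect_true(is.na(sup$p_raw))

  y <- c(4, 6, 7, 6.5)
  ab <- paired_test(x, y)
  ba <- paired_test(y, x)
  expect_equal(ab$p_raw, ba$p_raw)
  expect_equal(ab$estimate, -ba$estimate)
  wab <- paired_test(x, y, method = "wilcoxon")
  wba <- paired_test(y, x, method = "wilcoxon")
  expect_equal(wab$p_raw, wba$p_raw)
})

test_that("paired test p-values agree with enumeration oracles", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      x <- rnorm(6, 1)
      y <- rnorm(6)
      # wilcoxon two-sided p equals exact signed-rank enumeration
      w <- paired_test(x, y, method = "wilcoxon")
      expect_equal(w$p_raw, signed_rank_exact_ref(x - y), tolerance = 1e-12)
      # t p is close to the exact sign-flip permutation p; at n = 6 the
      # permutation null has granularity 2/64, so agreement is coarse
      tt <- paired_test(x, y, method = "t")
      d <- x - y
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
      tstat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
      tperm <- apply(signs, 1, function(s) abs(tstat(s * d)))
      p_perm <- mean(tperm >= abs(tstat(d)) - 1e-12)
      expect_lt(abs(tt$p_raw - p_perm), 0.35)
    }
  })
})

test_that("degenerate paired differences report the method's limit", {
  expect_warning(r <- paired_test(c(2, 3, 4), c(1, 2, 3)), "constant")
  expect_equal(r$p_raw, 0)
  expect_true(is.infinite(r$statistic))
})

test_that("Tukey contrasts handle identity, planted shifts and suppression", {
  grid <- tidyr::expand_grid(donor_id = sprintf("d%d", 1:6),
                             substrate = c("a", "b", "c", "d", "mixture"))
  flat <- dplyr::mutate(grid, concentration_mM = 5)
  tk <- tukey_contrasts(flat)
  expect_equal(nrow(tk), 10)
  expect_true(all(tk$p_adjusted == 1))
  expect_true(all(tk$estimate == 0))

  shifted <- dplyr::mutate(flat, concentration_mM = 5 +
                             10 * (substrate == "mixture"))
  tks <- tukey_contrasts(shifted)
  hit <- grepl("mixture", tks$comparison)
  expect_true(all(tks$significant[hit]))
  expect_true(all(!tks$significant[!hit]))

  two <- dplyr::filter(flat, donor_id %in% c("d1", "d2"))
  expect_true(all(tukey_contrasts(two)$suppressed))
})

test_that("donor blocking absorbs donor-level offsets", {
  withr::with_seed(7, {
    grid <- tidyr::expand_grid(donor_id = sprintf("d%d", 1:8),
                               substrate = c("a", "b", "c", "d", "mixture"))
    donor_fx <- stats::setNames(rnorm(8, sd = 12), sprintf("d%d", 1:8))
    df <- dplyr::mutate(
      grid,
      concentration_mM = 10 + donor_fx[donor_id] +
        2 * (substrate == "mixture") + rnorm(dplyr::n(), sd = 0.5)
    )
    blocked <- tukey_contrasts(df, blocked = TRUE)
    pooled <- tukey_contrasts(df, blocked = FALSE)
    hit <- grepl("mixture", blocked$comparison)
    expect_true(all(blocked$significant[hit]))
    # huge donor variance swamps the pooled residual
    expect_false(any(pooled$significant[hit]))
  })
})

test_that("a donor with a missing substrate is dropped with a message", {
  grid <- tidyr::expand_grid(donor_id = sprintf("d%d", 1:5),
                             substrate = c("a", "b", "c", "d", "mixture"))
  df <- dplyr::mutate(grid, concentration_mM = seq_len(25) / 3)
  df <- df[-1, ]
  expect_message(tk <- tukey_contrasts(df), "d1")
  expect_equal(nrow(tk), 10)
})

test_that("BH and Holm-Sidak match the textbook step procedures exactly", {
  expect_equal(adjust_pvalues(0.03, "bh"), 0.03)
  expect_equal(adjust_pvalues(0.03, "holm_sidak"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm_sidak"),
               c(1 - (1 - 0.01)^2, 0.04))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "0, 1")

  withr::with_seed(5, {
    for (rep in 1:200) {
      m <- sample(1:20, 1)
      p <- runif(m)
      expect_equal(adjust_pvalues(p, "bh"), bh_ref(p), tolerance = 1e-15)
      expect_equal(adjust_pvalues(p, "holm_sidak"), holm_sidak_ref(p),
                   tolerance = 1e-15)
    }
  })
})

test_that("observed-vs-expected suite emits one BH family of per-cell tests", {
  sim <- simulate_fermentation(ferm_config(synergy_mean = 0, synergy_sd = 0,
                                           noise_sd = 0, seed = 3))
  syn <- compute_synergy(sim$fermentation)
  out <- observed_vs_expected_suite(syn)
  expect_equal(nrow(out), 16)   # 4 conditions x 4 scfa types
  expect_true(all(out$p_raw[!out$suppressed] == 1))

  # strong homogeneous synergy: every total-SCFA cell significant
  sim2 <- simulate_fermentation(ferm_config(synergy_mean = 30, synergy_sd = 5,
                                            noise_sd = 0.1, seed = 23))
  out2 <- observed_vs_expected_suite(compute_synergy(sim2$fermentation))
  tot <- out2[out2$scfa_type == "total", ]
  expect_true(all(tot$significant))
  expect_true(all(out2$p_adjusted >= out2$p_raw, na.rm = TRUE))
})

test_that("suppressed cells stay out of the BH family", {
  sim <- simulate_fermentation(ferm_config(conditions = c(HC = 5L, UC = 2L),
                                           seed = 2))
  syn <- compute_synergy(sim$fermentation)
  out <- observed_vs_expected_suite(syn)
  uc <- out[out$condition == "UC", ]
  expect_true(all(uc$suppressed))
  expect_true(all(is.na(uc$p_adjusted)))
})

test_that("synergy comparisons across conditions flag a planted shift", {
  base <- ferm_config(synergy_mean = 10, synergy_sd = 8, noise_sd = 0.1,
                      seed = 41)
  sim <- simulate_fermentation(base)
  syn <- compute_synergy(sim$fermentation)
  # shift HC donors' synergy far upward by editing retained records
  syn$synergy_pct[syn$condition == "HC"] <-
    syn$synergy_pct[syn$condition == "HC"] + 60
  out <- synergy_comparison_suite(syn, "across_conditions")
  tot <- out[out$family == "total" & !out$suppressed, ]
  hc <- grepl("HC", tot$comparison)
  expect_true(all(tot$significant[hc]))
  expect_true(all(out$p_adjusted >= out$p_raw, na.rm = TRUE))
})

test_that("a Holm-Sidak family of one leaves the p-value unchanged", {
  rec <- tibble::tibble(
    donor_id = rep(sprintf("d%d", 1:6), 2),
    condition = rep(c("HC", "UC"), each = 6),
    scfa_type = "total",
    observed_mM = 2, expected_mM = 1,
    synergy_pct = withr::with_seed(2, rnorm(12, c(10, 30))),
    filter_status = "retained"
  )
  out <- synergy_comparison_suite(rec, "across_conditions")
  expect_equal(nrow(out), 1)
  expect_equal(out$p_adjusted, out$p_raw)
})

test_that("within-condition comparisons pair SCFA types on shared donors", {
  sim <- simulate_fermentation(ferm_config(seed = 15))
  syn <- compute_synergy(sim$fermentation)
  out <- synergy_comparison_suite(syn, "across_scfa_within_condition")
  expect_setequal(unique(out$family), unique(syn$condition))
  expect_true(all(out$n[!out$suppressed] >= 3))
})
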