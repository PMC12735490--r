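test_that("the additive expectation is the mean of the four fiber values", {
  expect_identical(expected_additive(c(4, 4, 4, 4)), 4)
  expect_identical(expected_additive(c(2, 4, 6, 8)), 5)
  expect_identical(expected_additive(c(0, 0, 0, 0)), 0)
  expect_error(expected_additive(c(1, 2, 3)), "4 fiber")
  expect_error(expected_additive(c(pectin = 1, fos = NA, a = 2, b = 3)), "fos")
  expect_error(expected_additive(c(1, 2, 3, -1)), ">= 0")
})

test_that("the synergy statistic is the relative excess in percent", {
  expect_equal(synergy_percent(10, 10), 0)
  expect_equal(synergy_percent(15, 10), 50)
  expect_equal(synergy_percent(5, 10), -50)
  expect_error(synergy_percent(5, 0), class = "fibersynergy_zero_expected")
  # scale invariance over random positive expectations
  withr::with_seed(1, {
    e <- runif(50, 0.1, 100)
    expect_equal(synergy_percent(e, e), rep(0, 50))
    expect_equal(synergy_percent(2 * e, e), rep(100, 50))
  })
})

test_that("filters fire on measurement error, detection limit and zero expectation", {
  rec <- tibble::tibble(
    observed_mM = c(5.4, 0.8, 8.0, 0.0),
    expected_mM = c(5.0, 1.5, 5.0, 0.0)
  )
  out <- apply_synergy_filters(rec, filter_config())
  expect_identical(out$filter_status,
                   c("excluded_measurement_error", "excluded_detection_limit",
                     "retained", "excluded_zero_expected"))
  # under the conjunctive rule a single firing test is not enough
  out_all <- apply_synergy_filters(rec, filter_config(combine_rule = "all"))
  expect_identical(out_all$filter_status[1:3],
                   c("retained", "retained", "retained"))
  both <- apply_synergy_filters(
    tibble::tibble(observed_mM = 0.8, expected_mM = 0.95),
    filter_config(combine_rule = "all")
  )
  expect_identical(both$filter_status, "excluded_measurement_error")
})

test_that("filter annotation is idempotent and order-independent", {
  syn <- compute_synergy(simulate_fermentation(ferm_config(seed = 9))$fermentation)
  again <- apply_synergy_filters(syn, filter_config())
  expect_identical(syn, again)
  shuffled <- withr::with_seed(2, syn[sample(nrow(syn)), ])
  re <- apply_synergy_filters(shuffled, filter_config())
  expect_identical(re$filter_status,
                   syn$filter_status[match(
                     paste(shuffled$donor_id, shuffled$scfa_type),
                     paste(syn$donor_id, syn$scfa_type)
                   )])
})

test_that("synergy records satisfy the defining identity when retained", {
  syn <- compute_synergy(simulate_fermentation(ferm_config(seed = 13))$fermentation)
  k <- syn$filter_status == "retained"
  expect_lt(max(abs(
    syn$synergy_pct[k] -
      (syn$observed_mM[k] - syn$expected_mM[k]) / syn$expected_mM[k] * 100
  )), 1e-9)
  expect_true(all(syn$expected_mM[k] > 0))
})

test_that("compute_synergy reports a donor's missing fiber substrate", {
  ferm <- tiny_ferm()
  broken <- dplyr::filter(ferm, !(donor_id == "d2" & substrate == "fos" &
                                    scfa_type == "acetate"))
  expect_error(compute_synergy(broken), "d2.*fos|fos.*d2")
})

test_that("group summaries honour the minimum-n reporting gate", {
  rec <- tibble::tibble(
    condition = c("HC", "HC", "HC", "UC", "UC"),
    scfa_type = "total",
    observed_mM = c(10, 15, 20, 10, 12),
    expected_mM = c(5, 5, 5, 5, 5),
    synergy_pct = c(100, 200, 300, 100, 140),
    filter_status = "retained"
  )
  s <- summarize_synergy(rec, by = "condition")
  expect_identical(s$stats_suppressed, c(FALSE, TRUE))
  vals <- summarize_synergy(
    tibble::tibble(condition = "HC", scfa_type = "total",
                   observed_mM = 1, expected_mM = 1,
                   synergy_pct = c(0, 50, 100), filter_status = "retained"),
    by = character()
  )
  expect_equal(vals$mean, 50)
  expect_equal(vals$median, 50)
})

test_that("summaries can use all computed records instead of retained ones", {
  rec <- tibble::tibble(
    condition = "HC", scfa_type = "total",
    observed_mM = c(5.2, 9), expected_mM = c(5, 5),
    synergy_pct = c(4, 80),
    filter_status = c("excluded_measurement_error", "retained")
  )
  expect_equal(summarize_synergy(rec, by = character())$mean, 80)
  expect_equal(summarize_synergy(rec, by = character(), use = "computed")$mean, 42)
})

test_that("donors are classified from total synergy with acid-level fallback", {
  rec <- tibble::tibble(
    donor_id = c("a", "a", "b", "c", "c", "d"),
    condition = "HC",
    scfa_type = c("total", "acetate", "total", "acetate", "butyrate", "total"),
    observed_mM = 1, expected_mM = 1,
    synergy_pct = c(40, -90, -10, 30, 10, 50),
    filter_status = c("retained", "retained", "retained", "retained",
                      "retained", "excluded_detection_limit")
  )
  lab <- classify_donors(rec)
  expect_identical(lab$synergy_label[match(c("a", "b", "c", "d"), lab$donor_id)],
                   c("synergy", "no_synergy", "synergy", "unassigned"))
})

test_that("per-SCFA strata split retained donors by synergy sign", {
  rec <- tibble::tibble(
    donor_id = c("a", "b", "c"), condition = "HC", scfa_type = "acetate",
    observed_mM = 1, expected_mM = 1,
    synergy_pct = c(25, -5, 10),
    filter_status = c("retained", "retained", "excluded_detection_limit")
  )
  st <- synergy_strata(rec)
  expect_identical(st$stratum[st$donor_id == "a"], "acetate-synergy")
  expect_identical(st$stratum[st$donor_id == "b"], "acetate-no_synergy")
  expect_false("c" %in% st$donor_id)
})
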