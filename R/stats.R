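#' Paired two-tailed test on donor-matched values
#'
#' Paired t-test (default) or Wilcoxon signed-rank test on donor-matched
#' measurement pairs, honouring the n < 3 reporting gate: with fewer
#' than `n_min` complete pairs the result row is emitted with
#' `suppressed = TRUE` and no p-value. When the paired differences have
#' zero variance the method's degenerate limit is reported (statistic 0,
#' p = 1 for identical vectors; p = 0 with a warning for a constant
#' non-zero shift under the t method).
#'
#' @param x,y Numeric vectors of equal length, paired by donor.
#' @param method `"t"` or `"wilcoxon"`.
#' @param n_min Minimum number of complete pairs.
#' @param alpha Significance level used for the `significant` flag.
#' @param label Optional comparison label.
#' @return One-row tibble: `comparison`, `method`, `n`, `estimate`
#'   (mean of x - y), `statistic`, `p_raw`, `significant`, `suppressed`.
#' @examples
#' paired_test(c(5, 7, 9, 6), c(4, 6, 7, 6))
#' @export
paired_test <- function(x, y, method = c("t", "wilcoxon"), n_min = 3L,
                        alpha = 0.05, label = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  d <- x - y
  # differences below 1e-9 relative to the data scale are numerical
  # zeros (mM concentrations carry nowhere near that precision)
  if (n > 0) {
    scale <- max(abs(c(x, y)), 1)
    d[abs(d) < 1e-9 * scale] <- 0
  }
  row <- tibble::tibble(
    comparison = label %||% "x vs y", method = method, n = n,
    estimate = if (n > 0) mean(d) else NA_real_,
    statistic = NA_real_, p_raw = NA_real_,
    significant = NA, suppressed = n < n_min
  )
  if (row$suppressed) return(row)

  if (sd(d) == 0) {
    if (mean(d) == 0) {
      row$statistic <- 0; row$p_raw <- 1
    } else {
      warn("paired differences are constant and non-zero; reporting the degenerate limit.")
      if (method == "t") {
        row$statistic <- sign(mean(d)) * Inf; row$p_raw <- 0
      } else {
        # exact signed-rank: all mass on one sign
        row$statistic <- if (mean(d) > 0) n * (n + 1) / 2 else 0
        row$p_raw <- min(1, 2 * 0.5^n)
      }
    }
  } else if (method == "t") {
    ht <- t.test(d)
    row$statistic <- unname(ht$statistic); row$p_raw <- ht$p.value
  } else {
    ht <- suppressWarnings(wilcox.test(d))
    row$statistic <- unname(ht$statistic); row$p_raw <- ht$p.value
  }
  row$significant <- row$p_raw < alpha
  row
}

#' Tukey pairwise contrasts between substrates within one condition
#'
#' All pairwise substrate contrasts (4 fibers + mixture gives 10) via the
#' studentized-range procedure on a donor-blocked one-way layout:
#' by default the donor effect is removed (`value ~ donor + substrate`)
#' before the residual mean square enters the Tukey statistic, matching
#' a repeated-measures design; `blocked = FALSE` pools residuals.
#' Donors missing any substrate are dropped (reported via a message);
#' with fewer than `n_min` complete donors the contrasts are emitted
#' suppressed.
#'
#' @param data Tibble with one value per donor and substrate.
#' @param value,substrate,donor Names of the respective columns.
#' @param blocked Remove the donor effect before testing (default TRUE).
#' @param n_min Minimum number of complete donors.
#' @param alpha Family-wise significance level.
#' @return Tibble of contrasts: `comparison`, `estimate`, `conf.low`,
#'   `conf.high`, `p_adjusted`, `significant`, `suppressed`.
#' @export
tukey_contrasts <- function(data, value = "concentration_mM",
                            substrate = "substrate", donor = "donor_id",
                            blocked = TRUE, n_min = 3L, alpha = 0.05) {
  assert_columns(data, c(value, substrate, donor), "contrast input")
  df <- tibble::tibble(
    value = data[[value]],
    substrate = factor(data[[substrate]]),
    donor = factor(data[[donor]])
  )
  # keep donors with one value for every substrate
  n_sub <- nlevels(df$substrate)
  complete <- df |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$substrate) == n_sub,
                     .by = "donor")
  dropped <- complete$donor[!complete$ok]
  if (length(dropped) > 0L) {
    inform(sprintf("tukey_contrasts: dropping donor(s) with missing substrates: %s.",
                   paste(dropped, collapse = ", ")))
    df <- dplyr::filter(df, !.data$donor %in% dropped)
    df$donor <- droplevels(df$donor)
  }
  pairs <- utils::combn(levels(df$substrate), 2)
  skeleton <- tibble::tibble(
    comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
    estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
    p_adjusted = NA_real_, significant = NA, suppressed = TRUE
  )
  if (nlevels(df$donor) < n_min) return(skeleton)

  means <- tapply(df$value, df$substrate, mean)
  fit <- if (blocked) aov(value ~ donor + substrate, data = df)
         else aov(value ~ substrate, data = df)
  mse <- sum(fit$residuals^2) / fit$df.residual
  rng <- diff(range(df$value))
  if (mse <= 1e-20 * max(rng, 1)^2) {
    # degenerate: residual variance is numerically zero; contrasts are
    # exact, so any non-trivial mean difference is certain
    est <- means[pairs[2, ]] - means[pairs[1, ]]
    return(dplyr::mutate(
      skeleton,
      estimate = unname(est),
      p_adjusted = ifelse(abs(est) <= 1e-9 * max(rng, 1), 1, 0),
      significant = .data$p_adjusted < alpha,
      suppressed = FALSE
    ))
  }
  tk <- TukeyHSD(fit, "substrate", conf.level = 1 - alpha)$substrate
  tibble::tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"], conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
    p_adjusted = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    suppressed = FALSE
  )
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up false-discovery-rate control, or
#' Holm-Sidak step-down family-wise-error control
#' (\eqn{\tilde p_{(i)} = \max_{j \le i} [1 - (1 - p_{(j)})^{m-j+1}]},
#' clipped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` or `"holm_sidak"`.
#' @return Adjusted p-values in the original order.
#' @examples
#' adjust_pvalues(c(0.01, 0.04), "holm_sidak") # 0.0199 0.0400
#' @export
adjust_pvalues <- function(p, method = c("bh", "holm_sidak")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("all p-values must lie in [0, 1].")
  }
  if (method == "bh") {
    return(p.adjust(p, method = "BH"))
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Observed vs expected mixture performance, per condition and SCFA type
#'
#' One paired two-tailed test per (condition, SCFA type) comparing the
#' observed mixture concentration with each donor's additive
#' expectation, with Benjamini-Hochberg correction applied across the
#' whole family of emitted tests. Cells with fewer than `n_min` donors
#' are suppressed (reported without p-values) and do not enter the BH
#' family.
#'
#' By default all computed records enter the tests (`records = "all"`;
#' only zero-expectation records are unusable) — the
#' measurement-error/detection-limit filters condition on the very
#' difference being tested and belong to the synergy quantification, not
#' here. Set `records = "retained"` to test post-filter records.
#'
#' @param synergy Synergy tibble from [compute_synergy()].
#' @param method `"t"` or `"wilcoxon"`.
#' @param records `"all"` or `"retained"`.
#' @param n_min Minimum donors per cell.
#' @param alpha Significance level after adjustment.
#' @return Tibble: `condition`, `scfa_type`, `n`, `estimate`,
#'   `statistic`, `p_raw`, `p_adjusted`, `adjust_method`, `significant`,
#'   `suppressed`.
#' @export
observed_vs_expected_suite <- function(synergy, method = c("t", "wilcoxon"),
                                       records = c("all", "retained"),
                                       n_min = 3L, alpha = 0.05) {
  method <- match.arg(method)
  records <- match.arg(records)
  assert_columns(synergy, c("donor_id", "condition", "scfa_type",
                            "observed_mM", "expected_mM", "filter_status"),
                 "synergy table")
  use <- if (records == "retained") {
    dplyr::filter(synergy, .data$filter_status == "retained")
  } else {
    dplyr::filter(synergy, .data$filter_status != "excluded_zero_expected")
  }
  out <- use |>
    dplyr::reframe(
      paired_test(.data$observed_mM, .data$expected_mM, method = method,
                  n_min = n_min, alpha = alpha),
      .by = c("condition", "scfa_type")
    ) |>
    dplyr::select(-"comparison", -"method", -"significant")
  emitted <- !out$suppressed
  out$p_adjusted <- NA_real_
  out$p_adjusted[emitted] <- adjust_pvalues(out$p_raw[emitted], "bh")
  out$adjust_method <- "bh"
  out$significant <- out$p_adjusted < alpha
  out
}

#' Synergy comparisons across conditions or between SCFA types
#'
#' Across conditions (`axis = "across_conditions"`): for each SCFA type,
#' every pair of conditions is compared on retained synergy percentages
#' with an unpaired Welch t-test (or Wilcoxon rank-sum), since filtering
#' produces unequal group sizes; Holm-Sidak adjustment is applied within
#' each SCFA type's family.
#'
#' Within condition (`axis = "across_scfa_within_condition"`): for each
#' condition, every pair of SCFA types is compared with a paired test on
#' the donors retained for both types; Holm-Sidak adjustment per
#' condition family.
#'
#' @param synergy Synergy tibble from [compute_synergy()].
#' @param axis Comparison axis (see above).
#' @param method `"t"` or `"wilcoxon"`.
#' @param n_min Minimum group size / pair count.
#' @param alpha Significance level after adjustment.
#' @return Tibble: `family`, `comparison`, `scfa_type` or `condition`,
#'   `n`, `estimate`, `statistic`, `p_raw`, `p_adjusted`,
#'   `adjust_method`, `significant`, `suppressed`.
#' @export
synergy_comparison_suite <- function(synergy,
                                     axis = c("across_conditions",
                                              "across_scfa_within_condition"),
                                     method = c("t", "wilcoxon"),
                                     n_min = 3L, alpha = 0.05) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  assert_columns(synergy, c("donor_id", "condition", "scfa_type",
                            "synergy_pct", "filter_status"), "synergy table")
  kept <- dplyr::filter(synergy, .data$filter_status == "retained")

  rows <- list()
  if (axis == "across_conditions") {
    for (scfa in unique(kept$scfa_type)) {
      sub <- dplyr::filter(kept, .data$scfa_type == scfa)
      conds <- sort(unique(sub$condition))
      if (length(conds) < 2L) next
      prs <- utils::combn(conds, 2)
      for (j in seq_len(ncol(prs))) {
        a <- sub$synergy_pct[sub$condition == prs[1, j]]
        b <- sub$synergy_pct[sub$condition == prs[2, j]]
        rows[[length(rows) + 1L]] <- two_sample_row(
          a, b, method, n_min,
          family = scfa, comparison = paste(prs[1, j], prs[2, j], sep = " vs ")
        )
      }
    }
  } else {
    wide <- kept |>
      dplyr::select("donor_id", "condition", "scfa_type", "synergy_pct") |>
      tidyr::pivot_wider(names_from = "scfa_type", values_from = "synergy_pct")
    types <- intersect(SCFA_TYPES, unique(kept$scfa_type))
    for (cond in sort(unique(wide$condition))) {
      sub <- dplyr::filter(wide, .data$condition == cond)
      if (length(types) < 2L) next
      prs <- utils::combn(types, 2)
      for (j in seq_len(ncol(prs))) {
        x <- sub[[prs[1, j]]]
        y <- sub[[prs[2, j]]]
        ok <- !is.na(x) & !is.na(y)
        pt <- paired_test(x[ok], y[ok], method = method, n_min = n_min,
                          label = paste(prs[1, j], prs[2, j], sep = " vs "))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          family = cond, comparison = pt$comparison, n = pt$n,
          estimate = pt$estimate, statistic = pt$statistic,
          p_raw = pt$p_raw, suppressed = pt$suppressed
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      family = character(), comparison = character(), n = integer(),
      estimate = double(), statistic = double(), p_raw = double(),
      p_adjusted = double(), adjust_method = character(),
      significant = logical(), suppressed = logical()
    ))
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("family", "comparison", "n", "estimate", "statistic",
                  "p_raw", "suppressed")
  out$p_adjusted <- NA_real_
  for (fam in unique(out$family)) {
    idx <- which(out$family == fam & !out$suppressed)
    if (length(idx) > 0L) {
      out$p_adjusted[idx] <- adjust_pvalues(out$p_raw[idx], "holm_sidak")
    }
  }
  out$adjust_method <- "holm_sidak"
  out$significant <- out$p_adjusted < alpha
  out
}

# Welch t (or rank-sum) two-sample comparison as one result row
two_sample_row <- function(a, b, method, n_min, family, comparison) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  row <- tibble::tibble(
    family = family, comparison = comparison,
    n = length(a) + length(b),
    estimate = mean(a) - mean(b),
    statistic = NA_real_, p_raw = NA_real_,
    suppressed = length(a) < n_min || length(b) < n_min
  )
  if (row$suppressed) return(row)
  if (sd(c(a - mean(a), b - mean(b))) == 0) {
    row$statistic <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    row$p_raw <- if (mean(a) == mean(b)) 1 else 0
    return(row)
  }
  ht <- if (method == "t") t.test(a, b)
        else suppressWarnings(wilcox.test(a, b))
  row$statistic <- unname(ht$statistic)
  row$p_raw <- ht$p.value
  row
}
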