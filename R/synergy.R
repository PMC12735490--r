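#' Additive expectation for a fiber mixture
#'
#' The null model for an equal-proportion (25% each) four-fiber mixture:
#' the expected SCFA concentration is the arithmetic mean of the four
#' individual fiber concentrations measured for the same donor.
#'
#' @param fiber_values Numeric vector of exactly 4 finite, non-negative
#'   concentrations (mM), optionally named by substrate.
#' @return The additive-expected concentration in mM.
#' @examples
#' expected_additive(c(2, 4, 6, 8)) # 5
#' @export
expected_additive <- function(fiber_values) {
  if (length(fiber_values) != 4L) {
    nm <- names(fiber_values)
    abort(sprintf(
      "expected exactly 4 fiber concentrations, got %d%s.",
      length(fiber_values),
      if (!is.null(nm)) sprintf(" (%s)", paste(nm, collapse = ", ")) else ""
    ))
  }
  if (anyNA(fiber_values) || any(!is.finite(fiber_values))) {
    nm <- names(fiber_values) %||% as.character(seq_along(fiber_values))
    bad <- nm[!is.finite(fiber_values)]
    abort(sprintf("missing/non-finite concentration for substrate(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if (any(fiber_values < 0)) abort("fiber concentrations must be >= 0.")
  mean(fiber_values)
}

#' Synergy percentage
#'
#' Relative excess of the observed mixture concentration over the
#' additive expectation: `(observed - expected) / expected * 100`.
#'
#' @param observed Observed mixture concentration(s), mM.
#' @param expected Additive-expected concentration(s), mM; must be > 0.
#' @return Synergy in percent (vectorised).
#' @examples
#' synergy_percent(15, 10) # 50
#' @export
synergy_percent <- function(observed, expected) {
  if (any(!is.finite(observed)) || any(!is.finite(expected))) {
    abort("`observed` and `expected` must be finite.")
  }
  if (any(expected <= 0)) {
    abort("synergy is undefined for expected <= 0 mM; flag such records instead.",
          class = "fibersynergy_zero_expected")
  }
  (observed - expected) / expected * 100
}

#' Filtering thresholds for synergy records
#'
#' @param error_threshold Records with `|observed - expected| <=` this
#'   value (mM) are within measurement error and excluded. Default 0.5.
#' @param detection_limit Records where observed or expected falls below
#'   this value (mM) are excluded. Default 1.0.
#' @param n_min Minimum group size for reporting statistics. Default 3.
#' @param combine_rule `"any"` (default): a record is excluded if either
#'   exclusion test fires; `"all"`: only if both fire.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(error_threshold = 0.5, detection_limit = 1.0,
                          n_min = 3L, combine_rule = c("any", "all")) {
  assert_scalar_number(error_threshold, "error_threshold", min = 0)
  assert_scalar_number(detection_limit, "detection_limit", min = 0)
  n_min <- as.integer(n_min)
  if (is.na(n_min) || n_min < 1L) abort("`n_min` must be an integer >= 1.")
  structure(
    list(error_threshold = error_threshold, detection_limit = detection_limit,
         n_min = n_min, combine_rule = match.arg(combine_rule)),
    class = "filter_config"
  )
}

#' Compute per-donor synergy records from a fermentation table
#'
#' For every (donor, SCFA type): the additive expectation is the mean of
#' the four individual fiber concentrations, the observed value is the
#' mixture concentration, and synergy is their relative difference in
#' percent. Records are then annotated with a filter status via
#' [apply_synergy_filters()].
#'
#' @param ferm Long fermentation tibble with columns `donor_id`,
#'   `condition`, `substrate`, `scfa_type`, `concentration_mM`.
#' @param filter A [filter_config()].
#' @param mixture_label Substrate label identifying the mixture.
#' @return Tibble with one row per (donor, SCFA type): `donor_id`,
#'   `condition`, `scfa_type`, `observed_mM`, `expected_mM`,
#'   `synergy_pct` (NA when expected is 0), `filter_status`.
#' @examples
#' sim <- simulate_fermentation(ferm_config(seed = 1))
#' compute_synergy(sim$fermentation)
#' @export
compute_synergy <- function(ferm, filter = filter_config(),
                            mixture_label = "mixture") {
  assert_columns(ferm, c("donor_id", "condition", "substrate", "scfa_type",
                         "concentration_mM"), "fermentation table")
  fibers <- setdiff(unique(ferm$substrate), mixture_label)
  # canonical reduction order, so the additive expectation is bitwise
  # reproducible regardless of row order
  fibers <- fibers[order(fibers, method = "radix")]
  if (length(fibers) != 4L) {
    abort(sprintf(
      "expected 4 fiber substrates besides '%s', found %d (%s).",
      mixture_label, length(fibers), paste(fibers, collapse = ", ")
    ))
  }
  if (!mixture_label %in% ferm$substrate) {
    abort(sprintf("no '%s' records in the fermentation table.", mixture_label))
  }

  wide <- ferm |>
    tidyr::pivot_wider(
      id_cols = c("donor_id", "condition", "scfa_type"),
      names_from = "substrate", values_from = "concentration_mM"
    )
  miss <- !complete.cases(wide[, fibers, drop = FALSE])
  if (any(miss)) {
    ex <- wide[which(miss)[1], ]
    missing_sub <- fibers[is.na(unlist(ex[fibers]))]
    abort(sprintf(
      "donor '%s' (%s) is missing fiber substrate(s): %s.",
      ex$donor_id, ex$scfa_type, paste(missing_sub, collapse = ", ")
    ))
  }

  out <- wide |>
    dplyr::mutate(
      observed_mM = .data[[mixture_label]],
      expected_mM = rowMeans(dplyr::pick(dplyr::all_of(fibers))),
      synergy_pct = dplyr::if_else(
        .data$expected_mM > 0,
        (.data$observed_mM - .data$expected_mM) / .data$expected_mM * 100,
        NA_real_
      )
    ) |>
    dplyr::select("donor_id", "condition", "scfa_type", "observed_mM",
                  "expected_mM", "synergy_pct")
  apply_synergy_filters(out, filter)
}

#' Annotate synergy records with a filter status
#'
#' Implements the uniform thresholds used before any synergy statistic:
#' a record is excluded when the observed-expected difference is within
#' measurement error (`|observed - expected| <= error_threshold`) or
#' when either value is below the detection limit; records whose
#' additive expectation is zero are flagged separately since the ratio
#' statistic is undefined there. Annotation is pure: no rows are
#' dropped, and re-applying the same config is idempotent.
#'
#' @param records Tibble with `observed_mM` and `expected_mM` columns.
#' @param filter A [filter_config()].
#' @return `records` with a `filter_status` column: one of `retained`,
#'   `excluded_measurement_error`, `excluded_detection_limit`,
#'   `excluded_zero_expected`.
#' @export
apply_synergy_filters <- function(records, filter = filter_config()) {
  assert_columns(records, c("observed_mM", "expected_mM"), "synergy records")
  obs <- records$observed_mM
  exp <- records$expected_mM
  err <- abs(obs - exp) <= filter$error_threshold
  det <- pmin(obs, exp) < filter$detection_limit
  excluded <- if (filter$combine_rule == "any") err | det else err & det
  status <- dplyr::case_when(
    exp <= 0 ~ "excluded_zero_expected",
    excluded & err ~ "excluded_measurement_error",
    excluded ~ "excluded_detection_limit",
    .default = "retained"
  )
  dplyr::mutate(records, filter_status = status)
}

#' Summarise synergy percentages by group
#'
#' Descriptive statistics of retained synergy percentages per group;
#' groups with fewer retained records than `n_min` are reported but
#' flagged `stats_suppressed`, honouring the n < 3 reporting gate.
#'
#' @param records Synergy tibble from [compute_synergy()].
#' @param by Grouping columns: any of `"condition"`, `"scfa_type"`, or
#'   `character()` for a single overall group.
#' @param n_min Minimum retained records per group.
#' @param use `"retained"` (default) summarises post-filter records, the
#'   reporting convention; `"computed"` summarises every record with a
#'   defined synergy percentage, the unbiased choice when estimating a
#'   population mean (the exclusion of within-measurement-error records
#'   asymmetrically trims values near zero).
#' @return Tibble of group columns plus `n`, `mean`, `sd`, `median`,
#'   `min`, `max`, `stats_suppressed`.
#' @export
summarize_synergy <- function(records, by = c("condition", "scfa_type"),
                              n_min = 3L, use = c("retained", "computed")) {
  use <- match.arg(use)
  assert_columns(records, c("synergy_pct", "filter_status"), "synergy records")
  kept <- if (use == "retained") {
    dplyr::filter(records, .data$filter_status == "retained")
  } else {
    dplyr::filter(records, !is.na(.data$synergy_pct))
  }
  kept |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$synergy_pct),
      sd = sd(.data$synergy_pct),
      median = median(.data$synergy_pct),
      min = min(.data$synergy_pct),
      max = max(.data$synergy_pct),
      .by = dplyr::all_of(by)
    ) |>
    dplyr::mutate(stats_suppressed = .data$n < n_min)
}

#' Classify donors as synergy / no-synergy
#'
#' A donor is labelled `synergy` when its retained total-SCFA synergy
#' percentage exceeds `threshold` (default 0). Donors without a retained
#' total record fall back to the mean of their retained acid-level
#' synergy values; donors with no retained records at all are
#' `unassigned`.
#'
#' @param records Synergy tibble from [compute_synergy()].
#' @param threshold Synergy percentage above which a donor counts as
#'   exhibiting synergy.
#' @return Tibble `donor_id`, `condition`, `synergy_label` with labels in
#'   `synergy`, `no_synergy`, `unassigned`.
#' @export
classify_donors <- function(records, threshold = 0) {
  assert_columns(records, c("donor_id", "condition", "scfa_type",
                            "synergy_pct", "filter_status"), "synergy records")
  records |>
    dplyr::summarise(
      total_syn = {
        k <- .data$filter_status == "retained"
        tot <- .data$synergy_pct[k & .data$scfa_type == "total"]
        if (length(tot) > 0) tot[1]
        else if (any(k)) mean(.data$synergy_pct[k])
        else NA_real_
      },
      .by = c("donor_id", "condition")
    ) |>
    dplyr::mutate(
      synergy_label = dplyr::case_when(
        is.na(.data$total_syn) ~ "unassigned",
        .data$total_syn > threshold ~ "synergy",
        .default = "no_synergy"
      )
    ) |>
    dplyr::select("donor_id", "condition", "synergy_label")
}

#' Per-SCFA synergy strata
#'
#' Stratum membership used by the co-occurrence network stage: for each
#' SCFA type, donors with a retained synergy percentage above the
#' threshold belong to the `<scfa>-synergy` stratum, retained donors at
#' or below it to `<scfa>-no_synergy`; filtered-out donors are omitted.
#'
#' @inheritParams classify_donors
#' @return Tibble `donor_id`, `condition`, `scfa_type`, `stratum`.
#' @export
synergy_strata <- function(records, threshold = 0) {
  assert_columns(records, c("donor_id", "condition", "scfa_type",
                            "synergy_pct", "filter_status"), "synergy records")
  records |>
    dplyr::filter(.data$filter_status == "retained") |>
    dplyr::mutate(stratum = paste0(
      .data$scfa_type, "-",
      dplyr::if_else(.data$synergy_pct > threshold, "synergy", "no_synergy")
    )) |>
    dplyr::select("donor_id", "condition", "scfa_type", "stratum")
}
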