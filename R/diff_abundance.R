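#' Estimate per-sample sampling fractions from log counts
#'
#' Compositional count data confound taxon abundance with each sample's
#' unknown sampling fraction (how much of the ecosystem ended up
#' sequenced). Following the bias-correction idea behind
#' compositionally aware differential-abundance methods, the per-sample
#' log sampling-fraction offset is estimated as the median across taxa
#' of the sample's log count minus its group's mean log count for that
#' taxon; the median makes the estimate robust to the minority of taxa
#' that are truly differential. Offsets are identifiable only up to a
#' global constant and are centred to mean zero.
#'
#' @param counts Taxa count table (tibble or taxa x samples matrix).
#' @param group Grouping factor/character vector, one entry per sample
#'   (in column order), or a metadata tibble with `sample_id` and
#'   `synergy_label`.
#' @param pseudocount Added to all counts before the log (default 1);
#'   may be 0 when all counts are positive.
#' @return Named numeric vector of per-sample offsets (mean 0).
#' @export
estimate_sampling_fractions <- function(counts, group, pseudocount = 1) {
  m <- taxa_matrix(counts)
  group <- resolve_groups(group, colnames(m))
  if (nrow(m) < 2L) abort("need >= 2 taxa to estimate sampling fractions.")
  tab <- table(group)
  if (any(tab < 2L)) {
    abort(sprintf("every group needs >= 2 samples; too small: %s.",
                  paste(names(tab)[tab < 2L], collapse = ", ")))
  }
  if (pseudocount == 0 && any(m == 0)) {
    abort("pseudocount = 0 requires strictly positive counts.")
  }
  y <- log(m + pseudocount)                       # taxa x samples
  centred <- y
  for (g in unique(group)) {
    idx <- group == g
    centred[, idx] <- y[, idx] - rowMeans(y[, idx, drop = FALSE])
  }
  offsets <- apply(centred, 2, median)
  offsets <- offsets - mean(offsets)
  setNames(offsets, colnames(m))
}

#' Bias-corrected differential abundance between synergy groups
#'
#' Compares synergy vs no-synergy donors taxon by taxon on
#' sampling-fraction-corrected log abundances. The procedure is a
#' deliberately transparent bias-correction scheme: (1) prevalence
#' filtering, (2) per-sample offset estimation via
#' [estimate_sampling_fractions()] on the tested taxa, (3) per-taxon
#' Welch t-test on `log(count + pseudocount) - offset`, giving a
#' natural-log fold change (synergy minus no-synergy) with its standard
#' error, (4) BH correction across tested taxa. Taxa entirely absent
#' from one group are reported as structural zeros and not tested.
#'
#' @param counts Taxa count table (tibble or taxa x samples matrix).
#' @param group Grouping as in [estimate_sampling_fractions()]; must
#'   contain exactly the labels `synergy` and `no_synergy` (samples with
#'   other labels are dropped).
#' @param prevalence_min A taxon is tested only if it is present in at
#'   least this fraction of the samples of at least one group
#'   (default 0.1).
#' @param pseudocount Added before logs (default 1).
#' @param alpha Significance level on BH-adjusted q-values.
#' @return Tibble of class `scfa_da`, tested taxa sorted by decreasing
#'   `lfc`: `taxon`, `status` (`tested`, `excluded_prevalence`,
#'   `structural_zero`), `lfc`, `se`, `statistic`, `df`, `p_raw`, `q`,
#'   `significant`.
#' @examples
#' sim <- simulate_taxa_counts(taxa_config(
#'   n_taxa = 30, enriched_taxa = c(taxon_05 = 4), seed = 1
#' ))
#' differential_abundance(sim$counts, sim$metadata)
#' @export
differential_abundance <- function(counts, group, prevalence_min = 0.1,
                                   pseudocount = 1, alpha = 0.05) {
  m <- taxa_matrix(counts)
  group <- resolve_groups(group, colnames(m))
  keep <- group %in% c("synergy", "no_synergy")
  if (!all(keep)) {
    m <- m[, keep, drop = FALSE]
    group <- group[keep]
  }
  for (g in c("synergy", "no_synergy")) {
    if (sum(group == g) < 2L) {
      abort(sprintf("group '%s' has fewer than 2 samples.", g))
    }
  }
  s1 <- group == "synergy"
  s2 <- group == "no_synergy"
  prev1 <- rowMeans(m[, s1, drop = FALSE] > 0)
  prev2 <- rowMeans(m[, s2, drop = FALSE] > 0)
  status <- dplyr::case_when(
    pmax(prev1, prev2) < prevalence_min ~ "excluded_prevalence",
    prev1 == 0 | prev2 == 0 ~ "structural_zero",
    .default = "tested"
  )
  tested <- status == "tested"
  if (sum(tested) < 2L) abort("nothing testable: fewer than 2 taxa pass the filters.")

  # pooled reference: per-group references identify offsets only up to
  # per-group constants, letting the groups' mean sampling-fraction
  # difference leak into every fold change; a pooled reference leaves a
  # single global constant, which cancels in the group contrast
  offsets <- estimate_sampling_fractions(m[tested, , drop = FALSE],
                                         rep("all", ncol(m)),
                                         pseudocount = pseudocount)
  y <- sweep(log(m[tested, , drop = FALSE] + pseudocount), 2, offsets)

  n1 <- sum(s1); n2 <- sum(s2)
  m1 <- rowMeans(y[, s1, drop = FALSE]); m2 <- rowMeans(y[, s2, drop = FALSE])
  v1 <- apply(y[, s1, drop = FALSE], 1, stats::var)
  v2 <- apply(y[, s2, drop = FALSE], 1, stats::var)
  lfc <- m1 - m2
  se <- sqrt(v1 / n1 + v2 / n2)
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tstat <- lfc / se
  p <- 2 * pt(-abs(tstat), df)
  q <- adjust_pvalues(p, "bh")

  res <- tibble::tibble(
    taxon = rownames(m), status = status,
    lfc = NA_real_, se = NA_real_, statistic = NA_real_, df = NA_real_,
    p_raw = NA_real_, q = NA_real_, significant = NA
  )
  res$lfc[tested] <- lfc
  res$se[tested] <- se
  res$statistic[tested] <- tstat
  res$df[tested] <- df
  res$p_raw[tested] <- p
  res$q[tested] <- q
  res$significant[tested] <- q < alpha
  res <- dplyr::arrange(res, .data$status != "tested", dplyr::desc(.data$lfc))
  class(res) <- c("scfa_da", class(res))
  attr(res, "n_per_group") <- c(synergy = n1, no_synergy = n2)
  attr(res, "alpha") <- alpha
  res
}

# normalize a grouping spec (vector or metadata tibble) to a character
# vector aligned with sample columns
resolve_groups <- function(group, sample_ids) {
  if (is.data.frame(group)) {
    assert_columns(group, c("sample_id", "synergy_label"), "metadata")
    idx <- match(sample_ids, group$sample_id)
    if (anyNA(idx)) {
      abort(sprintf("metadata is missing sample(s): %s.",
                    paste(sample_ids[is.na(idx)], collapse = ", ")))
    }
    return(as.character(group$synergy_label[idx]))
  }
  if (!is.null(names(group))) {
    idx <- match(sample_ids, names(group))
    if (anyNA(idx)) {
      abort(sprintf("group vector is missing sample(s): %s.",
                    paste(sample_ids[is.na(idx)], collapse = ", ")))
    }
    return(as.character(group[idx]))
  }
  if (length(group) != length(sample_ids)) {
    abort("`group` must have one entry per sample column.")
  }
  as.character(group)
}
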