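#' Configuration for the fermentation-table simulator
#'
#' Defines the statistical structure of a simulated in vitro fecal
#' fermentation experiment: a cohort of donors split across health
#' conditions, four individual fiber substrates plus their mixture, and
#' per-donor supra-additive mixture effects. The defaults mirror the
#' study design the package targets: 33 donors (HC 10, PD 10, CD 7,
#' UC 7), a four-fiber soluble mixture, and donor-level synergy drawn
#' from a normal distribution with mean 33% and sd 20%.
#'
#' Per-donor, per-fiber SCFA concentrations are drawn from a log-normal
#' distribution on the mM scale (location/scale per acid, optionally
#' rescaled per condition). Measurement noise is additive Gaussian on
#' the concentration scale, truncated at zero, as befits gas
#' chromatography error; the default `noise_sd` of 0.5 mM matches the
#' measurement-error threshold used by the downstream filter.
#'
#' @param conditions Named integer vector: donors per health condition.
#' @param fibers Character vector of exactly 4 fiber substrate labels.
#' @param scfa_types The three acids to simulate; `total` is always
#'   derived as their per-substrate sum.
#' @param base_meanlog,base_sdlog Named per-acid log-normal location and
#'   scale of per-donor per-fiber concentrations (mM).
#' @param condition_scale Optional named multiplier per condition applied
#'   to the concentration scale (default 1 for all).
#' @param synergy_mean,synergy_sd Mean and sd (%) of the injected
#'   per-donor synergy \eqn{\delta}.
#' @param per_scfa_delta If `TRUE`, draw an independent \eqn{\delta} per
#'   donor and acid instead of one per donor (stress-testing option).
#' @param noise_sd Additive measurement noise sd in mM (>= 0).
#' @param detection_limit Detection limit in mM carried in the config for
#'   downstream filtering defaults.
#' @param seed Optional integer seed; when set, generation is
#'   bit-reproducible and the caller's RNG state is untouched.
#' @return A list of class `ferm_config`.
#' @seealso [simulate_fermentation()]
#' @export
ferm_config <- function(conditions = c(HC = 10L, PD = 10L, CD = 7L, UC = 7L),
                        fibers = c("pectin", "beta_glucan", "fos", "arabinoxylan"),
                        scfa_types = c("acetate", "propionate", "butyrate"),
                        base_meanlog = c(acetate = log(22), propionate = log(8),
                                         butyrate = log(7)),
                        base_sdlog = c(acetate = 0.35, propionate = 0.40,
                                       butyrate = 0.45),
                        condition_scale = NULL,
                        synergy_mean = 33,
                        synergy_sd = 20,
                        per_scfa_delta = FALSE,
                        noise_sd = 0.5,
                        detection_limit = 1.0,
                        seed = NULL) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    abort("`conditions` must be a named vector of donor counts.")
  }
  conditions <- vapply(conditions, as.integer, 1L)
  if (any(conditions < 1L)) abort("`conditions`: every donor count must be >= 1.")
  if (length(fibers) != 4L || anyDuplicated(fibers)) {
    abort("`fibers` must contain exactly 4 distinct substrate labels.")
  }
  if (length(scfa_types) < 1L || !all(scfa_types %in% SCFA_ACIDS)) {
    abort("`scfa_types` must be a subset of acetate/propionate/butyrate.")
  }
  for (s in scfa_types) {
    if (is.na(base_meanlog[s])) abort(sprintf("`base_meanlog` is missing '%s'.", s))
    if (is.na(base_sdlog[s]) || base_sdlog[s] < 0) {
      abort(sprintf("`base_sdlog['%s']` must be a non-negative number.", s))
    }
  }
  assert_scalar_number(synergy_mean, "synergy_mean")
  assert_scalar_number(synergy_sd, "synergy_sd", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(detection_limit, "detection_limit", min = 0)
  if (is.null(condition_scale)) {
    condition_scale <- setNames(rep(1, length(conditions)), names(conditions))
  }
  structure(
    list(
      conditions = conditions, fibers = fibers, scfa_types = scfa_types,
      base_meanlog = base_meanlog, base_sdlog = base_sdlog,
      condition_scale = condition_scale,
      synergy_mean = synergy_mean, synergy_sd = synergy_sd,
      per_scfa_delta = isTRUE(per_scfa_delta),
      noise_sd = noise_sd, detection_limit = detection_limit,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "ferm_config"
  )
}

#' Simulate a long-format fermentation table with known ground truth
#'
#' Generates one concentration record per donor, substrate (4 fibers +
#' `"mixture"`) and SCFA type (three acids + derived `total`). For each
#' donor a synergy effect \eqn{\delta} is drawn from
#' `Normal(synergy_mean, synergy_sd)` and the mixture concentration of
#' each acid is built as the mean of the donor's four *recorded* fiber
#' values times \eqn{(1 + \delta/100)}, plus measurement noise, clamped
#' at zero. Totals are the exact per-substrate sum of the three acid
#' records, so the additive identity `total = acetate + propionate +
#' butyrate` holds by construction. With zero noise, the synergy
#' percentage recovered downstream equals the injected \eqn{\delta}
#' exactly for every acid and for the total.
#'
#' @param cfg A [ferm_config()].
#' @return A list of class `ferm_sim` with elements:
#'   * `fermentation`: tibble with columns `donor_id`, `condition`,
#'     `substrate`, `scfa_type`, `concentration_mM`;
#'   * `truth`: tibble with columns `donor_id`, `condition`, `scfa_type`,
#'     `delta_pct` — the injected synergy per donor (replicated per acid
#'     when a single donor-level draw is used).
#' @examples
#' sim <- simulate_fermentation(ferm_config(seed = 1))
#' dplyr::count(sim$fermentation, substrate)
#' @export
simulate_fermentation <- function(cfg = ferm_config()) {
  if (!inherits(cfg, "ferm_config")) cfg <- do.call(ferm_config, cfg)
  with_seed_if(cfg$seed, {
    cond <- rep(names(cfg$conditions), cfg$conditions)
    donor <- sprintf("%s%02d", cond, unlist(lapply(cfg$conditions, seq_len)))
    n_d <- length(donor)
    n_f <- length(cfg$fibers)
    acids <- cfg$scfa_types
    n_a <- length(acids)

    # fiber-level true concentrations, then measurement noise, clamped at 0
    # array [donor, fiber, acid]
    meanlog <- rep(cfg$base_meanlog[acids], each = n_d * n_f) +
      log(cfg$condition_scale[cond])
    sdlog <- rep(cfg$base_sdlog[acids], each = n_d * n_f)
    fib <- array(rlnorm(n_d * n_f * n_a, meanlog, sdlog), dim = c(n_d, n_f, n_a))
    if (cfg$noise_sd > 0) {
      fib <- fib + array(rnorm(length(fib), 0, cfg$noise_sd), dim = dim(fib))
    }
    fib <- pmax(fib, 0)

    # injected synergy: one draw per donor (replicated across acids) or
    # one per donor x acid
    if (cfg$per_scfa_delta) {
      delta <- matrix(rnorm(n_d * n_a, cfg$synergy_mean, cfg$synergy_sd),
                      nrow = n_d, ncol = n_a)
    } else {
      delta <- matrix(rnorm(n_d, cfg$synergy_mean, cfg$synergy_sd),
                      nrow = n_d, ncol = n_a)
    }

    # mixture built from the recorded fiber values; rowMeans matches the
    # reduction used downstream bit for bit, so the zero-noise identity
    # synergy == delta holds exactly
    ford <- order(cfg$fibers, method = "radix")
    fiber_mean <- vapply(seq_len(n_a),
                         function(a) rowMeans(matrix(fib[, ford, a],
                                                     nrow = n_d)),
                         numeric(n_d))                 # donor x acid
    mix <- fiber_mean * (1 + delta / 100)
    if (cfg$noise_sd > 0) {
      mix <- mix + matrix(rnorm(length(mix), 0, cfg$noise_sd), nrow = n_d)
    }
    mix <- pmax(mix, 0)

    # assemble long table: acids for 4 fibers + mixture, then derived totals
    rows_fib <- tibble::tibble(
      donor_id = rep(donor, times = n_f * n_a),
      condition = rep(cond, times = n_f * n_a),
      substrate = rep(rep(cfg$fibers, each = n_d), times = n_a),
      scfa_type = rep(acids, each = n_d * n_f),
      concentration_mM = as.vector(fib)
    )
    rows_mix <- tibble::tibble(
      donor_id = rep(donor, times = n_a),
      condition = rep(cond, times = n_a),
      substrate = "mixture",
      scfa_type = rep(acids, each = n_d),
      concentration_mM = as.vector(mix)
    )
    long <- dplyr::bind_rows(rows_fib, rows_mix)
    totals <- long |>
      dplyr::summarise(
        concentration_mM = sum(.data$concentration_mM),
        .by = c("donor_id", "condition", "substrate")
      ) |>
      dplyr::mutate(scfa_type = "total", .before = "concentration_mM")
    ferm <- dplyr::bind_rows(long, totals) |>
      dplyr::arrange(.data$donor_id, .data$substrate, .data$scfa_type)

    truth <- tibble::tibble(
      donor_id = rep(donor, times = n_a),
      condition = rep(cond, times = n_a),
      scfa_type = rep(acids, each = n_d),
      delta_pct = as.vector(delta)
    )
    structure(list(fermentation = ferm, truth = truth, config = cfg),
              class = "ferm_sim")
  })
}

#' Configuration for the taxa count-table simulator
#'
#' Counts are drawn from a Dirichlet-multinomial: each sample's
#' composition is a Dirichlet draw around a shared base composition, with
#' designated taxa's concentration parameters multiplied by their fold
#' change in the synergy group, and sequencing depth log-normal. The
#' default base composition follows a power-law rank-abundance profile
#' typical of 16S gut profiles, with total concentration 500 (moderate
#' overdispersion).
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param n_samples_per_group Named integer vector of samples per synergy
#'   label (default 12 `synergy`, 12 `no_synergy`); ignored when `groups`
#'   is supplied.
#' @param enriched_taxa Named numeric vector mapping taxon id to fold
#'   change (> 0; > 1 means enriched in the synergy group).
#' @param base_alpha Optional positive Dirichlet concentration vector of
#'   length `n_taxa`.
#' @param library_meanlog,library_sdlog Log-normal location/scale of
#'   sequencing depth.
#' @param timepoint Timepoint label stamped on the samples.
#' @param groups Optional tibble (`donor_id`, `synergy_label`) fixing the
#'   sample-to-group assignment, e.g. from [classify_donors()]; one
#'   sample is generated per donor.
#' @param seed Optional integer seed.
#' @return A list of class `taxa_config`.
#' @seealso [simulate_taxa_counts()]
#' @export
taxa_config <- function(n_taxa = 60L,
                        n_samples_per_group = c(synergy = 12L, no_synergy = 12L),
                        enriched_taxa = NULL,
                        base_alpha = NULL,
                        library_meanlog = log(5e4),
                        library_sdlog = 0.5,
                        timepoint = "post",
                        groups = NULL,
                        seed = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 2L) abort("`n_taxa` must be an integer >= 2.")
  if (is.null(groups)) {
    if (is.null(names(n_samples_per_group))) {
      abort("`n_samples_per_group` must be named by synergy label.")
    }
    n_samples_per_group <- vapply(n_samples_per_group, as.integer, 1L)
    if (any(n_samples_per_group < 2L)) {
      abort("`n_samples_per_group`: every group needs >= 2 samples.")
    }
  } else {
    assert_columns(groups, c("donor_id", "synergy_label"), "`groups`")
  }
  if (!is.null(enriched_taxa)) {
    enriched_taxa <- unlist(enriched_taxa)   # accept YAML/JSON maps
    if (is.null(names(enriched_taxa)) || !is.numeric(enriched_taxa) ||
        any(enriched_taxa <= 0)) {
      abort("`enriched_taxa` must be a named vector of positive fold changes.")
    }
  }
  if (is.null(base_alpha)) {
    p <- seq_len(n_taxa)^-0.8
    base_alpha <- 500 * p / sum(p)
  }
  if (length(base_alpha) != n_taxa || any(base_alpha <= 0)) {
    abort("`base_alpha` must be strictly positive with length `n_taxa`.")
  }
  assert_scalar_number(library_sdlog, "library_sdlog", min = 0)
  structure(
    list(
      n_taxa = n_taxa, n_samples_per_group = n_samples_per_group,
      enriched_taxa = enriched_taxa, base_alpha = base_alpha,
      library_meanlog = library_meanlog, library_sdlog = library_sdlog,
      timepoint = timepoint, groups = groups,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "taxa_config"
  )
}

#' Simulate a taxa count table with planted enrichment
#'
#' @param cfg A [taxa_config()].
#' @return A list of class `taxa_sim` with elements `counts` (tibble,
#'   `taxon` first column then one integer column per sample), `metadata`
#'   (tibble `sample_id`, `donor_id`, `timepoint`, `synergy_label`) and
#'   `truth` (tibble `taxon`, `fold_change`, `lfc` in natural log).
#' @examples
#' sim <- simulate_taxa_counts(taxa_config(
#'   n_taxa = 20, enriched_taxa = c(taxon_03 = 4), seed = 1
#' ))
#' sim$truth[sim$truth$fold_change > 1, ]
#' @export
simulate_taxa_counts <- function(cfg = taxa_config()) {
  if (!inherits(cfg, "taxa_config")) cfg <- do.call(taxa_config, cfg)
  with_seed_if(cfg$seed, {
    taxa <- sprintf("taxon_%02d", seq_len(cfg$n_taxa))
    if (!is.null(cfg$enriched_taxa)) {
      unknown <- setdiff(names(cfg$enriched_taxa), taxa)
      if (length(unknown) > 0L) {
        abort(sprintf("`enriched_taxa` names not among generated taxa: %s.",
                      paste(unknown, collapse = ", ")))
      }
    }
    if (is.null(cfg$groups)) {
      labels <- rep(names(cfg$n_samples_per_group), cfg$n_samples_per_group)
      donors <- sprintf("D%03d", seq_along(labels))
    } else {
      labels <- as.character(cfg$groups$synergy_label)
      donors <- as.character(cfg$groups$donor_id)
    }
    n_s <- length(labels)
    fold <- setNames(rep(1, cfg$n_taxa), taxa)
    fold[names(cfg$enriched_taxa)] <- cfg$enriched_taxa

    # Dirichlet draw per sample: enriched taxa get alpha * fold in the
    # synergy group only
    alpha <- matrix(cfg$base_alpha, nrow = cfg$n_taxa, ncol = n_s)
    alpha[, labels == "synergy"] <- alpha[, labels == "synergy"] * fold
    gam <- matrix(rgamma(cfg$n_taxa * n_s, shape = alpha), nrow = cfg$n_taxa)
    prob <- sweep(gam, 2, colSums(gam), "/")
    lib <- pmax(1, round(rlnorm(n_s, cfg$library_meanlog, cfg$library_sdlog)))
    counts <- vapply(seq_len(n_s),
                     function(s) rmultinom(1, size = lib[s], prob = prob[, s])[, 1],
                     integer(cfg$n_taxa))
    sample_id <- sprintf("%s_%s", donors, cfg$timepoint)
    dimnames(counts) <- list(taxa, sample_id)

    metadata <- tibble::tibble(
      sample_id = sample_id, donor_id = donors,
      timepoint = cfg$timepoint, synergy_label = labels
    )
    truth <- tibble::tibble(taxon = taxa, fold_change = unname(fold),
                            lfc = log(unname(fold)))
    structure(list(counts = taxa_tibble(counts), metadata = metadata,
                   truth = truth, config = cfg),
              class = "taxa_sim")
  })
}

#' Simulate taxa counts with a planted latent co-occurrence structure
#'
#' Fixture generator for co-occurrence network analyses: a designated
#' set of taxa share one latent factor on the log-abundance scale, so
#' their pairwise correlations are governed by the product of their
#' loadings, while the remaining taxa fluctuate independently. Log
#' abundances are exponentiated, normalised per sample and converted to
#' counts with a log-normal library size, so downstream analyses see
#' ordinary compositional count data.
#'
#' @param n_taxa Total number of taxa.
#' @param n_samples Number of samples.
#' @param loadings Named numeric vector (taxon id -> loading in (0, 1))
#'   of the taxa attached to the shared latent factor; e.g. a hub with
#'   loading 0.95 driving followers at 0.85.
#' @param mu Optional per-taxon log-abundance baseline. By default the
#'   factor members sit at 0 and the background taxa at `log(20)`, so
#'   the correlated module is a minor fraction of the community and
#'   compositional closure does not cancel the shared factor out of the
#'   relative abundances.
#' @param library_meanlog,library_sdlog Log-normal depth parameters.
#' @param seed Optional integer seed.
#' @return A list: `counts` (tibble, taxon first column), `members`
#'   (the correlated taxa, hub first by decreasing loading).
#' @export
simulate_latent_taxa <- function(n_taxa = 15L, n_samples = 100L,
                                 loadings = c(taxon_01 = 0.95,
                                              setNames(rep(0.85, 8),
                                                       sprintf("taxon_%02d", 2:9))),
                                 mu = NULL,
                                 library_meanlog = log(2e4),
                                 library_sdlog = 0.3,
                                 seed = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2L) abort("`n_taxa` must be >= 2.")
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  if (is.null(names(loadings)) || !all(names(loadings) %in% taxa)) {
    abort("`loadings` must be named by generated taxon ids.")
  }
  if (any(loadings <= 0 | loadings >= 1)) {
    abort("`loadings` must lie strictly between 0 and 1.")
  }
  with_seed_if(seed, {
    lam <- setNames(rep(0, n_taxa), taxa)
    lam[names(loadings)] <- loadings
    if (is.null(mu)) mu <- ifelse(lam > 0, 0, log(20))
    z <- rnorm(n_samples)
    eps <- matrix(rnorm(n_taxa * n_samples), nrow = n_taxa)
    logab <- mu + outer(lam, z) + sqrt(1 - lam^2) * eps
    rel <- exp(logab)
    rel <- sweep(rel, 2, colSums(rel), "/")
    lib <- pmax(1, round(rlnorm(n_samples, library_meanlog, library_sdlog)))
    counts <- vapply(seq_len(n_samples),
                     function(s) rmultinom(1, lib[s], rel[, s])[, 1],
                     integer(n_taxa))
    dimnames(counts) <- list(taxa, sprintf("S%03d", seq_len(n_samples)))
    list(counts = taxa_tibble(counts),
         members = names(sort(loadings, decreasing = TRUE)))
  })
}
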