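#' Pipeline configuration
#'
#' A run either simulates its inputs (`simulate` block) or reads them
#' from files (`inputs` block with paths to a fermentation CSV, a taxa
#' TSV per timepoint, and a metadata TSV). All stage options are
#' grouped per stage. Configurations can also be loaded from YAML or
#' JSON via [read_pipeline_config()].
#'
#' @param simulate `NULL`, or a list with elements `fermentation`
#'   ([ferm_config()] or argument list) and `taxa` ([taxa_config()] or
#'   argument list).
#' @param inputs `NULL`, or a list of paths: `fermentation`,
#'   `taxa_baseline` (optional), `taxa_post`, `metadata`.
#' @param filter A [filter_config()].
#' @param stats List: `method` (`"t"`/`"wilcoxon"`), `alpha`, `n_min`.
#' @param da List: `prevalence_min`, `pseudocount`, `timepoint`.
#' @param network A [network_config()] plus `min_samples`,
#'   `prevalence_min`, `hub_k`.
#' @param seed Integer seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(fermentation = ferm_config(),
                                            taxa = taxa_config()),
                            inputs = NULL,
                            filter = filter_config(),
                            stats = list(method = "t", alpha = 0.05, n_min = 3L),
                            da = list(prevalence_min = 0.1, pseudocount = 1,
                                      timepoint = "post"),
                            network = list(rho_min = 0.6, alpha = 0.05,
                                           min_samples = 5L,
                                           prevalence_min = 0.2, hub_k = 5L),
                            seed = 1L,
                            out_dir = tempfile("fibersynergy_run_")) {
  if (missing(simulate) && !is.null(inputs)) simulate <- NULL
  if (is.null(simulate) && is.null(inputs)) {
    abort("either a `simulate` block or an `inputs` block is required.")
  }
  if (!is.null(simulate) && !is.null(inputs)) {
    abort("give either a `simulate` block or an `inputs` block, not both.")
  }
  if (!is.null(inputs)) {
    needed <- c("fermentation", "metadata")
    for (nm in needed) {
      if (is.null(inputs[[nm]])) abort(sprintf("`inputs$%s` is required.", nm))
      if (!file.exists(inputs[[nm]])) {
        abort(sprintf("input file not found: %s", inputs[[nm]]))
      }
    }
    for (nm in intersect(c("taxa_baseline", "taxa_post"), names(inputs))) {
      if (!file.exists(inputs[[nm]])) {
        abort(sprintf("input file not found: %s", inputs[[nm]]))
      }
    }
  }
  structure(
    list(simulate = simulate, inputs = inputs, filter = filter,
         stats = stats, da = da, network = network,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`). Recognised
#'   top-level keys mirror the arguments of [pipeline_config()];
#'   `simulate$fermentation`, `simulate$taxa` and `filter` are given as
#'   plain argument lists.
#' @param seed,out_dir Optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL, out_dir = NULL) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$simulate)) {
    args$simulate <- list(
      fermentation = do.call(ferm_config,
                             as.list(raw$simulate$fermentation %||% list())),
      taxa = do.call(taxa_config, as.list(raw$simulate$taxa %||% list()))
    )
  } else {
    args$simulate <- NULL
  }
  if (!is.null(raw$inputs)) args$inputs <- raw$inputs
  if (!is.null(raw$filter)) args$filter <- do.call(filter_config,
                                                   as.list(raw$filter))
  defaults <- list(
    stats = list(method = "t", alpha = 0.05, n_min = 3L),
    da = list(prevalence_min = 0.1, pseudocount = 1, timepoint = "post"),
    network = list(rho_min = 0.6, alpha = 0.05, min_samples = 5L,
                   prevalence_min = 0.2, hub_k = 5L)
  )
  for (nm in names(defaults)) {
    if (!is.null(raw[[nm]])) {
      args[[nm]] <- utils::modifyList(defaults[[nm]], as.list(raw[[nm]]))
    }
  }
  args$seed <- seed %||% raw$seed %||% 1L
  args$out_dir <- out_dir %||% raw$out_dir %||% tempfile("fibersynergy_run_")
  do.call(pipeline_config, args)
}

#' Run the end-to-end synergy analysis
#'
#' Sequences the full analysis: data acquisition (simulation or files)
#' -> synergy computation and filtering -> fiber-contrast, observed vs
#' expected and synergy-comparison statistics -> donor classification ->
#' alpha diversity and its change -> synergy-feature correlation grids
#' -> bias-corrected differential abundance -> per-stratum co-occurrence
#' networks with hub taxa. Every stage's output is materialised under
#' `out_dir` so any stage can be audited or re-run, and a JSON report
#' records the seed, a configuration hash, per-stage record counts and
#' all suppressed-statistics events. Stage RNG seeds are derived
#' deterministically from the global seed, so a fixed-seed simulate run
#' is bit-reproducible.
#'
#' @param config A [pipeline_config()] or a path to a YAML/JSON config.
#' @return Invisibly, a list with the in-memory stage results and the
#'   `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config or a config file path.")
  }
  lg <- new_logger()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "networks"), showWarnings = FALSE)
  counts <- list()
  suppressed <- list()
  st <- config$stats

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }

  # -- stage 1: acquire data ------------------------------------------------
  if (!is.null(config$simulate)) {
    lg$log("stage simulate: generating fermentation + taxa tables (seed %d)",
           config$seed)
    truth_env <- run_stage("simulate", {
      fcfg <- config$simulate$fermentation
      if (!inherits(fcfg, "ferm_config")) fcfg <- do.call(ferm_config, fcfg)
      fcfg$seed <- fcfg$seed %||% derive_seed(config$seed, 1L)
      sim <- simulate_fermentation(fcfg)
      list(sim = sim)
    })
    ferm <- truth_env$sim$fermentation
    write_fermentation(ferm, file.path(config$out_dir, "fermentation.csv"))
    jsonlite::write_json(truth_env$sim$truth,
                         file.path(config$out_dir, "ground_truth_synergy.json"),
                         digits = NA)
  } else {
    lg$log("stage read: loading inputs")
    ferm <- run_stage("read", read_fermentation(config$inputs$fermentation))
  }
  counts$fermentation_records <- nrow(ferm)

  # -- stage 2: synergy -----------------------------------------------------
  synergy <- run_stage("synergy", compute_synergy(ferm, config$filter))
  readr::write_csv(synergy, file.path(config$out_dir, "synergy.csv"))
  counts$synergy_records <- nrow(synergy)
  counts$synergy_retained <- sum(synergy$filter_status == "retained")
  summary_tbl <- summarize_synergy(synergy, by = c("condition", "scfa_type"),
                                   n_min = config$filter$n_min)
  readr::write_csv(summary_tbl, file.path(config$out_dir, "synergy_summary.csv"))
  suppressed$synergy_summary <- summary_tbl[summary_tbl$stats_suppressed,
                                            c("condition", "scfa_type")]
  overall <- summarize_synergy(synergy, by = "scfa_type",
                               n_min = config$filter$n_min)
  readr::write_csv(overall, file.path(config$out_dir, "synergy_overall.csv"))

  # -- stage 3: statistics --------------------------------------------------
  fiber_contrasts <- run_stage("stats", {
    ferm |>
      dplyr::filter(.data$scfa_type == "total") |>
      dplyr::reframe(
        tukey_contrasts(dplyr::pick(dplyr::everything()),
                        n_min = st$n_min, alpha = st$alpha),
        .by = "condition"
      )
  })
  readr::write_csv(fiber_contrasts,
                   file.path(config$out_dir, "stats_fiber_contrasts.csv"))
  obs_exp <- run_stage("stats", observed_vs_expected_suite(
    synergy, method = st$method, n_min = st$n_min, alpha = st$alpha
  ))
  readr::write_csv(obs_exp, file.path(config$out_dir, "stats_obs_vs_exp.csv"))
  syn_cmp <- run_stage("stats", dplyr::bind_rows(
    across_conditions = synergy_comparison_suite(
      synergy, "across_conditions", method = st$method,
      n_min = st$n_min, alpha = st$alpha
    ),
    within_condition = synergy_comparison_suite(
      synergy, "across_scfa_within_condition", method = st$method,
      n_min = st$n_min, alpha = st$alpha
    ),
    .id = "axis"
  ))
  readr::write_csv(syn_cmp,
                   file.path(config$out_dir, "stats_synergy_comparisons.csv"))
  counts$tests_emitted <- sum(!obs_exp$suppressed) + sum(!syn_cmp$suppressed)
  suppressed$observed_vs_expected <- obs_exp[obs_exp$suppressed,
                                             c("condition", "scfa_type")]
  suppressed$synergy_comparisons <- syn_cmp[syn_cmp$suppressed,
                                            c("family", "comparison")]

  # -- stage 4: donor classification ---------------------------------------
  labels <- run_stage("classify", classify_donors(synergy))
  readr::write_csv(labels, file.path(config$out_dir, "donor_labels.csv"))
  counts$donors_synergy <- sum(labels$synergy_label == "synergy")
  counts$donors_no_synergy <- sum(labels$synergy_label == "no_synergy")
  counts$donors_unassigned <- sum(labels$synergy_label == "unassigned")

  # -- stage 5: taxa tables -------------------------------------------------
  if (!is.null(config$simulate)) {
    taxa <- run_stage("simulate_taxa", {
      tcfg <- config$simulate$taxa
      if (!inherits(tcfg, "taxa_config")) tcfg <- do.call(taxa_config, tcfg)
      assigned <- labels[labels$synergy_label %in% c("synergy", "no_synergy"), ]
      base_seed <- tcfg$seed %||% derive_seed(config$seed, 2L)
      per_tp <- lapply(c(baseline = "baseline", post = "post"), function(tp) {
        cfg_tp <- tcfg
        cfg_tp$groups <- tibble::tibble(donor_id = assigned$donor_id,
                                        synergy_label = assigned$synergy_label)
        cfg_tp$timepoint <- tp
        cfg_tp$seed <- derive_seed(base_seed, if (tp == "baseline") 1L else 2L)
        simulate_taxa_counts(cfg_tp)
      })
      per_tp
    })
    meta <- dplyr::bind_rows(lapply(taxa, `[[`, "metadata"))
    counts_post <- taxa$post$counts
    counts_baseline <- taxa$baseline$counts
    write_taxa_table(counts_post, file.path(config$out_dir, "taxa_post.tsv"))
    write_taxa_table(counts_baseline,
                     file.path(config$out_dir, "taxa_baseline.tsv"))
    write_sample_metadata(meta, file.path(config$out_dir, "metadata.tsv"))
    jsonlite::write_json(taxa$post$truth,
                         file.path(config$out_dir, "ground_truth_taxa.json"),
                         digits = NA)
  } else {
    meta <- run_stage("read", read_sample_metadata(config$inputs$metadata))
    counts_post <- run_stage("read", read_taxa_table(config$inputs$taxa_post))
    counts_baseline <- if (!is.null(config$inputs$taxa_baseline)) {
      run_stage("read", read_taxa_table(config$inputs$taxa_baseline))
    } else NULL
    if (!"synergy_label" %in% names(meta)) {
      meta <- dplyr::left_join(meta, labels[, c("donor_id", "synergy_label")],
                               by = "donor_id")
      meta$synergy_label[is.na(meta$synergy_label)] <- "unassigned"
    }
    join <- run_stage("read", validate_join(ferm, meta))
    if (length(join$fermentation_only) + length(join$metadata_only) > 0) {
      lg$log("donor mismatches: fermentation-only [%s], metadata-only [%s]",
             paste(join$fermentation_only, collapse = ","),
             paste(join$metadata_only, collapse = ","))
    }
  }
  counts$samples <- nrow(meta)

  # -- stage 6: diversity ---------------------------------------------------
  diversity <- run_stage("diversity", {
    tabs <- list(post = counts_post)
    if (!is.null(counts_baseline)) tabs$baseline <- counts_baseline
    dplyr::bind_rows(lapply(tabs, alpha_diversity, metadata = meta))
  })
  readr::write_csv(diversity, file.path(config$out_dir, "diversity.csv"))
  counts$diversity_records <- nrow(diversity)

  # -- stage 7: correlation grids ------------------------------------------
  corr_div <- run_stage("correlate", {
    feats <- diversity_features(diversity)
    correlation_grid(synergy, feats, alpha = st$alpha,
                     n_min = config$filter$n_min)
  })
  readr::write_csv(tidy(corr_div),
                   file.path(config$out_dir, "correlations_diversity.csv"))
  corr_scfa <- run_stage("correlate", correlation_grid(
    synergy, scfa_features(synergy), alpha = st$alpha,
    n_min = config$filter$n_min
  ))
  readr::write_csv(tidy(corr_scfa),
                   file.path(config$out_dir, "correlations_scfa.csv"))
  counts$correlation_cells <- nrow(corr_div) + nrow(corr_scfa)

  # -- stage 8: differential abundance -------------------------------------
  tp_meta <- meta[meta$timepoint == config$da$timepoint, ]
  group_sizes <- table(tp_meta$synergy_label[
    tp_meta$synergy_label %in% c("synergy", "no_synergy")])
  if (length(group_sizes) < 2L || any(group_sizes < 2L)) {
    lg$log("diffabund skipped: need >= 2 samples in both synergy groups (have %s)",
           paste(names(group_sizes), group_sizes, sep = "=", collapse = ", "))
    da <- NULL
    suppressed$differential_abundance <- "group below minimum size"
    counts$da_tested <- 0L
    counts$da_significant <- 0L
  } else {
    da <- run_stage("diffabund", {
      tab <- if (config$da$timepoint == "baseline" && !is.null(counts_baseline)) {
        counts_baseline
      } else counts_post
      m <- taxa_matrix(tab)
      m <- m[, colnames(m) %in% tp_meta$sample_id, drop = FALSE]
      differential_abundance(m, tp_meta,
                             prevalence_min = config$da$prevalence_min,
                             pseudocount = config$da$pseudocount,
                             alpha = st$alpha)
    })
    readr::write_csv(tidy(da), file.path(config$out_dir, "diff_abundance.csv"))
    counts$da_tested <- sum(da$status == "tested")
    counts$da_significant <- sum(da$significant, na.rm = TRUE)
  }

  # -- stage 9: co-occurrence networks -------------------------------------
  nw <- config$network
  net_cfg <- network_config(rho_min = nw$rho_min, alpha = nw$alpha)
  strata <- run_stage("network", synergy_strata(synergy))
  networks <- list()
  hubs <- list()
  post_meta <- meta[meta$timepoint == "post", ]
  m_post <- taxa_matrix(counts_post)
  for (s in sort(unique(strata$stratum))) {
    donors <- strata$donor_id[strata$stratum == s]
    samples <- post_meta$sample_id[post_meta$donor_id %in% donors]
    sub <- m_post[, colnames(m_post) %in% samples, drop = FALSE]
    if (ncol(sub) < nw$min_samples) {
      lg$log("network stratum %s skipped: %d samples < %d", s, ncol(sub),
             nw$min_samples)
      next
    }
    tc <- run_stage("network", taxa_correlation_matrix(
      sub, min_samples = nw$min_samples, prevalence_min = nw$prevalence_min
    ))
    net <- build_network(tc, net_cfg, stratum = s)
    networks[[s]] <- net
    hubs[[s]] <- dplyr::mutate(
      centrality_and_hubs(net, k = nw$hub_k), stratum = s, .before = 1
    )
    safe <- gsub("[^A-Za-z0-9_-]", "_", s)
    export_network(net, file.path(config$out_dir, "networks",
                                  paste0(safe, ".graphml")), "graphml")
    export_network(net, file.path(config$out_dir, "networks",
                                  paste0(safe, "_edges.tsv")), "edge_tsv")
  }
  hub_tbl <- dplyr::bind_rows(hubs)
  if (nrow(hub_tbl) > 0) {
    readr::write_csv(hub_tbl, file.path(config$out_dir, "network_hubs.csv"))
  }
  counts$networks_built <- length(networks)

  # -- report ---------------------------------------------------------------
  headline <- overall[overall$scfa_type == "total", ]
  h1 <- function(x) if (length(x) >= 1L) x[[1]] else NA_real_
  hash_cfg <- config
  hash_cfg$out_dir <- NULL   # path varies run to run; keep the hash stable
  payload <- list(
    package_version = as.character(utils::packageVersion("fibersynergy")),
    seed = config$seed,
    config_hash = rlang::hash(hash_cfg),
    record_counts = counts,
    suppressed = lapply(suppressed, function(x) {
      if (is.character(x)) x else as.list(as.data.frame(x))
    }),
    headline = list(
      mean_total_synergy_pct = h1(headline$mean),
      sd_total_synergy_pct = h1(headline$sd),
      median_total_synergy_pct = h1(headline$median),
      max_total_synergy_pct = h1(headline$max)
    )
  )
  payload$report_hash <- rlang::hash(payload)
  jsonlite::write_json(payload, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(lg$lines(), file.path(config$out_dir, "run.log"))
  lg$log("pipeline complete: outputs in %s", config$out_dir)

  invisible(list(
    fermentation = ferm, synergy = synergy, summary = summary_tbl,
    overall = overall, fiber_contrasts = fiber_contrasts,
    observed_vs_expected = obs_exp, synergy_comparisons = syn_cmp,
    labels = labels, metadata = meta, diversity = diversity,
    correlations = list(diversity = corr_div, scfa = corr_scfa),
    differential_abundance = da, networks = networks, hubs = hub_tbl,
    report = payload
  ))
}
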