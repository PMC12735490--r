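Package: fibersynergy
Title: Quantifying Synergistic SCFA Production by Dietary Fiber Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify synergistic short-chain fatty acid (SCFA)
    production by a dietary fiber mixture in in vitro fecal fermentations,
    relative to the additive expectation from its individual fiber
    components, and to characterise the microbial signatures associated
    with synergy. Implements the synergy percentage statistic with
    measurement-error and detection-limit filtering, donor
    classification, paired and Tukey-type group comparisons with
    Benjamini-Hochberg and Holm-Sidak multiple-testing control,
    alpha-diversity metrics (Shannon, richness, Pielou evenness) and
    their fermentation-induced change, Spearman correlation grids,
    bias-corrected compositional differential abundance between synergy
    and no-synergy donors, and Spearman co-occurrence networks with hub
    identification. Includes a synthetic-data generator with known
    ground truth and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
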