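# fibersynergy

Quantifying synergistic short-chain fatty acid (SCFA) production by
dietary fiber mixtures, and the microbial signatures that go with it.

## The problem

When a mixture of structurally diverse dietary fibers is fermented in
vitro by a donor's fecal microbiota, the SCFA yield (acetate,
propionate, butyrate, total) is often *more* than the average of what
the individual fibers produce — the community appears to exploit
complementary substrate niches cooperatively. This package implements
the full analysis chain for such experiments, for microbiome
researchers comparing fiber formulations across donors and health
conditions (e.g. healthy controls vs Crohn's disease, ulcerative
colitis, Parkinson's disease):

1. **Synergy quantification.** For an equal-proportion four-fiber
   mixture, the additive null model is

   `Expected = (SCFA_fiber1 + SCFA_fiber2 + SCFA_fiber3 + SCFA_fiber4) / 4`

   per donor and SCFA type, and the synergy statistic is the relative
   excess in percent:

   `Synergy (%) = (Observed_mixture − Expected) / Expected × 100`

   Records are filtered with uniform thresholds before any statistic:
   a record within measurement error (|Observed − Expected| ≤ 0.5 mM)
   or below the detection limit (1.0 mM) is excluded, and no group
   statistic is reported for fewer than 3 retained records.

2. **Group statistics.** Donor-blocked Tukey contrasts of the mixture
   against each fiber; paired two-tailed observed-vs-expected tests per
   condition and SCFA type with Benjamini–Hochberg correction; synergy
   comparisons across conditions (Welch) and between SCFA types
   (paired) with Holm–Šidák adjustment.

3. **Microbial signatures.** Alpha diversity (Shannon, richness,
   Pielou evenness) at baseline, post-fermentation, and their change Δ;
   Spearman correlation grids between synergy and diversity or absolute
   SCFA; bias-corrected compositional differential abundance between
   synergy and no-synergy donors (sampling-fraction offsets + Welch
   tests on corrected log abundances, BH across taxa); and signed
   Spearman co-occurrence networks per synergy stratum with degree
   centrality, hub extraction, and Cytoscape-compatible GraphML export.

A seeded synthetic-data generator reproduces the statistical structure
of the study design (34 donors across 4 conditions, 5 substrates ×
4 SCFA measures, donor-level synergy ~ Normal(33%, 20%), mM-scale
measurement noise, taxa count tables with planted enrichment), so every
stage is testable end-to-end with known ground truth.

## Worked example

```r
library(fibersynergy)

sim <- simulate_fermentation(ferm_config(seed = 1))   # 34-donor cohort
syn <- compute_synergy(sim$fermentation)
summarize_synergy(syn, by = "scfa_type")
#> # A tibble: 4 × 8
#>   scfa_type      n  mean    sd median    min   max stats_suppressed
#>   <chr>      <int> <dbl> <dbl>  <dbl>  <dbl> <dbl> <lgl>
#> 1 acetate       33  36.6  25.4   35.8  -8.01  94.4 FALSE
#> 2 butyrate      32  40.0  22.1   38.4  -7.05  88.3 FALSE
#> 3 propionate    33  36.8  26.3   36.9 -13.9   94.5 FALSE
#> 4 total         34  36.0  25.1   37.0  -9.05  93.5 FALSE
```

Retained donors show a mean total-SCFA synergy of 36% in this draw
(the generator injects 33 ± 20%); the spread includes a few negative
donors, as real cohorts do. Observed vs expected mixture output is
tested per condition with BH correction:

```r
dplyr::filter(observed_vs_expected_suite(syn), scfa_type == "total")
#>   condition scfa_type     n estimate statistic    p_raw  p_adjusted significant
#> 1 CD        total         7     19.5      2.74 0.0335      0.0368   TRUE
#> 2 HC        total        10     12.9      5.65 0.000313    0.00153  TRUE
#> 3 PD        total        10     14.9      4.92 0.000821    0.00219  TRUE
#> 4 UC        total         7     11.9      4.32 0.00497     0.00795  TRUE
```

All four conditions exceed the additive expectation (estimate = mean
observed − expected in mM). `classify_donors(syn)` then labels donors
(here 31 synergy / 3 no-synergy), feeding the differential-abundance
and network stages. The whole chain — synergy, statistics, diversity,
correlation grids, differential abundance, per-stratum networks,
report — runs from one config:

```r
res <- run_pipeline(pipeline_config(
  simulate = list(fermentation = ferm_config(),
                  taxa = taxa_config(enriched_taxa = c(taxon_03 = 4))),
  seed = 42, out_dir = "my_run"
))
res$report$headline
```

Every stage's table is materialised under `out_dir`, and
`report.json` records the seed, a config hash and all
suppressed-statistics events. `autoplot()` methods cover correlation
grids, differential-abundance results and networks; `tidy()`/`glance()`
give broom-style summaries.

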