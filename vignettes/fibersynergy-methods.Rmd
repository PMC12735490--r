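---
title: "Methods: quantifying fiber-mixture SCFA synergy and its microbial correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fiber-mixture SCFA synergy and its microbial correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methodology:
the models implemented, the assumptions they rest on, the parameters
that matter, and the choices made where the design was genuinely open.

## The synergy statistic and its null model

An equal-proportion (25% each) mixture of four fibers is fermented by
each donor's fecal community alongside the four fibers individually.
If fibers acted independently, the mixture's SCFA yield would be the
average of the four individual yields for that donor:

$$\mathrm{Expected} = \tfrac{1}{4}\sum_{i=1}^{4} \mathrm{SCFA}_{\mathrm{fiber}\,i},
\qquad
\mathrm{Synergy}\,(\%) = \frac{\mathrm{Observed}_{\mathrm{mixture}} - \mathrm{Expected}}
{\mathrm{Expected}} \times 100 .$$

The statistic is computed per donor and per SCFA type (acetate,
propionate, butyrate, total). It is a ratio statistic, so it is
scale-free (`synergy_percent(e, e) = 0`, `synergy_percent(2e, e) =
100` for any `e > 0`) but undefined when the expectation is zero;
such records receive the distinct status `excluded_zero_expected`
rather than an infinite value, which keeps all summaries finite.

### Filtering

Small or unstable effects are excluded before any statistic, with
uniform thresholds (`filter_config()`):

* **Measurement error** — `|Observed − Expected| ≤ 0.5` mM: the
  difference is within gas-chromatography measurement error, so its
  sign is not trustworthy.
* **Detection limit** — either value below `1.0` mM: the ratio's
  denominator or numerator is itself unreliable.
* **Minimum n** — groups with fewer than 3 retained records are
  reported with `stats_suppressed = TRUE` and excluded from test
  families.

The two exclusion tests are combined disjunctively by default
(`combine_rule = "any"`): either condition alone makes the synergy
value unreliable. The conjunctive reading is available
(`combine_rule = "all"`) since the prose rule could be parsed either
way. The detection limit is applied to *both* observed and expected
values — a sub-detection expectation invalidates the ratio just as a
sub-detection observation does.

Filtering is annotation, never deletion: every record keeps its
`filter_status`, so the choice of which records enter a downstream
computation is explicit at each call site.

### Pre- vs post-filter averaging

Group summaries default to retained records (`use = "retained"`), the
reporting convention for synergy tables. For *parameter estimation* —
"what is the population mean synergy?" — the package exposes
`use = "computed"`: excluding within-measurement-error records trims
values near zero asymmetrically (when the population mean is positive)
and biases the retained-record mean upward by a fraction of a percent
to a few percent depending on noise. The package's own recovery
analyses use the computed mean for exactly this reason.

## Statistical testing scheme

Three families of tests mirror the standard analysis of such designs:

1. **Mixture vs individual fibers** (`tukey_contrasts()`): all pairwise
   substrate contrasts via the studentized-range procedure on a
   donor-blocked one-way layout (`value ~ donor + substrate`). Blocking
   is the default because every substrate is fermented by the same
   donors; removing the donor effect before the residual mean square
   enters the Tukey statistic is the repeated-measures-correct choice.
   A pooled-residual variant (`blocked = FALSE`) is provided because
   the original computation's layout is not documented; the blocked
   default is the conservative reading of a repeated-measures design.

2. **Observed vs expected** (`observed_vs_expected_suite()`): one
   paired two-tailed test per (condition × SCFA type), BH correction
   across the whole emitted family (up to 16 tests — a single family is
   the conservative reading when the family boundary is not stated).
   The default test is the paired t-test, with Wilcoxon signed-rank as
   an option; the t default matches the tiered significance annotations
   this analysis conventionally produces, and the signed-rank option is
   a cheap robustness check. These tests run on all computed records by
   design: the measurement-error filter conditions on the very
   difference under test, and a paired test applied after selecting
   |difference| > 0.5 mM would reject at far above its nominal level
   under the null. The package verifies the nominal 5% size by
   simulation (see the calibration section).

3. **Synergy comparisons** (`synergy_comparison_suite()`): across
   conditions, unpaired Welch tests per SCFA type (filtering produces
   unequal group sizes, so the equal-variance assumption is not
   imposed); between SCFA types within a condition, paired tests on
   donors retained for both types. Holm–Šidák step-down adjustment is
   applied per family (per SCFA type, or per condition), the natural
   family when each SCFA type's comparisons are interpreted separately.

`adjust_pvalues()` implements BH step-up (via `stats::p.adjust`) and
Holm–Šidák step-down
($\tilde p_{(i)} = \max_{j \le i}\,[1 - (1 - p_{(j)})^{m-j+1}]$,
clipped at 1) — the latter hand-written since base R offers Holm's
Bonferroni-style version only. Both are checked exactly against
brute-force step-procedure references on random inputs.

## Alpha diversity

Shannon entropy is computed on relative abundances in natural-log
units (the log base is a free convention; Pielou evenness
`H / ln(richness)` is base-invariant, so downstream rank correlations
are unaffected either way; base 2 is available). Richness is observed
feature count, evenness is undefined (NA, propagated through Δ) for
single-taxon samples. No rarefaction or coverage correction is applied
— raw proportions are used, and library-size effects on richness are a
known caveat the correlation analysis inherits. The change Δ is
post-fermentation minus baseline, per donor.

## Correlation grids

`correlation_grid()` computes Spearman rank correlations (average
ranks for ties) between per-donor synergy percentages and donor-level
features (diversity metrics at baseline/post/Δ, absolute SCFA).
Two-sided p-values are exact — full rank-permutation null — for
n ≤ 9 without ties, asymptotic otherwise. Donors are dropped pairwise
per cell, because filtering makes synergy availability cell-specific;
cells with fewer than 3 pairs or a constant margin are reported missing
with a reason, never as zero. No multiplicity adjustment is applied by
default, matching the per-cell annotation convention of correlation
heatmaps (a BH variant is one flag away).

## Bias-corrected differential abundance

Count tables are compositional: each sample's counts reflect an
unknown sampling fraction as much as the underlying abundances. The
package implements a deliberately transparent bias-correction scheme
(it is *not* a port of the published ANCOM-BC estimator — no iterative
EM bias estimation, no covariate models — and is documented as such):

1. prevalence filtering (default: tested if present in ≥ 10% of the
   samples of at least one group; taxa entirely absent from one group
   are *structural zeros*, reported but not tested — their fold change
   is undefined without stronger assumptions);
2. per-sample offsets: the median across tested taxa of the sample's
   log count minus the per-taxon reference mean (`pseudocount = 1`
   added before logs), centred to mean zero. Within
   `differential_abundance()` the reference is the pooled mean over
   all samples: a group-wise reference identifies offsets only up to
   per-group constants, so the groups' average sampling-fraction
   difference would leak into every fold change; the pooled reference
   leaves one global constant, which cancels in the group contrast.
   The median keeps the estimate robust as long as differential taxa
   are a minority;
3. per-taxon Welch t-tests on offset-corrected log abundances, giving
   a natural-log fold change (synergy minus no-synergy) with standard
   error; BH across tested taxa.

Known bias sources, all verified small at the scales the package
simulates: the pseudocount (vanishing with depth except at zero
counts), compositional renormalisation (a planted fold f on a taxon
with baseline proportion p realises f/(1+(f−1)p), hence enrichment is
planted on minor taxa in the package's own recovery checks), and the
log-scale variance mismatch between groups.

## Co-occurrence networks

Within each stratum (SCFA type × synergy label, from
`synergy_strata()`), Spearman correlations between prevalence-filtered
taxa over relative abundances give a symmetric rho/p matrix pair. An
edge is kept when the BH-adjusted p across all taxon pairs is below
0.05 *and* `|rho| ≥ 0.6` — thresholds follow common co-occurrence
practice since the upstream convention is not documented; both are
config-exposed, and filtering is monotone (tightening either threshold
never adds an edge). Node centrality defaults to degree (betweenness
optional, weighted by 1/|rho|); hub ranking breaks degree ties by
summed |rho| and then lexicographic taxon id, so rankings are
deterministic. Networks export to Cytoscape-importable GraphML and
edge-list TSV, and re-import losslessly.

## The synthetic-data generator

The generator emulates the *statistical* structure of the study — it
is not a fermentation model (no kinetics, no cross-feeding mechanism):

* **Cohort**: donors per condition default to the study's printed
  group sizes — HC 10, PD 10, CD 7, UC 7 (34 donors; the printed
  per-condition sizes are taken as authoritative for the design).
* **Concentrations**: per-donor per-fiber SCFA values are log-normal
  on the mM scale. The study does not report per-condition baselines
  numerically, so the location/scale defaults (acetate ≈ 22 mM,
  propionate ≈ 8 mM, butyrate ≈ 7 mM medians; log-sd 0.35–0.45;
  condition multiplier 1) are order-of-magnitude choices typical of
  12-h in vitro fecal fermentations, chosen once and not revisited.
* **Synergy**: one draw per donor, δ ~ Normal(33, 20) in percent,
  matching the reported effect scale; the mixture concentration of
  each acid is the mean of the donor's four *recorded* fiber values ×
  (1 + δ/100) plus noise. A per-acid δ option exists for stress tests.
  Totals are derived as exact sums of the three acids.
* **Noise**: additive Gaussian on mM concentrations (GC error lives on
  the concentration scale), truncated at zero, applied to every
  recorded value; default sd 0.5 mM, the same scale as the
  measurement-error threshold.
* **Taxa counts**: Dirichlet-multinomial around a power-law base
  composition (total concentration 500, i.e. moderate
  overdispersion), log-normal library sizes, enrichment planted by
  multiplying designated taxa's Dirichlet parameters by their fold
  change in the synergy group. A latent-factor variant
  (`simulate_latent_taxa()`) plants co-occurrence structure for the
  network analyses, with the correlated module kept a minor fraction
  of the community so compositional closure does not cancel the shared
  factor.

What passing tests on this generator do **not** show: robustness to
real-data features the generator omits — heavy-tailed or skewed
synergy distributions, donor-specific noise, batch effects,
phylogenetically structured correlation, zero-inflation beyond the
Dirichlet-multinomial's own.

## Numerical choices

* With zero injected effect and zero noise, the synergy statistic is
  bitwise 0 for acid records (generator and analysis reduce the four
  fiber values with the same canonically ordered mean); derived totals
  agree to ~1e-13 because summation order differs, and identities on
  totals are asserted at 1e-9.
* Paired differences below 1e-9 relative to the data scale are treated
  as exact zeros — mM concentrations carry nowhere near that
  precision, and without the guard floating-point residue would turn
  exact-null cells into uniform p-values.
* Degenerate inputs have defined limits: zero-variance paired
  differences give p = 1 (identical) or p = 0 with a warning
  (constant shift); Tukey contrasts with residual MSE below
  1e-20 × range² report exact 0/1 p-values; constant correlation
  margins are missing cells, not zeros.
* Stage seeds derive deterministically from one global seed, so a
  fixed-seed pipeline run is bit-reproducible while stages stay
  independent.

## Problem sizes used in the package's own checks

The test-suite and acceptance analyses run at sizes chosen to make
Monte-Carlo error small relative to the tolerances while remaining
desk-scale: 500 seeds for mean-synergy recovery (34-donor and
500-donor cohorts), 2000 replicate families for the type-I error of
the observed-vs-expected suite, 1000 random vectors for the
multiple-testing oracles, 200 instances for Spearman exactness, 200
seeds each for differential-abundance recovery (50 samples/group,
planted ln 4) and hub recovery (100 samples, 15 taxa, hub loading
0.95 driving 8 followers at 0.85).

## Known limitations

* The donor classification threshold (synergy iff retained total-SCFA
  synergy > 0%) is the simplest reading of "exhibiting synergy"; it is
  a config parameter, and cohorts concentrated near zero will be
  sensitive to it.
* The differential-abundance stage is a documented simplification of
  published bias-correction estimators; effect sizes for taxa near
  structural zeros or with very low prevalence are not recoverable.
* Whether the reported effect scale averages donors before or after
  filtering, and which samples entered the original group comparison
  (baseline, post, or both), are not documented upstream; both are
  exposed as options (`use =`, `timepoint =`) rather than fixed.
* In vitro fermentation data say nothing about host absorption or in
  vivo SCFA kinetics; the package analyses the assay, not the
  physiology.
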