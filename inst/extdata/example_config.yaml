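# Example pipeline configuration for fibersynergy::run_pipeline().
# A `simulate` block generates the inputs; replace it with an `inputs`
# block (fermentation / taxa_post / taxa_baseline / metadata paths) to
# run on measured data.
simulate:
  fermentation:
    synergy_mean: 33
    synergy_sd: 20
    noise_sd: 0.5
  taxa:
    n_taxa: 60
    enriched_taxa:
      taxon_21: 4
      taxon_33: 2.5
filter:
  error_threshold: 0.5
  detection_limit: 1.0
  n_min: 3
stats:
  method: t
  alpha: 0.05
network:
  rho_min: 0.6
  alpha: 0.05
seed: 1
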