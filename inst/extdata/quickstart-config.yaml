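# Quick-start pipeline configuration. Paths match the output layout of
#   wcflux simulate --out-dir wcflux-data
# Run with:
#   wcflux run-all --config quickstart-config.yaml --out-dir wcflux-out
flux_path: wcflux-data/flux.tsv
simulations_path: wcflux-data/simulations.tsv
phenotype_path: wcflux-data/phenotype_flags.tsv
stoichiometry_path: wcflux-data/stoichiometry.tsv
out_dir: wcflux-out
seed: 1
input_length: 100
classifier:
  epochs: 10
  batch_size: 20
  width: 64
min_accuracy: 0.70
noise_coverage: 0.95
matching_strategy: maximum
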