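# Demo study: simulated F2 intercross with four planted co-expression
# modules, a marker -> gene -> trait causal chain hosted by the first
# module, and trait-reactive genes.
simulation:
  n_samples: 2000
  module_sizes: [120, 90, 70, 60]
  within_module_cor: 0.7
  n_background_genes: 250
  n_markers: 1
  a1: 0.5
  a2: 0.5
  n_reactive_genes: 15
  b: 0.5
  noise_sd: 1
  seed: 20251001
pipeline:
  beta: 8
  cut_height: 0.97
  min_module_size: 50
  set_size: 400
  n_sets: 10000
  ms_quantile: 0.95
  leo_threshold: 0.3
  rmsea_threshold: 0.05
  edge_weight_threshold: 0.02
signature:
  n_module_genes: 20
  n_background_genes: 10
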