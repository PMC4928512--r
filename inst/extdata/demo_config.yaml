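# Demo configuration: synthetic cohort, reduced sizes so the full pipeline
# runs in seconds. Real analyses use mode: tables or mode: volumes with
# n_permutations: 10000 and n_randomizations: 1000.
mode: synthetic
synthetic:
  n_case: 20
  n_control: 15
  n_regions: 30
  planted_r_case: 0.1
  global_attenuation: 0.8
comparisons:
  - [case, control]
n_permutations: 200
n_randomizations: 25
seed: 42
density:
  low: 0.2
  high: 0.6
  step: 0.2
metric_mode: weighted
alpha_edges: 0.05
edge_correction: fwe
alpha_metrics: 0.05
output_dir: metconn_output
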