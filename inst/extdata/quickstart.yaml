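seed: 42
output_dir: quickstart_results
connectome:
  type: synthetic
  n_regions: 20
  density: 0.3
  length_scale_mm: 40
tables:
  mu_step: 0.25
  sigma_step: 0.5
simulation:
  duration: 30
  transient: 2
cohort:
  n_subjects: 2
metrics:
  TR: 1
stats:
  n_permutations: 200
perturbations:
  - family: noise_level
    scales: [1.2]
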