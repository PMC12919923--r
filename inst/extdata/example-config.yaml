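# Example pipeline configuration. Omitted fields take package defaults
# (see defaultConfig()); unknown fields are rejected.
seed: 42
simulation:
  n_individuals: 20000
  gwas_n_exposure_arm: 20000
  gwas_n_outcome_arm: 20000
  n_snps_exposure: 25
  n_snps_mediator: 15
  n_mediators: 2
  mediator_names: [insulin, shbg]
  beta_xm: [0.5, -0.3]
  beta_my: [0.4, -0.2]
  baseline_hazard: 0.004
instruments:
  p_threshold: 5.0e-8
  r2_threshold: 0.01
  window_kb: 10000
mr:
  model: random
  presso_n_sim: 500
triangulation:
  alpha: 0.05
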