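# One-command demo configuration for run_pipeline():
#   run_pipeline(read_run_config(system.file("extdata", "demo_config.yaml",
#                                            package = "hapburden")))
# Desk-scale cohorts with the default 5q22.1 common-haplotype landscape.
seed: 1
n_case: 500
n_control: 500
em:
  tol: 1.0e-8
  max_iter: 1000
selection:
  n_total: 16
  n_reference: 2
  common_freq_threshold: 0.005
reads:
  n_reads: 2000
  read_len: 100
  adapter: AGATCGGAAGAGC
  frac_adapter: 0.05
  frac_lowq: 0.05
  frac_highN: 0.05
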