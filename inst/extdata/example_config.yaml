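# Example run configuration for the edsim pipeline.
# Null paths fall back to the shipped parameter table / default targets and
# the synthetic life table.
seed: 1
out_dir: edsim_output
profile: desk            # desk | paper | test
paths:
  param_table: null
  life_table: null
  targets: null
calibrate:
  free_blocks: [incidence_multiplier]   # or "all"
simulate:
  n_runs: 100
  n_persons: 20000
  scenarios: [baseline, no_treatment, full_treatment, no_incidence]
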