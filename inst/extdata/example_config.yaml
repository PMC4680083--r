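# Example run configuration for dcnvoc::read_run_config() /
# inst/scripts/dcnvoc.R run-all. Keys mirror run_config(); unknown keys
# are rejected.
seed: 1
n_trials: 20
cycle: 0.333333
threshold: 0.95
n_iter: 12000
burn_in: 2000
n_cells: 8
cf_range_hz: [10000, 35000]
reverb:
  delay: 0.001
  decay: 0.002
  n_echoes: 5
boltzmann:
  x1: -0.2
  x2: -0.2
  a1: 12.8
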