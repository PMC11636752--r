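# Example pipeline configuration (see ?read_config). Unset fields fall
# back to the package defaults.
seed: 20240325
noise_cv: 0.1
stages:
  - gen_synthetic
  - simulate
  - metrics
scenario:
  tea_dose: 0.019   # ug/kg body weight/day
  tea_days: 35
  rif_dose: 600     # mg/day
  rif_start_day: 4
  rif_days: 14
solver:
  dt_out: 0.1       # h
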