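# Reference single-dose scenario: the bundled demographic average male
# drinking 0.25 g ethanol/kg as a 12.5 %w/v drink. Short horizon so the
# smoke run completes quickly; raise t_end for full exposure metrics.
schema_version: 1
individual:
  age: 25.6
  sex: male
  height: 180
  weight: 74.5
  body_fat: 0.20
regimen:
  times: [0]
  dose_g_per_kg: 0.25
  strength_wv: 12.5
scenario:
  expression_scale: 1
  isoform: ALDH2.1
  disulfiram_mg_l: 0
numerics:
  t_end: 60
  dt: 1
  tol: 0.01
  n_sub: 8
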