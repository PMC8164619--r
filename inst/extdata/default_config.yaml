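# Default pipeline configuration: synthetic survey calibrated to the
# packaged per-region summary table, packaged consumption parameters,
# EFSA-derived reference dose.
survey:
  source: synthetic       # or a path to a records CSV
  censor_threshold: 0.002 # mg/kg
groups:
  file: ~                 # null = packaged parameter table
regional:
  group: "19-65 years, male"
simulation:
  iterations: 100000
  seed: 1
  rfd: 0.36               # ug/kg bw/day
  af: 1.0
  ed: 1
  at: 1
outputs:
  dir: cdrice-outputs
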