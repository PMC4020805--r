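name: synthetic-uv
provenance: synthetic coefficients; not a measured camera
grid:
  start_nm: 300.0
  stop_nm: 710.0
  step_nm: 1.0
channels:
- channel_id: uv
  sensitivity:
    terms:
    - a: 1.0
      b: 360.0
      c: 25.0
    ci95: ~
  transfer:
    form: single_exp
    coefficients:
      a: 0.08
      b: 2.5
    ci95: ~
exposure:
  scale_per_channel:
    uv: 0.000476810824581
  max_level: 245
  bit_depth: 8
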