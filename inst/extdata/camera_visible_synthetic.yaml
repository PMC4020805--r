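name: synthetic-visible
provenance: synthetic coefficients; not a measured camera
grid:
  start_nm: 300.0
  stop_nm: 710.0
  step_nm: 1.0
channels:
- channel_id: red
  sensitivity:
    terms:
    - a: 1.0
      b: 600.0
      c: 45.0
    - a: 0.25
      b: 545.0
      c: 25.0
    ci95: ~
  transfer:
    form: biexponential
    coefficients:
      a: 0.515604
      b: 0.690511
      c: -0.50755
      d: -8.739706999999999
    ci95: ~
- channel_id: green
  sensitivity:
    terms:
    - a: 1.0
      b: 535.0
      c: 50.0
    ci95: ~
  transfer:
    form: biexponential
    coefficients:
      a: 0.515604
      b: 0.690511
      c: -0.50755
      d: -8.739706999999999
    ci95: ~
- channel_id: blue
  sensitivity:
    terms:
    - a: 1.0
      b: 465.0
      c: 40.0
    ci95: ~
  transfer:
    form: biexponential
    coefficients:
      a: 0.515604
      b: 0.690511
      c: -0.50755
      d: -8.739706999999999
    ci95: ~
exposure:
  scale_per_channel:
    red: 0.000107638408622
    green: 9.798838807711496e-05
    blue: 0.00011655011912
  max_level: 245
  bit_depth: 8
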