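# Published CIE D65 relative spectral power distribution, 300-780 nm at
# 10 nm, normalised to 100 at 560 nm. Used only as an oracle for the
# daylight-series synthesis.
published_d65 <- data.frame(
  wl = seq(300, 780, 10),
  spd = c(0.0341, 3.2945, 20.236, 37.0535, 39.9488, 44.9117, 46.6383, 52.0891,
          49.9755, 54.6482, 82.7549, 91.486, 93.4318, 86.6823, 104.865, 117.008,
          117.812, 114.861, 115.923, 108.811, 109.354, 107.802, 104.79, 107.689,
          104.405, 104.046, 100.0, 96.3342, 95.788, 88.6856, 90.0062, 89.5991,
          87.6987, 83.2886, 83.6992, 80.0268, 80.2146, 82.2778, 78.2842, 69.7213,
          71.6091, 74.349, 61.604, 69.8856, 75.087, 63.5927, 46.4182, 66.8054,
          63.3828)
)
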