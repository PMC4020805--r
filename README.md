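# camflor

Radiometric calibration of consumer digital cameras for quantifying flower
colour signals in the visible **and ultraviolet** bands.

## The problem

Plant–pollinator research needs both the *spectral* and the *spatial*
structure of floral signals: many flowers carry UV bullseyes and patterning
that bees and birds perceive but a spectrophotometer — measuring a few
isolated points — largely misses. Digital cameras capture the spatial
dimension at once, but consumer cameras return pixel values that are
**non-linearly** related to the light that reached the sensor, so raw images
cannot be used as measurements. `camflor` is for researchers who want to
turn 8-bit camera images (a standard RGB DSLR plus a UV-converted body
behind a UV-pass filter) into per-pixel reflectance maps with stated
uncertainty, and to compare those maps against spectrophotometer
predictions.

## The model

The linear response of channel *i* to a surface of reflectance *R* under
illuminant *E* is

    Q_i = ∫ S_i(λ) E(λ) R(λ) dλ

with `S_i` the channel's spectral sensitivity, modelled as a one- or
two-term Gaussian sum `S(λ) = Σ_k a_k exp(−((λ−b_k)/c_k)²)`. The camera
reports `I_i = G_i(H_i · Q_i)`, where `H_i` is the per-channel exposure
scale and `G_i` the transfer non-linearity, modelled as `q(x) = a·e^{bx}`
(single exponential) or `q(x) = a·e^{bx} + c·e^{dx}` (biexponential).
Calibration proceeds by

1. fitting `G_i` to a grey-ramp characterisation series and inverting it
   numerically into a 256-entry look-up table with bootstrap uncertainty;
2. standardising exposure per channel so a perfect white reflector maps to
   exactly 245 of 255 levels (no white-balance transform; levels above 245
   are flagged as clipped, linear values below ~9% of full scale as
   noise-dominated);
3. converting linear values to reflectance against in-frame achromatic
   standards (white spectralon, 33% grey, 95% checker white), combined by
   inverse-variance weighting;
4. sampling regions (15×15-pixel squares, or pseudo-random cells of 4×3 /
   6×2 grids) and comparing camera-recovered with spectrophotometer-predicted
   reflectance by Wilcoxon rank-sum tests.

The reference illuminant is the CIE daylight series (D65 at 6500 K)
synthesised from its component vectors. A forward renderer and synthetic
scene generators (neutral swatch charts, UV-bullseye flowers, grey ramps)
provide ground-truth imagery for validating every stage; the shipped camera
profiles are clearly labelled **synthetic**.

## Worked example

Characterise a camera from a noisy grey ramp, build the LUT, then recover
the six neutral swatches of a rendered test chart:

```r
library(camflor)

cam <- standardise_exposure(synthetic_visible_profile())

# transfer-function fit from a simulated characterisation series
series <- make_grey_series(cam$transfers$green, n_steps = 14,
                           noise = noise_spec(0.5, 0.3), seed = 11)
fit_transfer(series, form = "auto")
#> <transfer_function:biexponential> a=0.519675, b=0.677656, c=-0.510351, d=-8.59239

# six-swatch chart: render -> linearise -> calibrate -> recover
sw   <- make_swatch_frame(camera = cam)
lin  <- linearise_image(sw$frame, lapply(cam$transfers, invert_to_lut, n_boot = 0))
refl <- to_reflectance(lin, calibrate_exposure(lin, sw$standards))
rec  <- vapply(seq_along(sw$reflectances), function(i) {
  roi <- sw$swatch_rois[[sprintf("swatch_%d", i)]]
  mean(refl$channels$green[roi$rows, roi$cols])
}, numeric(1))
data.frame(nominal_pct = 100 * sw$reflectances, recovered_pct = round(100 * rec, 2))
#>   nominal_pct recovered_pct
#> 1        3.10          3.14
#> 2        9.11          9.11
#> 3       19.50         19.62
#> 4       37.20         37.30
#> 5       60.90         60.87
#> 6       94.80         94.69
```

Every swatch at or above the ~9% noise floor is recovered well within 2
percentage points of its nominal reflectance; the auto-selected transfer
form and its coefficients match the generating biexponential. The fitted
LUT reports per-level uncertainty whose *relative* magnitude grows sharply
below the noise floor — the quantitative form of "don't trust dark pixels".

A thin command-line wrapper ships in `inst/cli/camflor` with subcommands
`characterise`, `linearise`, `recover`, `simulate`, `sample` and `compare`,
e.g.

```sh
Rscript inst/cli/camflor simulate --template bullseye --band uv --seed 1 --out-prefix sim
Rscript inst/cli/camflor characterise --series inst/extdata/grey_series_synthetic.csv --out lut.csv
```

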