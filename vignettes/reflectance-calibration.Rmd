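---
title: "Recovering floral reflectance from consumer camera images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering floral reflectance from consumer camera images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camflor)
```

# The measurement problem

Flower colour signals matter to pollinators across a spectral window (roughly
320--710 nm) that includes ultraviolet structure invisible to humans.
Spectrophotometers measure reflectance precisely but only at a handful of
points, so the *spatial* organisation of the signal -- bullseye guides, petal
gradients, patterning -- is under-sampled. A digital camera captures the
spatial dimension at once, but consumer cameras are built to please human
viewers, not to measure energy: the pixel value is a non-linear function of
the light that reached the sensor. `camflor` implements the calibration chain
that turns 8-bit camera images (one visible RGB camera, one UV-converted
camera behind a UV-pass filter) into per-pixel reflectance estimates with
stated uncertainty.

# Forward model

The linear response of a colour channel with spectral sensitivity $S_i(\lambda)$
viewing a surface of reflectance $R(\lambda)$ under illumination $E(\lambda)$ is

$$Q_i = \int S_i(\lambda)\,E(\lambda)\,R(\lambda)\,d\lambda ,$$

evaluated by the trapezoidal rule on a common wavelength grid
(`predict_response()`). The camera, however, reports

$$I_i = G_i\!\left(H_i \, Q_i\right)\cdot 255 \;\text{(quantised)},$$

where $H_i$ collects the exposure parameters (aperture, integration time,
gain scale) into a per-channel multiplier and $G_i$ is the channel's
non-linear transfer function, which folds in vendor "gamma correction".
Recovering $Q_i$ therefore requires (i) a model of $S_i$, (ii) a model of
$G_i$ and its inverse, and (iii) a way to pin $H_i$ using objects of known
reflectance in the frame.

## Wavelength grid and illuminant

The default working grid is 300--710 nm at 1 nm: it covers the UV camera's
band (about 320--395 nm behind the filter) and the visible camera's band
(about 400--710 nm) with margin. Quadrature is trapezoidal throughout; on
1 nm grids the rule agrees with 0.01 nm quadrature to better than $10^{-4}$
relative for smooth spectra (this is tested).

The reference illuminant is the CIE daylight series synthesised from its
correlated colour temperature (`cie_daylight_spd()`): daylight chromaticity
from the CCT, weights of the two characteristic vectors from the
chromaticity, SPD normalised to 100 at 560 nm. At 6500 K this is D65. The
historical re-definition of the radiation constant means the canonical
phases are actually defined at slightly shifted temperatures (6500 K becomes
6504 K); the `cct_correction` flag applies that shift and defaults to *on*
because that is what reproduces the published D65 tabulation (the synthesis
is tested against that table at every 10 nm node).

## Channel sensitivities

Each channel's sensitivity is a sum of one or two Gaussian terms
$S(\lambda)=\sum_k a_k \exp\left(-\left((\lambda-b_k)/c_k\right)^2\right)$.
`fit_sensitivity()` fits both variants by Levenberg--Marquardt least squares
(initialised at the argmax sample, with width from the FWHM estimate; the
second term seeded at the largest residual) and keeps the two-term model only
when

* every one of its six coefficients is individually significant (95% Wald
  interval excluding zero), **and**
* the richer model is supported by very strong evidence, $\Delta\mathrm{BIC}
  \le -10$ on the Kass--Raftery scale.

The significance rule alone has two failure modes that motivated the second
gate: on noiseless data a perfect fit makes every interval zero-width, so
even a numerically negligible second term is "significant"; and a borderline
noise bump spanning two or three samples can be fitted as a tiny yet formally
significant band. Genuine second terms in our simulations improve BIC by
around 130; spurious ones never reach 10. Term widths are additionally
bounded below by the sampling step, because a band narrower than the sample
spacing is unresolvable. Fitted objects carry Wald intervals and the
coefficient covariance.

## Transfer functions and LUT linearisation

Two parametric families cover the cameras addressed here: a single
exponential $q(x)=a e^{bx}$ and a biexponential $q(x)=a e^{bx}+c e^{dx}$,
both mapping relative exposure $x\in[0,1]$ to normalised pixel value $q$.
`fit_transfer()` fits them to a grey-ramp characterisation series, weighting
by the per-step pixel variance when the series provides it (`sd_pixel`), and
applies the same two-gate selection in `auto` mode. Fits that are
non-monotonic on $[0,1]$ are rejected outright. Curves that drift mildly past
the nominal range under characterisation noise ($q(0)$ slightly below 0 or
$q(1)$ slightly above 1.05) are kept but flagged, since the corresponding
levels are clamped in the look-up table anyway; grossly out-of-range curves
are rejected.

Linearisation inverts the fitted transfer numerically (bisection to
$10^{-9}$, one entry per 8-bit level) into a 256-entry LUT
(`invert_to_lut()`). The numerical route was chosen because the
biexponential has no closed-form inverse, and one code path then serves both
families plus the identity. Levels below $q(0)\cdot 255$ (the black offset of
a pure exponential) or above $q(1)\cdot 255$ are clamped and flagged.

### Uncertainty of the inverse

Coefficient uncertainty is pushed through the inverse by a seeded parametric
bootstrap: 1000 coefficient draws from the multivariate normal with the
fit's covariance (correlations between the exponential coefficients are
strong, and ignoring them distorts the propagated band), each inverted, and
the per-level SD stored. Both the absolute SD and the SD relative to the
entry are kept. The distinction matters: for a gamma-like (concave) transfer
the toe is steep, so pixel-level noise maps to *small absolute* exposure
errors at low levels -- but the recovered values there are themselves tiny,
and the *relative* uncertainty is an order of magnitude larger at level 10
than at level 128 for the shipped synthetic camera. The reliability
statement "low-signal values are untrustworthy" is a statement about
relative uncertainty, and that is what the package's contracts assert.

### Noise floor

Camera responses corresponding to less than about 9% of full-scale incident
radiation are dominated by sensor noise and are likely governed by a
different response regime altogether. Pixels whose linear value falls below
this floor are flagged `low_signal` (the threshold is configurable);
flagged pixels are excluded from region statistics and calibration but never
silently dropped from the image.

# Exposure standardisation and reflectance recovery

Exposure is standardised *per channel*, never through a white-balance
transform: the scale is chosen so that a perfect white reflector produces a
camera response of exactly 245 of 255 levels. Keeping the brightest valid
response at 245 leaves headroom so that averaged responses contain no
saturated pixels; anything *above* 245 sits in the saturation zone and is
flagged `clipped`.

Reflectance is recovered from the linearised image with in-frame achromatic
standards (`calibrate_exposure()` + `to_reflectance()`): for each channel,
scale = nominal reflectance / mean linear value over the standard's ROI,
after excluding clipped and low-signal pixels. Three standard types are
supported -- a near-perfect white spectrophotometry standard, a
barium-sulphate/charcoal grey reflecting about 33% across the UV band, and a
colour-checker white reflecting about 95% of visible light. When several
usable standards are present their scale estimates are combined by
inverse-variance weighting (delta-method variance from the ROI statistics);
the combination rule is this package's choice, as no canonical rule exists
for reconciling multiple in-frame standards. Values above the standard
("super-white") are kept and flagged, not clamped.

A purely advisory diagnostic, `saturation_check()`, screens the *non-linear*
image for vendor-boosted channels: no sample region should out-shine a
~90%+ achromatic standard in any channel; saturated yellows and oranges
often do in the red channel because firmware boosts it, and such regions are
not radiometrically faithful.

# Sampling statistics

Two sampling designs mirror field practice: `point_sample()` takes
15 x 15-pixel squares (225 px, comparable to a spectrophotometer probe's
footprint) around chosen centres; `grid_sample()` lays a 4 x 3 (scheme A) or
6 x 2 (scheme B) grid over a petal bounding box and draws 3 cells without
replacement under a stated seed. Pixel coordinates are 0-based, row-major,
origin top-left; squares include both borders.

Recovered-vs-predicted comparisons use the two-sided Wilcoxon rank-sum test
(`compare_methods()`): the exact null distribution when the combined sample
is at most 20 with no ties, the normal approximation with continuity
correction otherwise. The rank-based choice is justified per sample by
`normality_check()` (Shapiro--Wilk), since recovered reflectance over
patterned petals is frequently non-normal. Per-channel results are reported
without multiplicity correction, with a Holm-adjusted column added as an
extension. Whether per-region means or pooled per-pixel values are the
sampling units is configurable (`mode`), defaulting to per-region means.
`variability_summary()` ranks channels by pooled dispersion to quantify
spatio-chromatic variability per band.

# The synthetic scene generator

`make_grey_series()`, `make_swatch_frame()` and `make_flower_scene()`
generate the package's ground-truth imagery:

* grey ramps: 12--16 exposures log-spaced over [0.02, 1], each observed as a
  patch of pixels under the package noise model (Gaussian read noise,
  default SD 1 intensity level, plus a shot-noise-like term with
  coefficient 0.5 on the square root of the signal in levels -- values chosen
  once as typical of consumer sensors at moderate ISO);
* the six-swatch frame: neutral patches at 3.10, 9.11, 19.5, 37.2, 60.9 and
  94.8% reflectance beside a perfect white column -- the classic chart for
  evaluating a linearisation end to end;
* flower scenes on a 512 x 512 canvas: a disk corolla sized to admit a
  4 x 3 grid of 40 px cells, with `plain`, `gradient` (five radial
  reflectance bands) and `bullseye` (UV-absorbing centre inside a
  UV-reflective corolla) templates, all three standard types in frame, and
  a dim flat background. Petal spectra are sums of a logistic long-pass edge
  and Gaussian bands imitating a yellow flower with UV patterning; they are
  synthetic parameterisations, not measured spectra.

Two synthetic camera profiles ship with the package: a visible RGB profile
whose shared biexponential transfer was obtained by fitting that family to a
gamma-1/2.2 curve with the black offset constrained below the noise floor,
and a UV profile with a single-exponential transfer. They are labelled
synthetic throughout: the coefficients are plausible, not measurements, and
real work should fit profiles from characterisation data or load them from
config (`read_camera_profile()`).

What the generator deliberately does **not** emulate: optics (vignetting,
point-spread, chromatic aberration), demosaicing, illumination gradients
across the frame, iridescence and volume scattering, and 3-D self-shading.
Passing the end-to-end tests therefore demonstrates that the *calibration
chain* is self-consistent and unbiased under its stated model, not that any
physical camera is characterised by the shipped coefficients.

# Numerical and degenerate-input choices

* Grid mismatches between spectra are errors, never silent resampling;
  `resample_spectrum()` truncates to zero outside the source support with a
  warning rather than extrapolating.
* Reflectance above 1.05 is tolerated (field measurements can exceed the
  white standard) but flagged `super_white`.
* Inversion targets outside a transfer's range clamp to the nearest valid
  exposure with a flag.
* Constant samples are rejected by the normality check; all-tied inputs to
  the rank test return the maximal p with a warning.
* 8-bit input is asserted (integer values 0--255); anything else errors
  rather than being rescaled.
* Exact ties in the channel-dispersion ranking share the minimum rank.

# Problem sizes

The test-suite simulations use 512 x 512 scenes (single frames), 100
replicate fits for the confidence-interval coverage study, 1000 null
simulations of 15-vs-15 samples for the rank-test error rate, 10,000 seeded
draws for the grid-sampling uniformity property, and 1000-draw bootstraps
for LUT uncertainty -- sizes at which the Monte-Carlo error is comfortably
below the tolerances being asserted while the whole suite runs in well under
a minute.

# Known limitations

* Absolute radiometry (irradiance in physical units) is out of scope; all
  quantities are relative to in-frame standards.
* 8-bit pipelines only; quantisation limits recovery near full scale to
  roughly 0.3% granularity.
* Responses below the ~9% noise floor are flagged, not modelled; a darker
  regime model would be needed to use them.
* The camera colour space does not match human or pollinator colour spaces;
  mapping recovered channel reflectances into CIE or animal spaces is
  intentionally not provided.
* UV and visible frames are assumed already registered (matched
  magnification at capture); no image registration is performed.
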