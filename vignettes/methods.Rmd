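---
title: "Non-contact SpO2 from hyperspectral diffuse reflectance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact SpO2 from hyperspectral diffuse reflectance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsoximetry)
```

# The measurement problem

Pulse oximetry estimates the fraction of hemoglobin carrying oxygen (SpO2)
from the differential light absorption of oxyhemoglobin (HbO2) and
deoxyhemoglobin (Hb), but requires skin contact. A non-contact alternative
images the skin with a hyperspectral camera under broadband illumination:
each pixel carries a full diffuse-reflectance spectrum, and because Hb
absorbs more red light than HbO2 (the gap closing at the ~800 nm isosbestic
point and reversing in the near infrared), the reflectance of perfused
tissue in the red band encodes blood oxygenation. This package implements
that analysis chain end to end — reference calibration, band selection,
spatial-frequency denoising, K-means vessel delineation, and a linear
image-statistic-to-SpO2 calibration validated against repeated
pulse-oximeter readings — together with a synthetic forearm phantom that
makes every stage testable at desk scale.

# Reference calibration

Raw sensor counts mix illuminant shape, sensor gain and dark offset.
`calibrate_cube()` converts a measured cube to percent reflectance with the
standard white/dark normalization

$$R(\lambda) = \frac{I_m(\lambda) - I_d(\lambda)}{I_w(\lambda) - I_d(\lambda)} \times 100\,\%$$

per pixel and band, where $I_w$ is a capture of a near-perfect (0.99)
diffuser and $I_d$ a capture with blocked optics. Two numerical choices
matter:

* **Denominator floor.** Pixels with $|I_w - I_d| \le \tau$ are marked
  invalid rather than producing huge ratios; $\tau$ defaults to $10^{-6}$
  of the white cube's dynamic range. Invalid pixels are excluded from every
  downstream statistic.
* **No clipping.** Values outside [0, 100] % are retained and counted in a
  per-band quality report (`calibration_report()`); clipping would silently
  bias region means.

The calibration is exactly linear in the measured cube and exactly
invariant to any positive per-band gain applied jointly to the three cubes
— both properties are tested to machine precision.

# The synthetic forearm phantom

No raw data accompanied the study this design follows, so the package
ships a forward model (`phantom_config()`, `render_phantom()`) whose
ground truth is known by construction:

* **Skin background.** A smooth logistic rise of reflectance with
  wavelength (low in the blue-green, higher in the red/NIR), spatially
  uniform.
* **Vessels.** Tubular inclusions (sinuous polyline centerline, fixed
  radius) attenuating the background by single-pass Beer–Lambert
  absorption, $R = R_{bg}\exp\{-d\,f\,[S\,\varepsilon_{HbO_2} +
  (1-S)\,\varepsilon_{Hb}]\}$ with per-vessel optical depth multiplier
  $d$, blood fraction $f$ and saturation $S$. The optical path is flat
  (top-hat) inside the radius — the minimal model that yields the
  saturation-to-reflectance monotonicity the pipeline exploits; radiative
  transfer, cylindrical chord profiles, melanin heterogeneity and specular
  glints are deliberately out of scope.
* **Sensor.** Measured = illuminant x reflectance + dark offset + read
  noise (Gaussian, `dark_offset_sd` counts) + a signal-proportional
  Gaussian shot-noise surrogate (`shot_noise_scale`, default 1 % of
  signal). Poisson noise was rejected to keep the variance
  parameterization explicit. The white reference is the same illuminant on
  a 0.99 diffuser; sensor gain is folded into the illuminant.

The **stylized extinction spectra** (`extinction_spectrum()`) are sums of
Gaussians, not literature tabulations: the package's claims are about
self-consistent recovery, and molar-accurate tables would add provenance
burden without changing any algorithm under test. They are built as a
shared base curve plus/minus a difference term, which enforces exactly the
structure oximetry relies on: Hb above HbO2 throughout 590–650 nm with the
gap peaking at 610 nm, an exact crossing at the 800 nm isosbestic point,
and HbO2 above Hb in the NIR. The green-band bump of the base curve decays
before 590 nm and the red difference band is narrow (sigma 35 nm), so the
base absorption is locally flat across 600–650 nm and the phantom's
saturation-sensitivity peak is driven by the extinction difference rather
than by base-curve slopes; with broad bumps the sensitivity peak would sit
tens of nm redward of the extinction-difference peak, which is a property
of real tissue worth avoiding in a phantom meant to validate band
selection against its own extinction ground truth.

Default study conditions mirror the emulated protocol: 128 x 128 pixels,
64 bands over 400–900 nm (the illumination range; the camera's nominal
4.68 nm resolution over 128 bands is halved to keep desk-scale runtimes),
one vein (radius 5 px, S about 0.25 below arterial) and one artery (radius
4 px, S = arterial SaO2), five integer pulse-oximeter readings per subject
with 0.8 %SpO2 pre-rounding noise — matching the spread of the printed
repeated-reading tables. `generate_cohort()` spaces true SaO2 evenly
across the requested range and derives an independent RNG stream per
subject, so cohorts are bit-reproducible.

What passing tests on this phantom do **not** show: robustness to curved
anatomy, illumination falloff, motion, melanin variation, or specular
reflection — none of which the phantom contains.

# Band selection

Per-subject signatures are ROI mean reflectance spectra
(`roi_signature()`), smoothed along wavelength with a centered moving
average (`moving_average()`, window K = 10 bands per the emulated
protocol; the window shrinks symmetrically at the spectrum ends rather
than inventing padding). `select_optimum_band()` then scores each band in
560–700 nm — a window bracketing the red discrimination band — by the
absolute Pearson correlation across subjects between band reflectance and
mean oximeter SpO2.

One subtlety drives the design: with a cohort of ~10 subjects the
correlation saturates into a plateau (|r| about 0.99 across the entire red
band), and the floating-point argmax of that plateau is noise. Bands
within `tie_tol = 0.01` of the maximum are therefore treated as tied, and
the tie is broken by the larger between-subject reflectance standard
deviation — the band of maximum SpO2-driven variation — then by lower
wavelength. On default cohorts this lands within one band of the
extinction-difference peak and is stable across seeds. Constant-reflectance
bands score zero (their correlation is undefined), and a constant SpO2
vector is an error.

# Image enhancement

The selected band image is min–max normalized (`normalize_image()`;
constant images map to zero) and denoised in the spatial-frequency domain
(`fft_denoise()`): forward 2-D FFT, masking, inverse transform. The mask
zeroes the DC coefficient (removing the global illumination pedestal, so
the output mean is ~0) and attenuates high spatial frequencies with a
Gaussian roll-off at `lowpass_frac = 0.25` of Nyquist — wide enough to
keep vessel-scale structure, strong enough to suppress pixel noise. The
frequency radius is measured as max(|f_row|, |f_col|)/Nyquist, so a hard
mask at fraction 1 is a true all-pass (a Euclidean radius would clip the
spectrum's corners). Both the profile and the cutoff are configurable;
this is the least constrained stage of the emulated protocol.
`contour_quantize()` renders the result as an equal-width contour map
(equal-count levels were considered and rejected as they hide absolute
contrast between vessels).

# Vessel delineation

`kmeans_lloyd()` is Lloyd's algorithm with k-means++ seeding, best of
`n_init = 10` restarts by within-cluster sum of squares, farthest-point
re-seeding of empty clusters, and a per-iteration inertia trace (tested to
be non-increasing); it is deterministic given a seed, and `K = 10` follows
the emulated protocol. Clustering operates on the **normalized** band
image: the protocol's own figure chain applies K-means to the normalized
image, and the alternative (clustering the low-pass-filtered image) is
structurally worse — blur creates gradient rings around the dark vein
whose clusters fall between vein and artery intensity and break the
labeling rule below.

`label_vessels()` scores each cluster by pixel fraction, mean intensity
and elongation, and admits as vessel candidates those with fraction in
[0.002, 0.2] and elongation >= 2. Elongation is the major/minor axis ratio
from the second moments of the whole cluster pixel cloud — robust to the
fragmentation of connected components when pixel noise splits a tubular
cluster. Because K = 10 exceeds the phantom's three intensity levels,
k-means routinely splits one vessel's noise distribution into
near-identical clusters (means ~1 % of the image range apart, versus ~40 %
between vessels); candidates within `merge_tol = 0.05` of a group's level
are merged into one vessel mask. The lowest-intensity group is the vein —
at the red analysis band deoxygenated blood absorbs most — and the
next-lowest is the artery; a single candidate group leaves the artery mask
empty with a warning, and no candidates is an error carrying the per-
cluster diagnostics.

# SpO2 statistics and calibration

`reading_stats()` implements the repeated-reading arithmetic of the
emulated protocol: arithmetic mean, sample (n-1) standard deviation and
standard error SD/sqrt(n), reported at table precision (mean 1 d.p.,
SD/SE 2 d.p.) alongside full precision. The sample SD is not a stylistic
choice: it is the definition that reproduces every printed table row
(e.g. readings 97, 96, 97, 95, 97 give SD 0.894 -> 0.89; the population SD
would give 0.80).

`region_stats()` takes mean and SD of the FFT-filtered band image over a
mask; `fit_spo2_calibration()` fits the ordinary-least-squares line
SpO2 = a x mean + b across subjects. The calibration regresses on the
**artery** region mean: a pulse oximeter reads arterial saturation, and the
per-image min–max normalization pins the image minimum — the vein core —
near zero, stripping the vein mean of most of its saturation signal (on
default cohorts the artery mean correlates with true SaO2 at r about 0.99,
the vein mean at about 0.6). `estimate_spo2()` applies the line with a
[50, 100] % clip and flag, `agreement_report()` gives bias/MAE/RMSE/r
against the oximeter, and `loo_spo2_estimates()` is the leave-one-out
check that the map generalizes beyond its fitting cohort. On the default
10-subject cohort the leave-one-out MAE is a few tenths of a percent SpO2
— of the same order as the oximeter means' own standard errors.

# Orchestration and problem sizes

`run_simulate()` / `run_analyze()` / `run_report()` chain the stages
against a YAML-configurable directory layout (ENVI cubes, PNG masks, CSV
tables, JSON manifests recording all seeds); a thin command-line wrapper
ships in `inst/cli/hsoximetry.R`. Per-subject analysis failures are logged
and skipped rather than aborting a cohort. The test suite exercises unit
fixtures at 48 x 48 x 24 and the full study-scale recovery at
128 x 128 x 64 with 10 subjects; the latter is the problem size reported
by `scripts/acceptance.R`.

# Known limitations

* The phantom's spatially uniform background makes min–max normalization
  benign; on real skin the image extremes are not anatomically stable and
  a quantile-based normalization would be preferable.
* Band selection needs >= 3 subjects with non-constant SpO2; it cannot run
  on a single capture.
* The linear SpO2 map is validated only on synthetic cohorts; nothing here
  establishes clinical accuracy.
* ENVI support covers BSQ/BIL reading and BSQ float64 writing — the
  dialects the pipeline itself produces — not tiled, compressed or BIP
  variants.
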