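Package: hsoximetry
Title: Non-Contact Blood Oxygen Saturation from Hyperspectral Diffuse
    Reflectance Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating blood oxygen saturation (SpO2) from
    non-contact hyperspectral diffuse-reflectance images of skin. Provides
    white/dark reference calibration of raw radiance cubes to percent
    reflectance, ENVI cube input/output, extraction and smoothing of
    region-of-interest spectral signatures, selection of the wavelength most
    correlated with pulse-oximeter SpO2, spatial-frequency (2-D FFT)
    denoising of band images, K-means delineation of veins and arteries,
    repeated-reading statistics, and linear calibration of vessel-region
    image statistics to SpO2 with agreement reporting. A synthetic
    Beer-Lambert forearm phantom generator with known per-pixel saturation
    and matched noisy pulse-oximeter readings makes the whole pipeline
    testable without human-subject data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
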