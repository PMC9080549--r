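#' Stylized hemoglobin extinction spectra
#'
#' Smooth sum-of-Gaussians stand-ins for the oxy- (HbO2) and
#' deoxy-hemoglobin (Hb) extinction coefficients, built as a shared base
#' curve plus/minus a difference term. The pair reproduces the two features
#' tissue oximetry actually relies on: Hb absorbs more than HbO2 throughout
#' the red (the gap peaks near 610 nm and is strictly positive on
#' 590-650 nm), the curves cross exactly at the 800 nm isosbestic point, and
#' beyond it HbO2 absorbs more in the near infrared. Units are arbitrary but
#' consistent: the product depth x blood fraction x epsilon is a
#' dimensionless optical density.
#'
#' These are deliberately not literature tabulations — the synthetic phantom
#' only needs a self-consistent asymmetry, not molar accuracy.
#'
#' @param name `"Hb"` or `"HbO2"`.
#' @param wavelengths Wavelength grid in nm, within \[400, 1000\], strictly
#'   increasing.
#' @return A `chromophore_spectrum`: list with `name`, `wavelengths`,
#'   `epsilon` (strictly positive).
#' @examples
#' wl <- seq(400, 900, by = 10)
#' hb <- extinction_spectrum("Hb", wl)
#' hbo2 <- extinction_spectrum("HbO2", wl)
#' all(hb$epsilon[wl >= 590 & wl <= 650] > hbo2$epsilon[wl >= 590 & wl <= 650])
#' @export
extinction_spectrum <- function(name, wavelengths) {
  if (!name %in% c("Hb", "HbO2")) {
    stop(sprintf("unknown chromophore '%s' (expected \"Hb\" or \"HbO2\")", name),
         call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (any(wavelengths < 400 | wavelengths > 1000)) {
    stop("wavelengths must lie within [400, 1000] nm", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  eps <- extinction_base(wavelengths) +
    (if (name == "Hb") 1 else -1) * extinction_delta(wavelengths)
  structure(list(name = name, wavelengths = wavelengths, epsilon = eps),
            class = "chromophore_spectrum")
}

gaussian_bump <- function(wl, mu, sigma) exp(-(wl - mu)^2 / (2 * sigma^2))

# shared base absorption: Soret/green band + mild NIR rise over a pedestal
extinction_base <- function(wl) {
  0.8 + 2.8 * gaussian_bump(wl, 550, 18) + 0.8 * gaussian_bump(wl, 930, 110)
}

# half-difference (eps_Hb - eps_HbO2)/2: red bump centred at 610 nm minus a
# NIR bump scaled so the difference is exactly zero at the 800 nm isosbestic
extinction_delta <- function(wl) {
  kappa <- gaussian_bump(800, 610, 35) / gaussian_bump(800, 950, 120)
  0.6 * (gaussian_bump(wl, 610, 35) - kappa * gaussian_bump(wl, 950, 120))
}

#' Wavelength of maximal Hb/HbO2 extinction difference
#'
#' Returns the grid wavelength maximizing `|eps_Hb - eps_HbO2|` — the band
#' where, under the stylized spectra, reflectance is most sensitive to
#' oxygen saturation. Used as the reference point when checking the
#' data-driven band selection.
#'
#' @param wavelengths Wavelength grid in nm.
#' @return The wavelength (nm) of the maximal absolute difference.
#' @export
extinction_difference_peak <- function(wavelengths) {
  hb <- extinction_spectrum("Hb", wavelengths)
  hbo2 <- extinction_spectrum("HbO2", wavelengths)
  wavelengths[which.max(abs(hb$epsilon - hbo2$epsilon))]
}

#' Effective extinction of partially oxygenated blood
#'
#' Linear mix `S * eps_HbO2 + (1 - S) * eps_Hb` for saturation fraction `S`.
#'
#' @param saturation Fraction of hemoglobin carrying oxygen, in \[0, 1\].
#' @param wavelengths Wavelength grid (nm).
#' @return Numeric vector of effective extinction per band.
#' @export
blood_extinction <- function(saturation, wavelengths) {
  stopifnot(saturation >= 0, saturation <= 1)
  hb <- extinction_spectrum("Hb", wavelengths)
  hbo2 <- extinction_spectrum("HbO2", wavelengths)
  saturation * hbo2$epsilon + (1 - saturation) * hb$epsilon
}
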