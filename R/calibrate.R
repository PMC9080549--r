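#' White/dark reference calibration to percent reflectance
#'
#' Converts a raw measured cube to percent diffuse reflectance using paired
#' white-reference and dark-reference cubes:
#' `R = (I_m - I_d) / (I_w - I_d) * 100`, per pixel and band. Pixels where
#' the denominator magnitude `|I_w - I_d|` is at or below the floor `tau`
#' are marked invalid and excluded from all downstream statistics. Values
#' are deliberately not clipped to \[0, 100\]: out-of-range reflectances are
#' retained (and counted in the quality report) so region means are not
#' silently biased.
#'
#' @param measured,white,dark [hyper_cube()]s of kind `"raw"` sharing shape
#'   and wavelength axis. `white` and `dark` may also be numeric vectors of
#'   one value per band (a per-band scalar reference, for phantoms with
#'   spatially uniform illumination).
#' @param denom_floor Denominator floor `tau`; default `1e-6` times the
#'   white cube's dynamic range.
#' @return A [hyper_cube()] of kind `"reflectance"` (percent), carrying a
#'   `valid_mask` (a pixel is valid if every band's denominator clears the
#'   floor) and a per-band quality report retrievable with
#'   [calibration_report()].
#' @examples
#' wl <- c(500, 600)
#' m <- hyper_cube(array(5, c(2, 2, 2)), wl)
#' w <- hyper_cube(array(9, c(2, 2, 2)), wl)
#' d <- hyper_cube(array(1, c(2, 2, 2)), wl)
#' calibrate_cube(m, w, d)$values[1, 1, ] # 50% at both bands
#' @export
calibrate_cube <- function(measured, white, dark, denom_floor = NULL) {
  stopifnot(inherits(measured, "hyper_cube"))
  d <- dim(measured$values)
  white <- as_reference_cube(white, d, measured$wavelengths, "white")
  dark <- as_reference_cube(dark, d, measured$wavelengths, "dark")
  if (!isTRUE(all.equal(measured$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(measured$wavelengths, dark$wavelengths))) {
    stop("measured, white and dark cubes must share a wavelength axis",
         call. = FALSE)
  }
  if (!identical(dim(white$values), d) || !identical(dim(dark$values), d)) {
    stop("measured, white and dark cubes must share dimensions", call. = FALSE)
  }

  denom <- white$values - dark$values
  if (is.null(denom_floor)) {
    rng <- diff(range(white$values, finite = TRUE))
    denom_floor <- 1e-6 * if (rng > 0) rng else 1
  }
  bad <- abs(denom) <= denom_floor
  refl <- (measured$values - dark$values) / denom * 100
  refl[bad] <- NA_real_

  valid_mask <- apply(!bad, c(1, 2), all)
  if (!any(valid_mask)) {
    stop("calibration produced no valid pixels (denominator below floor everywhere)",
         call. = FALSE)
  }

  report <- tibble::tibble(
    band = seq_len(d[3]),
    wavelength_nm = measured$wavelengths,
    pct_invalid = 100 * apply(bad, 3, mean),
    pct_below_0 = 100 * apply(refl < 0, 3, function(x) mean(x, na.rm = TRUE)),
    pct_above_100 = 100 * apply(refl > 100, 3, function(x) mean(x, na.rm = TRUE))
  )

  out <- hyper_cube(refl, measured$wavelengths, kind = "reflectance",
                    valid_mask = valid_mask)
  attr(out, "quality_report") <- report
  out
}

as_reference_cube <- function(ref, d, wavelengths, what) {
  if (inherits(ref, "hyper_cube")) return(ref)
  if (is.numeric(ref) && length(ref) == d[3]) {
    return(hyper_cube(array(rep(ref, each = d[1] * d[2]), dim = d),
                      wavelengths, kind = "raw"))
  }
  stop(sprintf("`%s` must be a hyper_cube or a per-band numeric vector", what),
       call. = FALSE)
}

#' Per-band calibration quality report
#'
#' @param calibrated A cube returned by [calibrate_cube()].
#' @return Tibble with columns `band`, `wavelength_nm`, `pct_invalid`,
#'   `pct_below_0`, `pct_above_100`.
#' @export
calibration_report <- function(calibrated) {
  rep <- attr(calibrated, "quality_report")
  if (is.null(rep)) stop("no quality report attached; was this cube calibrated?",
                         call. = FALSE)
  rep
}
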