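#' Min-max normalize a band image
#'
#' Rescales the valid pixels linearly so the minimum maps to 0 and the
#' maximum to 1; a constant image maps to all zeros. Invalid pixels stay
#' invalid (NA).
#'
#' @param img A [band_image()].
#' @return A [band_image()] of kind `"normalized"`.
#' @export
normalize_image <- function(img) {
  stopifnot(inherits(img, "band_image"))
  v <- valid_values(img)
  if (length(v) == 0) stop("image has no valid pixels", call. = FALSE)
  rng <- range(v)
  out <- img$values
  out <- if (diff(rng) > 0) (out - rng[1]) / diff(rng) else out * 0
  if (!is.null(img$valid_mask)) out[!img$valid_mask] <- NA_real_
  band_image(out, wavelength = img$wavelength, kind = "normalized",
             valid_mask = img$valid_mask)
}

#' Spatial-frequency denoising of a band image
#'
#' Forward 2-D FFT, multiplication of the spectrum by a frequency mask, and
#' inverse transform (real part). The mask zeroes the DC coefficient when
#' `remove_dc` (so the output mean is ~0, removing the global illumination
#' pedestal) and attenuates spatial frequencies above `lowpass_frac` of
#' Nyquist with either a `"gaussian"` roll-off or a `"hard"` cutoff,
#' suppressing pixel-scale noise while keeping vessel-scale structure.
#' Frequency radius is measured as `max(|f_row|, |f_col|) / Nyquist`, so a
#' hard mask with `lowpass_frac = 1` passes everything.
#'
#' @param img A [band_image()] with finite values everywhere.
#' @param remove_dc Zero the DC coefficient? Default `TRUE`.
#' @param lowpass_frac Cutoff as a fraction of Nyquist, in (0, 1\].
#' @param profile `"gaussian"` (default) or `"hard"`.
#' @return A [band_image()] of kind `"filtered"`.
#' @export
fft_denoise <- function(img, remove_dc = TRUE, lowpass_frac = 0.25,
                        profile = c("gaussian", "hard")) {
  stopifnot(inherits(img, "band_image"))
  profile <- match.arg(profile)
  if (lowpass_frac <= 0 || lowpass_frac > 1) {
    stop("lowpass_frac must lie in (0, 1]", call. = FALSE)
  }
  x <- img$values
  if (!all(is.finite(x))) {
    stop("fft_denoise requires finite values at every pixel", call. = FALSE)
  }
  mask <- frequency_mask(nrow(x), ncol(x), remove_dc, lowpass_frac, profile)
  spec <- stats::fft(x) * mask
  out <- Re(stats::fft(spec, inverse = TRUE)) / length(x)
  band_image(out, wavelength = img$wavelength, kind = "filtered",
             valid_mask = img$valid_mask)
}

# frequency grid in cycles/image for an axis of length n, FFT ordering
fft_freqs <- function(n) {
  i <- 0:(n - 1)
  ifelse(i <= n %/% 2, i, i - n)
}

frequency_mask <- function(nr, nc, remove_dc, lowpass_frac, profile) {
  fr <- abs(fft_freqs(nr)) / (nr / 2)
  fc <- abs(fft_freqs(nc)) / (nc / 2)
  r <- outer(fr, fc, pmax)        # Chebyshev radius, 1 at Nyquist
  m <- switch(profile,
    hard = (r <= lowpass_frac) * 1,
    gaussian = exp(-(r / lowpass_frac)^2 / 2)
  )
  if (remove_dc) m[1, 1] <- 0
  m
}

#' Equal-width contour quantization
#'
#' Bins the valid values of an image into `levels` equal-width intensity
#' bands labelled `0 .. levels - 1` (a contour-map representation of the
#' filtered image); the labelling is monotone in value.
#'
#' @param img A [band_image()].
#' @param levels Number of contour levels, >= 2.
#' @return Integer matrix of labels (NA at invalid pixels).
#' @export
contour_quantize <- function(img, levels = 10) {
  stopifnot(inherits(img, "band_image"))
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  v <- valid_values(img)
  if (length(v) == 0) stop("image has no valid pixels", call. = FALSE)
  rng <- range(v)
  out <- img$values
  if (diff(rng) == 0) {
    lab <- matrix(0L, nrow(out), ncol(out))
  } else {
    lab <- matrix(pmin(as.integer(floor((out - rng[1]) / diff(rng) * levels)),
                       levels - 1L),
                  nrow(out), ncol(out))
  }
  if (!is.null(img$valid_mask)) lab[!img$valid_mask] <- NA_integer_
  lab[!is.finite(img$values)] <- NA_integer_
  lab
}
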