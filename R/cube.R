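#' Hyperspectral cube
#'
#' A hyperspectral cube is a rank-3 intensity array (rows x cols x bands)
#' with a strictly increasing wavelength axis in nanometres and a `kind` tag
#' recording what the values mean: `"raw"` sensor counts, `"reflectance"` in
#' percent, or `"normalized"` values in \[0, 1\]. An optional per-pixel
#' logical `valid_mask` marks pixels whose values are defined (e.g. where the
#' white minus dark reference exceeded the denominator floor during
#' calibration).
#'
#' @param values Numeric array, `rows x cols x bands`. A matrix is promoted
#'   to a single-band cube.
#' @param wavelengths Numeric vector of band-centre wavelengths (nm),
#'   strictly increasing, length equal to `dim(values)[3]`.
#' @param kind One of `"raw"`, `"reflectance"`, `"normalized"`.
#' @param valid_mask Optional logical matrix `rows x cols`; `NULL` means all
#'   pixels valid.
#'
#' @return An object of class `hyper_cube`.
#' @examples
#' cube <- hyper_cube(array(1, dim = c(4, 4, 3)), c(500, 600, 700))
#' dim(cube$values)
#' @export
hyper_cube <- function(values, wavelengths,
                       kind = c("raw", "reflectance", "normalized"),
                       valid_mask = NULL) {
  kind <- match.arg(kind)
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a rows x cols x bands array", call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3]) {
    stop(sprintf("cube has %d bands but %d wavelengths",
                 dim(values)[3], length(wavelengths)), call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!is.null(valid_mask)) {
    valid_mask <- matrix(as.logical(valid_mask), dim(values)[1], dim(values)[2])
  }
  if (kind == "normalized") {
    v <- if (is.null(valid_mask)) values else values[rep_len(valid_mask, length(values))]
    v <- v[is.finite(v)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      stop("kind = \"normalized\" requires valid values in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(values = values, wavelengths = wavelengths, kind = kind,
         valid_mask = valid_mask),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind = %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  if (!is.null(x$valid_mask)) {
    cat(sprintf("  valid pixels: %d / %d\n", sum(x$valid_mask), length(x$valid_mask)))
  }
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Index of the band nearest a target wavelength
#'
#' Finds the band whose centre wavelength is closest to `target_nm`; exact
#' ties are broken toward the lower wavelength. Targets more than 50 nm
#' outside the cube's wavelength range are rejected.
#'
#' @param cube A [hyper_cube()].
#' @param target_nm Target wavelength in nm.
#' @return Integer band index (1-based).
#' @examples
#' cube <- hyper_cube(array(0, dim = c(1, 1, 4)), c(600, 605, 610, 615))
#' nearest_band(cube, 610)
#' @export
nearest_band <- function(cube, target_nm) {
  stopifnot(inherits(cube, "hyper_cube"), is.numeric(target_nm),
            length(target_nm) == 1)
  wl <- cube$wavelengths
  if (target_nm < min(wl) - 50 || target_nm > max(wl) + 50) {
    stop(sprintf("target %.1f nm is outside [%.1f, %.1f] +/- 50 nm",
                 target_nm, min(wl), max(wl)), call. = FALSE)
  }
  d <- abs(wl - target_nm)
  # which.min returns the first (lowest-wavelength) minimiser, the tie rule
  which.min(d)
}

#' Extract one band as a 2-D image
#'
#' @param cube A [hyper_cube()].
#' @param target_nm Wavelength to extract (nearest band is used).
#' @return A [band_image()] carrying the band's actual centre wavelength and
#'   the cube's kind and validity mask.
#' @export
extract_band <- function(cube, target_nm) {
  b <- nearest_band(cube, target_nm)
  band_image(cube$values[, , b], wavelength = cube$wavelengths[b],
             kind = if (cube$kind == "raw") "reflectance" else cube$kind,
             valid_mask = cube$valid_mask)
}

#' Three-channel visible composite of a cube
#'
#' Splits `[lo_nm, hi_nm]` into three equal-width wavelength thirds and
#' averages the cube within each third to form blue, green and red channels;
#' each channel is independently min-max scaled to \[0, 1\]. This is a
#' display aid, not a colorimetric rendering.
#'
#' @param cube A [hyper_cube()] with at least three bands inside the range.
#' @param lo_nm,hi_nm Wavelength range, default 400-700 nm.
#' @return A `rows x cols x 3` array with channels ordered R, G, B in
#'   planes 1-3 (suitable for [png::writePNG()] after `aperm` if needed).
#' @export
visible_composite <- function(cube, lo_nm = 400, hi_nm = 700) {
  stopifnot(inherits(cube, "hyper_cube"), lo_nm < hi_nm)
  wl <- cube$wavelengths
  inside <- which(wl >= lo_nm & wl <= hi_nm)
  if (length(inside) < 3) {
    stop(sprintf("need >= 3 bands in [%.0f, %.0f] nm, found %d",
                 lo_nm, hi_nm, length(inside)), call. = FALSE)
  }
  edges <- seq(lo_nm, hi_nm, length.out = 4)
  d <- dim(cube$values)
  out <- array(0, dim = c(d[1], d[2], 3))
  # thirds: lowest wavelengths -> blue (plane 3), highest -> red (plane 1)
  for (i in 1:3) {
    bands <- inside[wl[inside] >= edges[i] &
                      (wl[inside] < edges[i + 1] | (i == 3 & wl[inside] <= edges[4]))]
    if (length(bands) == 0) bands <- inside[which.min(abs(wl[inside] - mean(edges[i:(i + 1)])))]
    ch <- apply(cube$values[, , bands, drop = FALSE], c(1, 2), mean)
    rng <- range(ch, finite = TRUE)
    ch <- if (diff(rng) > 0) (ch - rng[1]) / diff(rng) else ch * 0
    out[, , 4 - i] <- ch
  }
  out
}

#' 2-D band image
#'
#' A single-wavelength scalar field extracted from a cube, tagged with its
#' wavelength and processing stage (`reflectance`, `normalized`, `filtered`).
#'
#' @param values Numeric matrix (rows x cols).
#' @param wavelength Band-centre wavelength in nm.
#' @param kind One of `"reflectance"`, `"normalized"`, `"filtered"`.
#' @param valid_mask Optional logical matrix; `NULL` means all valid.
#' @return An object of class `band_image`.
#' @export
band_image <- function(values, wavelength = NA_real_,
                       kind = c("reflectance", "normalized", "filtered"),
                       valid_mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (!is.null(valid_mask)) {
    valid_mask <- matrix(as.logical(valid_mask), nrow(values), ncol(values))
  }
  if (kind == "normalized") {
    v <- if (is.null(valid_mask)) values else values[valid_mask]
    v <- v[is.finite(v)]
    if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12)) {
      stop("normalized band image must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(values = values, wavelength = wavelength, kind = kind,
                 valid_mask = valid_mask),
            class = "band_image")
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("<band_image> %d x %d @ %.1f nm, kind = %s\n",
              nrow(x$values), ncol(x$values), x$wavelength, x$kind))
  invisible(x)
}

#' @export
dim.band_image <- function(x) dim(x$values)

valid_values <- function(img) {
  v <- img$values
  if (!is.null(img$valid_mask)) v <- v[img$valid_mask]
  v[is.finite(v)]
}
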