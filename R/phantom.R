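#' Vessel specification for the forearm phantom
#'
#' Describes one subcutaneous tubular vessel: a 2-D centerline polyline (in
#' pixel coordinates, rows/cols), a radius, an effective optical path
#' multiplier, the fraction of the path occupied by blood, and the blood's
#' oxygen saturation. Arteries typically carry saturation 0.95-0.99, veins
#' 0.6-0.8.
#'
#' @param centerline Numeric matrix with columns `row`, `col` (pixels,
#'   1-based); at least one point.
#' @param radius Vessel radius in pixels, >= 1.
#' @param depth_factor Dimensionless effective optical path multiplier, > 0.
#' @param blood_fraction Fraction of the optical path occupied by blood,
#'   in \[0, 1\].
#' @param saturation Oxygen saturation fraction S in \[0, 1\].
#' @param role `"vein"` or `"artery"`; used to assemble ground-truth masks.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(centerline, radius, depth_factor = 1.6,
                        blood_fraction = 0.85, saturation,
                        role = c("vein", "artery")) {
  role <- match.arg(role)
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 2, nrow(centerline) >= 1,
            radius >= 1, depth_factor > 0,
            blood_fraction >= 0, blood_fraction <= 1,
            saturation >= 0, saturation <= 1)
  structure(list(centerline = centerline, radius = radius,
                 depth_factor = depth_factor, blood_fraction = blood_fraction,
                 saturation = saturation, role = role),
            class = "vessel_spec")
}

#' Forearm phantom configuration
#'
#' Collects everything the synthetic capture generator needs: image size,
#' wavelength grid, smooth skin-background reflectance parameters, vessels,
#' illuminant spectral shape (sensor gain folded in), dark-offset and noise
#' levels, and the RNG seed. The defaults emulate a 128 x 128 forearm patch
#' imaged over 400-900 nm in 64 bands with one vein and one artery running
#' across the field of view.
#'
#' @param height,width Image size in pixels.
#' @param band_grid Wavelength grid in nm, within \[400, 1000\].
#' @param background_params List with `base`, `rise`, `center`, `width`:
#'   skin background reflectance `base + rise * plogis((lambda - center) /
#'   width)` — low in the blue, rising through the red, as skin does.
#' @param vessels List of [vessel_spec()] objects. Defaults to a gently
#'   sinuous vein (radius 5, S = 0.70) and artery (radius 4, S = 0.97).
#' @param illuminant Strictly positive counts per band (gain folded in), or
#'   `NULL` for a smooth broadband default peaking in the NIR.
#' @param dark_offset_mean,dark_offset_sd Sensor dark level and read noise,
#'   in counts.
#' @param shot_noise_scale Signal-proportional noise: the Gaussian SD added
#'   to a signal of `s` counts is `shot_noise_scale * s`.
#' @param seed RNG seed making [render_phantom()] deterministic.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 128, width = 128,
                           band_grid = seq(400, 900, length.out = 64),
                           background_params = list(base = 0.25, rise = 0.35,
                                                    center = 580, width = 40),
                           vessels = default_vessels(height, width),
                           illuminant = NULL,
                           dark_offset_mean = 100, dark_offset_sd = 2,
                           shot_noise_scale = 0.01,
                           seed = 1L) {
  band_grid <- as.numeric(band_grid)
  if (length(band_grid) == 0) stop("band_grid must be non-empty", call. = FALSE)
  if (any(band_grid < 400 | band_grid > 1000)) {
    stop("band_grid must lie within [400, 1000] nm", call. = FALSE)
  }
  if (length(band_grid) > 1 && any(diff(band_grid) <= 0)) {
    stop("band_grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(illuminant)) {
    illuminant <- 3000 * (0.4 + 0.6 * gaussian_bump(band_grid, 800, 300))
  }
  if (length(illuminant) != length(band_grid) || any(illuminant <= 0)) {
    stop("illuminant must be strictly positive on the band grid", call. = FALSE)
  }
  stopifnot(height >= 8, width >= 8, dark_offset_sd >= 0, shot_noise_scale >= 0)
  structure(list(height = height, width = width, band_grid = band_grid,
                 background_params = background_params, vessels = vessels,
                 illuminant = illuminant,
                 dark_offset_mean = dark_offset_mean,
                 dark_offset_sd = dark_offset_sd,
                 shot_noise_scale = shot_noise_scale,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

default_vessels <- function(height, width, vein_sat = 0.70, artery_sat = 0.97) {
  cols <- seq(8, width - 7, length.out = 48)
  vein_rows <- 0.35 * height + 0.04 * height * sin(2 * pi * cols / width)
  artery_rows <- 0.68 * height + 0.03 * height * sin(2 * pi * cols / width + 1.2)
  list(
    vessel_spec(cbind(row = vein_rows, col = cols), radius = 5,
                saturation = vein_sat, role = "vein"),
    vessel_spec(cbind(row = artery_rows, col = cols), radius = 4,
                depth_factor = 1.4, saturation = artery_sat, role = "artery")
  )
}

skin_background <- function(band_grid, p) {
  p$base + p$rise * stats::plogis((band_grid - p$center) / p$width)
}

# boolean mask of pixels within `radius` of the centerline polyline
vessel_mask <- function(vessel, height, width) {
  cl <- vessel$centerline
  px_row <- matrix(rep(seq_len(height), width), height, width)
  px_col <- matrix(rep(seq_len(width), each = height), height, width)
  d2 <- matrix(Inf, height, width)
  n <- nrow(cl)
  segs <- if (n == 1) cbind(1, 1) else cbind(seq_len(n - 1), 2:n)
  for (s in seq_len(nrow(segs))) {
    a <- cl[segs[s, 1], ]; b <- cl[segs[s, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2s <- (px_row - a[1])^2 + (px_col - a[2])^2
    } else {
      t <- ((px_row - a[1]) * ab[1] + (px_col - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2s <- (px_row - (a[1] + t * ab[1]))^2 + (px_col - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, d2s)
  }
  d2 <= vessel$radius^2
}

#' Render a synthetic forearm capture set
#'
#' Forward model: each pixel's true reflectance is the smooth skin
#' background attenuated, inside vessels, by single-pass Beer-Lambert
#' absorption, `R_true = R_bg(lambda) * exp(-depth_factor * blood_fraction *
#' [S * eps_HbO2 + (1 - S) * eps_Hb])`. The sensor sees `illuminant * R +
#' dark_offset + noise`; the white reference is a 0.99-reflectance diffuser
#' under the same illuminant, and the dark reference is offset plus read
#' noise only. Rendering is deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return A `raw_capture_set`: list with `measured`, `white`, `dark`
#'   ([hyper_cube()]s of kind `"raw"` sharing dimensions and wavelength
#'   axis) and `truth` (per-pixel `sao2_map`, NA outside vessels, plus
#'   logical `vein_mask` / `artery_mask`).
#' @export
render_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$height; w <- config$width
  wl <- config$band_grid
  nb <- length(wl)

  r_bg <- skin_background(wl, config$background_params)
  # per-pixel optical density profile
  od <- matrix(0, h, w)            # scalar multiplier map
  eps_map <- array(0, dim = c(h, w, nb))
  vein_mask <- matrix(FALSE, h, w)
  artery_mask <- matrix(FALSE, h, w)
  sao2_map <- matrix(NA_real_, h, w)
  for (v in config$vessels) {
    if (any(v$centerline[, 1] - v$radius < 1 | v$centerline[, 1] + v$radius > h |
            v$centerline[, 2] - v$radius < 1 | v$centerline[, 2] + v$radius > w)) {
      stop("vessel does not fit inside the image bounds", call. = FALSE)
    }
    m <- vessel_mask(v, h, w)
    eps <- blood_extinction(v$saturation, wl)
    idx <- which(m)
    for (b in seq_len(nb)) {
      plane <- eps_map[, , b]
      plane[idx] <- v$depth_factor * v$blood_fraction * eps[b]
      eps_map[, , b] <- plane
    }
    sao2_map[idx] <- v$saturation
    if (v$role == "vein") vein_mask <- vein_mask | m else artery_mask <- artery_mask | m
  }

  r_true <- array(rep(r_bg, each = h * w), dim = c(h, w, nb)) * exp(-eps_map)
  illum <- array(rep(config$illuminant, each = h * w), dim = c(h, w, nb))

  withr::with_seed(config$seed, {
    noisy <- function(signal) {
      signal + config$dark_offset_mean +
        stats::rnorm(length(signal), sd = config$dark_offset_sd) +
        stats::rnorm(length(signal), sd = config$shot_noise_scale * abs(signal))
    }
    measured <- array(noisy(illum * r_true), dim = dim(r_true))
    white <- array(noisy(illum * 0.99), dim = dim(r_true))
    dark <- array(config$dark_offset_mean +
                    stats::rnorm(length(r_true), sd = config$dark_offset_sd),
                  dim = dim(r_true))
  })

  structure(list(
    measured = hyper_cube(measured, wl, kind = "raw"),
    white = hyper_cube(white, wl, kind = "raw"),
    dark = hyper_cube(dark, wl, kind = "raw"),
    truth = list(sao2_map = sao2_map, vein_mask = vein_mask,
                 artery_mask = artery_mask),
    config = config
  ), class = "raw_capture_set")
}

#' Simulate repeated pulse-oximeter readings
#'
#' Readings are `round(100 * true_sao2 + N(0, noise_sd))`, clipped to
#' \[70, 100\] — integer percent values with the repeat-to-repeat scatter a
#' fingertip oximeter shows.
#'
#' @param true_sao2 True arterial saturation fraction, in (0, 1\].
#' @param n Number of repeated readings (the study protocol used 5).
#' @param noise_sd Reading noise SD in %SpO2 before rounding.
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer vector of %SpO2 readings.
#' @examples
#' simulate_oximeter(0.97, n = 5, noise_sd = 0.8, seed = 1)
#' @export
simulate_oximeter <- function(true_sao2, n = 5, noise_sd = 0.8, seed = NULL) {
  if (n <= 0) stop("n must be >= 1", call. = FALSE)
  stopifnot(true_sao2 > 0, true_sao2 <= 1, noise_sd >= 0)
  draw <- function() {
    as.integer(pmin(100, pmax(70,
      round(100 * true_sao2 + stats::rnorm(n, sd = noise_sd)))))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}

#' Generate a synthetic subject cohort
#'
#' Each subject shares the base phantom geometry but has its own true
#' arterial saturation (evenly spaced across `sao2_range`), with the vein
#' saturation coupled as `max(0.4, SaO2 - vein_offset)`; each subject gets
#' its own RNG stream derived from `seed` and a set of repeated
#' pulse-oximeter readings.
#'
#' @param n_subjects Number of subjects, >= 2.
#' @param sao2_range Length-2 vector `c(lo, hi)` of true SaO2 fractions,
#'   `lo < hi`.
#' @param base_config A [phantom_config()] giving geometry, noise and bands.
#' @param seed Master RNG seed.
#' @param n_readings Readings per subject (default 5).
#' @param oximeter_noise_sd Reading noise SD in %SpO2.
#' @param vein_offset Arteriovenous saturation difference (fraction).
#' @return List of subjects; each element has `subject_id`, `true_sao2`,
#'   `capture` (a `raw_capture_set`), `readings` (integer %SpO2).
#' @seealso [cohort_readings()] for the readings as a tidy tibble.
#' @export
generate_cohort <- function(n_subjects, sao2_range = c(0.90, 0.99),
                            base_config = phantom_config(), seed = 1L,
                            n_readings = 5, oximeter_noise_sd = 0.8,
                            vein_offset = 0.25) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (sao2_range[1] >= sao2_range[2]) {
    stop("sao2_range must satisfy lo < hi", call. = FALSE)
  }
  sao2 <- seq(sao2_range[1], sao2_range[2], length.out = n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- base_config
    cfg$seed <- derive_seed(seed, i)
    cfg$vessels <- lapply(cfg$vessels, function(v) {
      v$saturation <- if (v$role == "artery") sao2[i] else
        max(0.4, sao2[i] - vein_offset)
      v
    })
    list(subject_id = sprintf("S%02d", i),
         true_sao2 = sao2[i],
         capture = render_phantom(cfg),
         readings = simulate_oximeter(sao2[i], n = n_readings,
                                      noise_sd = oximeter_noise_sd,
                                      seed = derive_seed(seed, i) + 1L))
  })
}

#' Cohort readings as a tidy tibble
#'
#' @param cohort Output of [generate_cohort()].
#' @return Tibble with columns `subject_id`, `reading_index`, `spo2`.
#' @export
cohort_readings <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    tibble::tibble(subject_id = s$subject_id,
                   reading_index = seq_along(s$readings),
                   spo2 = s$readings)
  })
}
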