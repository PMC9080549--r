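#' ROI mean spectral signature
#'
#' Per-band mean reflectance over the pixels in `roi_mask` that are valid in
#' the calibrated cube — the per-subject diffuse-reflectance signature.
#'
#' @param calibrated A reflectance [hyper_cube()] (from [calibrate_cube()]).
#' @param roi_mask Logical matrix selecting the region of interest; `NULL`
#'   uses the whole image.
#' @param subject_id Label carried into the output.
#' @return Tibble with columns `subject_id`, `wavelength_nm`,
#'   `reflectance_pct`, `n_pixels`.
#' @export
roi_signature <- function(calibrated, roi_mask = NULL, subject_id = "S01") {
  stopifnot(inherits(calibrated, "hyper_cube"))
  d <- dim(calibrated$values)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1], d[2])
  stopifnot(is.logical(roi_mask), all(dim(roi_mask) == d[1:2]))
  sel <- roi_mask
  if (!is.null(calibrated$valid_mask)) sel <- sel & calibrated$valid_mask
  n <- sum(sel)
  if (n < 1) stop("ROI does not overlap any valid pixel", call. = FALSE)
  flat <- matrix(calibrated$values, d[1] * d[2], d[3])
  refl <- colMeans(flat[as.vector(sel), , drop = FALSE], na.rm = TRUE)
  tibble::tibble(subject_id = subject_id,
                 wavelength_nm = calibrated$wavelengths,
                 reflectance_pct = refl,
                 n_pixels = n)
}

#' Centered moving average
#'
#' Moving mean of window size `k` along a vector. Interior windows cover
#' exactly `k` points (`floor((k-1)/2)` to the left, `ceiling((k-1)/2)` to
#' the right); near the ends the window shrinks to the symmetric
#' `+/- min(i-1, n-i)` form rather than inventing padding values.
#'
#' @param x Numeric vector.
#' @param k Window size, `1 <= k <= length(x)`.
#' @return Numeric vector of the same length.
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), k = 3)
#' @export
moving_average <- function(x, k = 10) {
  n <- length(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop(sprintf("window k = %d exceeds %d points", k, n), call. = FALSE)
  hl <- floor((k - 1) / 2)
  hh <- ceiling((k - 1) / 2)
  vapply(seq_len(n), function(i) {
    s <- min(i - 1L, n - i)
    if (s < max(hl, hh)) mean(x[(i - s):(i + s)])
    else mean(x[(i - hl):(i + hh)])
  }, numeric(1))
}

#' Smooth spectral signatures along the wavelength axis
#'
#' Applies [moving_average()] (the study protocol's K = 10 filter) to each
#' subject's reflectance signature.
#'
#' @param signatures Tibble as returned by [roi_signature()], possibly for
#'   several subjects.
#' @param k Moving-average window size in bands.
#' @return Tibble of the same shape with smoothed `reflectance_pct`.
#' @export
smooth_signature <- function(signatures, k = 10) {
  signatures |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$wavelength_nm, .by_group = TRUE) |>
    dplyr::mutate(reflectance_pct = moving_average(.data$reflectance_pct, k = k)) |>
    dplyr::ungroup()
}

#' Select the wavelength most correlated with SpO2
#'
#' For each candidate band inside `search_range`, computes the Pearson
#' correlation across subjects between ROI reflectance at that band and the
#' subjects' mean pulse-oximeter SpO2; the selected band maximizes the
#' absolute correlation. Bands within `tie_tol` of the maximal criterion are
#' treated as tied — with a handful of subjects the correlation saturates
#' into a flat plateau whose exact argmax is noise — and the tie is broken
#' by larger between-subject reflectance SD (the band of maximal
#' SpO2-driven variation), then by lower wavelength. Bands whose
#' reflectance is constant across subjects score 0 (their correlation is
#' undefined). The full criterion curve is returned for inspection.
#'
#' @param signatures Tibble with `subject_id`, `wavelength_nm`,
#'   `reflectance_pct` for >= 3 subjects sharing one wavelength grid
#'   (typically smoothed with [smooth_signature()]).
#' @param spo2 Tibble with `subject_id`, `spo2` (mean oximeter %SpO2 per
#'   subject), or a named numeric vector.
#' @param search_range Wavelength window (nm) to search; the default
#'   560-700 nm brackets the red band where the Hb/HbO2 absorption gap is
#'   widest.
#' @param tie_tol Absolute tolerance on the correlation criterion within
#'   which bands are considered tied (default 0.01).
#' @return An object of class `optimum_band`: list with `wavelength`,
#'   `criterion_value`, `curve` (tibble `wavelength_nm`, `criterion`,
#'   `between_subject_sd`) and `search_range`. Has [tidy()][generics::tidy]
#'   and `autoplot()` methods.
#' @export
select_optimum_band <- function(signatures, spo2, search_range = c(560, 700),
                                tie_tol = 0.01) {
  if (is.numeric(spo2) && !is.null(names(spo2))) {
    spo2 <- tibble::tibble(subject_id = names(spo2), spo2 = unname(spo2))
  }
  stopifnot(all(c("subject_id", "wavelength_nm", "reflectance_pct") %in%
                  names(signatures)),
            all(c("subject_id", "spo2") %in% names(spo2)))
  wide <- signatures |>
    dplyr::select("subject_id", "wavelength_nm", "reflectance_pct") |>
    tidyr::pivot_wider(names_from = "subject_id",
                       values_from = "reflectance_pct")
  subjects <- setdiff(names(wide), "wavelength_nm")
  if (length(subjects) < 3) stop("need >= 3 subjects", call. = FALSE)
  if (anyNA(wide)) {
    stop("signatures do not share a common wavelength grid", call. = FALSE)
  }
  spo2 <- spo2[match(subjects, spo2$subject_id), ]
  if (anyNA(spo2$spo2)) stop("missing SpO2 for some subjects", call. = FALSE)
  if (stats::sd(spo2$spo2) == 0) {
    stop("SpO2 values are all equal; correlation is undefined", call. = FALSE)
  }

  wl <- wide$wavelength_nm
  in_range <- wl >= search_range[1] & wl <= search_range[2]
  if (!any(in_range)) stop("no bands inside the search range", call. = FALSE)
  refl <- as.matrix(wide[subjects])
  sds <- apply(refl, 1, stats::sd)
  crit <- vapply(seq_along(wl), function(b) {
    if (sds[b] == 0) return(0)
    abs(stats::cor(refl[b, ], spo2$spo2))
  }, numeric(1))

  curve <- tibble::tibble(wavelength_nm = wl, criterion = crit,
                          between_subject_sd = sds)[in_range, ]
  best <- max(curve$criterion)
  ties <- which(curve$criterion >= best - tie_tol)
  if (length(ties) > 1) {
    ties <- ties[curve$between_subject_sd[ties] == max(curve$between_subject_sd[ties])]
  }
  pick <- ties[which.min(curve$wavelength_nm[ties])]

  structure(list(wavelength = curve$wavelength_nm[pick],
                 criterion_value = best,
                 curve = curve,
                 search_range = search_range),
            class = "optimum_band")
}

#' @export
print.optimum_band <- function(x, ...) {
  cat(sprintf(
    "<optimum_band> %.1f nm (|r| = %.4f over %d bands in [%.0f, %.0f] nm)\n",
    x$wavelength, x$criterion_value, nrow(x$curve),
    x$search_range[1], x$search_range[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy optimum_band
#' @export
tidy.optimum_band <- function(x, ...) x$curve

#' @method glance optimum_band
#' @export
glance.optimum_band <- function(x, ...) {
  tibble::tibble(wavelength_nm = x$wavelength,
                 criterion = x$criterion_value,
                 n_bands = nrow(x$curve),
                 range_lo_nm = x$search_range[1],
                 range_hi_nm = x$search_range[2])
}
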