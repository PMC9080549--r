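#' Repeated pulse-oximeter reading statistics
#'
#' Mean, sample standard deviation (n-1 denominator) and standard error
#' (SD / sqrt(n)) of one subject's repeated integer %SpO2 readings — the row
#' arithmetic of a repeated-reading protocol. Full-precision values are
#' returned alongside report-precision roundings (mean to 1 d.p., SD/SE to
#' 2 d.p.).
#'
#' @param readings Integer vector of %SpO2 readings, length >= 2.
#' @param subject_id Label carried into the output.
#' @return One-row tibble: `subject_id`, `n`, `mean`, `sd`, `se`,
#'   `mean_rounded`, `sd_rounded`, `se_rounded`.
#' @examples
#' reading_stats(c(97, 96, 97, 95, 97)) # mean 96.4, sd 0.89, se 0.40
#' @export
reading_stats <- function(readings, subject_id = "S01") {
  if (length(readings) < 2) stop("need >= 2 readings", call. = FALSE)
  m <- mean(readings)
  s <- stats::sd(readings)
  se <- s / sqrt(length(readings))
  tibble::tibble(subject_id = subject_id, n = length(readings),
                 mean = m, sd = s, se = se,
                 mean_rounded = round(m, 1), sd_rounded = round(s, 2),
                 se_rounded = round(se, 2))
}

#' Reading statistics for a whole cohort
#'
#' @param readings Tibble with `subject_id`, `spo2` (one row per reading),
#'   e.g. from [cohort_readings()].
#' @return One row per subject, as in [reading_stats()].
#' @export
cohort_reading_stats <- function(readings) {
  readings |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ reading_stats(.x$spo2, subject_id = .y$subject_id)[-1]) |>
    dplyr::ungroup()
}

#' Mean and SD of a masked image region
#'
#' @param img A [band_image()].
#' @param mask Logical matrix selecting the region.
#' @param region Label for the region (e.g. `"vein"`, `"artery"`, `"roi"`).
#' @param subject_id Label carried into the output.
#' @return One-row tibble: `subject_id`, `region`, `mean`, `sd`, `n_pixels`.
#' @export
region_stats <- function(img, mask, region = "roi", subject_id = "S01") {
  stopifnot(inherits(img, "band_image"), all(dim(mask) == dim(img$values)))
  sel <- mask
  if (!is.null(img$valid_mask)) sel <- sel & img$valid_mask
  v <- img$values[sel]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("mask selects no valid pixels", call. = FALSE)
  tibble::tibble(subject_id = subject_id, region = region,
                 mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                 n_pixels = length(v))
}

#' Fit the linear image-statistic to SpO2 calibration
#'
#' Ordinary least squares for `SpO2 = a * region_mean + b` across subjects,
#' with Pearson r and in-sample RMSE as diagnostics. This is the transfer
#' function mapping the vessel-region mean of the filtered band image to a
#' saturation percentage.
#'
#' @param data Tibble with columns `region_mean` and `spo2` (one row per
#'   subject, n >= 3).
#' @return An object of class `spo2_calibration`: `slope`, `intercept`,
#'   `r`, `rmse`, `n`, and the underlying `lm` fit. Has `tidy()` and
#'   `glance()` methods.
#' @export
fit_spo2_calibration <- function(data) {
  stopifnot(all(c("region_mean", "spo2") %in% names(data)))
  if (nrow(data) < 3) stop("need >= 3 subjects", call. = FALSE)
  if (stats::sd(data$region_mean) == 0) {
    stop("degenerate predictor: region means are all equal", call. = FALSE)
  }
  fit <- stats::lm(spo2 ~ region_mean, data = data)
  pred <- stats::fitted(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(data$region_mean, data$spo2),
    rmse = sqrt(mean((data$spo2 - pred)^2)),
    n = nrow(data),
    fit = fit
  ), class = "spo2_calibration")
}

#' @export
print.spo2_calibration <- function(x, ...) {
  cat(sprintf(
    "<spo2_calibration> SpO2 = %.4g * mean + %.4g  (r = %.3f, rmse = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r, x$rmse, x$n))
  invisible(x)
}

#' @method tidy spo2_calibration
#' @export
tidy.spo2_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance spo2_calibration
#' @export
glance.spo2_calibration <- function(x, ...) {
  tibble::tibble(r = x$r, rmse = x$rmse, n = x$n)
}

#' Apply a fitted SpO2 calibration
#'
#' @param calibration A [fit_spo2_calibration()] object.
#' @param region_mean Numeric vector of vessel-region image means.
#' @return Tibble with `region_mean`, `spo2_est` (clipped to \[50, 100\])
#'   and a `clipped` flag.
#' @export
estimate_spo2 <- function(calibration, region_mean) {
  stopifnot(inherits(calibration, "spo2_calibration"))
  raw <- calibration$slope * region_mean + calibration$intercept
  tibble::tibble(region_mean = region_mean,
                 spo2_est = pmin(100, pmax(50, raw)),
                 clipped = raw < 50 | raw > 100)
}

#' Agreement between estimated and reference SpO2
#'
#' Bias (mean of estimate minus reference), mean absolute error, RMSE and
#' Pearson correlation between paired SpO2 vectors. The correlation is NA
#' when either vector is constant.
#'
#' @param estimates,reference Paired numeric vectors of %SpO2, length >= 2.
#' @return One-row tibble: `n`, `bias`, `mae`, `rmse`, `r`.
#' @export
agreement_report <- function(estimates, reference) {
  if (length(estimates) != length(reference)) {
    stop("estimates and reference must have equal length", call. = FALSE)
  }
  if (length(estimates) < 2) stop("need >= 2 pairs", call. = FALSE)
  diff <- estimates - reference
  r <- if (stats::sd(estimates) == 0 || stats::sd(reference) == 0) NA_real_
       else stats::cor(estimates, reference)
  tibble::tibble(n = length(estimates), bias = mean(diff),
                 mae = mean(abs(diff)), rmse = sqrt(mean(diff^2)), r = r)
}

#' Leave-one-out SpO2 estimates over a cohort
#'
#' For each subject, refits the linear calibration on all other subjects
#' and predicts the held-out subject's SpO2 from its region mean — the
#' standard check that the image-to-SpO2 map generalizes beyond the
#' subjects it was fitted on.
#'
#' @param data Tibble with `subject_id`, `region_mean`, `spo2` (one row per
#'   subject, n >= 4).
#' @return `data` with an added `spo2_loo` column.
#' @export
loo_spo2_estimates <- function(data) {
  stopifnot(all(c("subject_id", "region_mean", "spo2") %in% names(data)))
  if (nrow(data) < 4) stop("need >= 4 subjects for leave-one-out", call. = FALSE)
  data$spo2_loo <- vapply(seq_len(nrow(data)), function(i) {
    fit <- fit_spo2_calibration(data[-i, ])
    estimate_spo2(fit, data$region_mean[i])$spo2_est
  }, numeric(1))
  data
}

#' Printed pulse-oximeter readings from the source study
#'
#' The repeated integer %SpO2 readings printed for the two volunteer groups
#' (group 1: visible-band analysis, eight subjects; group 2: 610 nm
#' analysis, seven subjects), five readings per subject, as shipped in
#' `inst/extdata/pulse_oximeter_readings.csv`.
#'
#' @return Tibble with columns `group`, `patient`, `reading_index`, `spo2`.
#' @export
oximeter_readings <- function() {
  path <- system.file("extdata", "pulse_oximeter_readings.csv",
                      package = "hsoximetry", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
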