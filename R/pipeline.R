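#' Default pipeline configuration
#'
#' Assembles every tunable of the end-to-end pipeline in one nested list:
#' cohort generation (subjects, SaO2 range, oximeter readings), phantom
#' rendering (image and band-grid geometry, noise), and analysis (signature
#' smoothing window, band search range, FFT mask, K-means, vessel shape
#' gates). Values follow the study protocol where one is stated (five
#' readings per subject, smoothing window 10, K-means K = 10).
#'
#' @param seed Master seed; every random stage derives its stream from it.
#' @return An object of class `pipeline_config` (a named list), serializable
#'   with [write_pipeline_config()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    version = 1L,
    seed = as.integer(seed),
    cohort = list(n_subjects = 8L, sao2_lo = 0.90, sao2_hi = 0.99,
                  n_readings = 5L, oximeter_noise_sd = 0.8,
                  vein_offset = 0.25),
    phantom = list(height = 128L, width = 128L, n_bands = 64L,
                   band_lo = 400, band_hi = 900,
                   dark_offset_mean = 100, dark_offset_sd = 2,
                   shot_noise_scale = 0.01),
    analysis = list(smoothing_k = 10L, search_lo = 560, search_hi = 700,
                    remove_dc = TRUE, lowpass_frac = 0.25,
                    profile = "gaussian",
                    kmeans_k = 10L, kmeans_n_init = 10L,
                    min_frac = 0.002, max_frac = 0.2, min_elongation = 2.0)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_pipeline_config())
  for (top in names(base)) {
    if (is.list(base[[top]])) {
      for (key in names(cfg[[top]])) base[[top]][[key]] <- cfg[[top]][[key]]
    } else if (!is.null(cfg[[top]])) {
      base[[top]] <- cfg[[top]]
    }
  }
  structure(base, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_phantom <- function(config) {
  p <- config$phantom
  phantom_config(height = p$height, width = p$width,
                 band_grid = seq(p$band_lo, p$band_hi, length.out = p$n_bands),
                 dark_offset_mean = p$dark_offset_mean,
                 dark_offset_sd = p$dark_offset_sd,
                 shot_noise_scale = p$shot_noise_scale,
                 seed = config$seed)
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort described by `config` and writes, under
#' `out_dir`: per-subject ENVI cube triplets (measured/white/dark), truth
#' masks as PNG, the readings CSV, the truth table, and a JSON manifest
#' recording all parameters and seeds.
#'
#' @param config A [default_pipeline_config()]-shaped configuration.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
run_simulate <- function(config = default_pipeline_config(), out_dir) {
  if (config$cohort$n_subjects < 2) {
    stop("cohort.n_subjects must be >= 2", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(
    n_subjects = config$cohort$n_subjects,
    sao2_range = c(config$cohort$sao2_lo, config$cohort$sao2_hi),
    base_config = config_phantom(config),
    seed = config$seed,
    n_readings = config$cohort$n_readings,
    oximeter_noise_sd = config$cohort$oximeter_noise_sd,
    vein_offset = config$cohort$vein_offset)

  for (s in cohort) {
    sdir <- file.path(out_dir, "subjects", s$subject_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write_envi(s$capture$measured, file.path(sdir, "measured"))
    write_envi(s$capture$white, file.path(sdir, "white"))
    write_envi(s$capture$dark, file.path(sdir, "dark"))
    png::writePNG(s$capture$truth$vein_mask * 1, file.path(sdir, "vein_truth.png"))
    png::writePNG(s$capture$truth$artery_mask * 1, file.path(sdir, "artery_truth.png"))
  }
  utils::write.csv(cohort_readings(cohort),
                   file.path(out_dir, "readings.csv"), row.names = FALSE)
  utils::write.csv(
    tibble::tibble(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                   true_sao2 = vapply(cohort, `[[`, 0, "true_sao2")),
    file.path(out_dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load a simulated cohort from disk
#'
#' @param dir Directory written by [run_simulate()].
#' @return Cohort list in the [generate_cohort()] shape (truth SaO2 maps are
#'   not round-tripped; the masks and readings are).
#' @export
load_cohort <- function(dir) {
  readings <- utils::read.csv(file.path(dir, "readings.csv"))
  subjects <- sort(list.dirs(file.path(dir, "subjects"), recursive = FALSE))
  truth_tbl <- if (file.exists(file.path(dir, "truth.csv")))
    utils::read.csv(file.path(dir, "truth.csv")) else NULL
  lapply(subjects, function(sdir) {
    id <- basename(sdir)
    for (f in c("measured", "white", "dark")) {
      if (!file.exists(file.path(sdir, paste0(f, ".hdr")))) {
        stop(sprintf("subject %s: missing %s cube (%s)", id, f,
                     file.path(sdir, paste0(f, ".hdr"))), call. = FALSE)
      }
    }
    capture <- structure(list(
      measured = read_envi(file.path(sdir, "measured.hdr")),
      white = read_envi(file.path(sdir, "white.hdr")),
      dark = read_envi(file.path(sdir, "dark.hdr")),
      truth = list(
        vein_mask = png::readPNG(file.path(sdir, "vein_truth.png")) > 0.5,
        artery_mask = png::readPNG(file.path(sdir, "artery_truth.png")) > 0.5)
    ), class = "raw_capture_set")
    list(subject_id = id,
         true_sao2 = if (!is.null(truth_tbl))
           truth_tbl$true_sao2[match(id, truth_tbl$subject_id)] else NA_real_,
         capture = capture,
         readings = readings$spo2[readings$subject_id == id])
  })
}

#' Analyze a cohort in memory
#'
#' Runs the full analysis chain: Eq.-(1)-style white/dark calibration, ROI
#' spectral signatures, moving-average smoothing, selection of the
#' SpO2-correlated optimum band, per-subject normalization and FFT
#' denoising of that band image, K-means vessel segmentation, vessel-region
#' statistics, the linear region-mean-to-SpO2 calibration, and the
#' agreement report against the oximeter means. Subjects whose segmentation
#' fails are skipped with a warning rather than aborting the cohort.
#'
#' @param cohort Cohort list from [generate_cohort()] or [load_cohort()].
#' @param config Pipeline configuration (analysis parameters are read from
#'   `config$analysis`).
#' @return List of class `cohort_analysis`: `signatures`, `band`
#'   (`optimum_band`), per-subject `subjects` (filtered image, masks,
#'   composite), `region_stats`, `oximeter`, `calibration`, `estimates`,
#'   `agreement`, `failed` (subject ids skipped).
#' @export
analyze_cohort <- function(cohort, config = default_pipeline_config()) {
  a <- config$analysis
  calibrated <- lapply(cohort, function(s) {
    calibrate_cube(s$capture$measured, s$capture$white, s$capture$dark)
  })
  signatures <- purrr::map2_dfr(calibrated, cohort, function(cal, s) {
    roi_signature(cal, subject_id = s$subject_id)
  })
  smoothed <- smooth_signature(signatures, k = a$smoothing_k)
  oximeter <- cohort_reading_stats(cohort_readings(cohort))
  band <- select_optimum_band(
    smoothed,
    tibble::tibble(subject_id = oximeter$subject_id, spo2 = oximeter$mean),
    search_range = c(a$search_lo, a$search_hi))

  failed <- character(0)
  subjects <- list()
  region_rows <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    res <- tryCatch({
      img <- extract_band(calibrated[[i]], band$wavelength)
      norm <- normalize_image(img)
      filt <- fft_denoise(norm, remove_dc = a$remove_dc,
                          lowpass_frac = a$lowpass_frac, profile = a$profile)
      # cluster the normalized image (crisp vessel levels); the FFT-filtered
      # image is what region statistics are computed on
      model <- suppressWarnings(
        kmeans_lloyd(as.vector(norm$values), k = a$kmeans_k,
                     seed = derive_seed(config$seed, 1000L + i),
                     n_init = a$kmeans_n_init))
      masks <- label_vessels(model, norm, min_frac = a$min_frac,
                             max_frac = a$max_frac,
                             min_elongation = a$min_elongation)
      vessel_union <- masks$vein_mask | masks$artery_mask
      stats <- dplyr::bind_rows(
        region_stats(filt, masks$vein_mask, "vein", s$subject_id),
        if (any(masks$artery_mask))
          region_stats(filt, masks$artery_mask, "artery", s$subject_id),
        region_stats(filt, vessel_union, "vessel", s$subject_id))
      list(subject_id = s$subject_id, normalized = norm, filtered = filt,
           masks = masks, model = model, stats = stats)
    }, error = function(e) {
      warning(sprintf("subject %s skipped: %s", s$subject_id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- c(failed, s$subject_id)
    else {
      subjects[[s$subject_id]] <- res
      region_rows[[s$subject_id]] <- res$stats
    }
  }
  region <- dplyr::bind_rows(region_rows)

  # calibrate on the artery region: the pulse oximeter measures *arterial*
  # saturation, and min-max normalization pins the image minimum (the vein
  # core) so the vein mean carries little saturation signal
  cal_data <- region |>
    dplyr::filter(.data$region == "artery") |>
    dplyr::select("subject_id", region_mean = "mean") |>
    dplyr::inner_join(dplyr::select(oximeter, "subject_id", spo2 = "mean"),
                      by = "subject_id")
  calibration <- fit_spo2_calibration(cal_data)
  estimates <- dplyr::bind_cols(
    cal_data["subject_id"],
    estimate_spo2(calibration, cal_data$region_mean),
    spo2_oximeter = cal_data$spo2)
  agreement <- agreement_report(estimates$spo2_est, estimates$spo2_oximeter)

  structure(list(signatures = smoothed, band = band, subjects = subjects,
                 region_stats = region, oximeter = oximeter,
                 calibration = calibration, estimates = estimates,
                 agreement = agreement, failed = failed,
                 config = config),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects (%d skipped), band %.1f nm\n",
              length(x$subjects), length(x$failed), x$band$wavelength))
  cat(sprintf("  calibration r = %.3f, agreement rmse = %.3f %%SpO2\n",
              x$calibration$r, x$agreement$rmse))
  invisible(x)
}

#' Run the analysis stage against a simulated cohort on disk
#'
#' Loads the cohort from `dir`, runs [analyze_cohort()], and writes
#' signatures, criterion curve, region statistics, estimates, agreement and
#' per-subject masks/overlays under `dir/analysis`, plus a manifest with the
#' parameters and seeds used.
#'
#' @param config Pipeline configuration.
#' @param dir Directory holding a [run_simulate()] cohort.
#' @return Invisibly, the `cohort_analysis` object.
#' @export
run_analyze <- function(config = default_pipeline_config(), dir) {
  cohort <- load_cohort(dir)
  res <- analyze_cohort(cohort, config)
  adir <- file.path(dir, "analysis")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$signatures, file.path(adir, "signatures.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(res$band), file.path(adir, "band_criterion.csv"),
                   row.names = FALSE)
  utils::write.csv(res$region_stats, file.path(adir, "region_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(res$estimates, file.path(adir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(res$agreement, file.path(adir, "agreement.csv"),
                   row.names = FALSE)
  for (id in names(res$subjects)) {
    s <- res$subjects[[id]]
    sdir <- file.path(adir, "subjects", id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(s$masks$vein_mask * 1, file.path(sdir, "vein_mask.png"))
    png::writePNG(s$masks$artery_mask * 1, file.path(sdir, "artery_mask.png"))
    cube <- read_envi(file.path(dir, "subjects", id, "measured.hdr"))
    comp <- visible_composite(cube)
    over <- overlay_mask(comp, s$masks$vein_mask, c(0, 0, 1), 0.5)
    over <- overlay_mask(over, s$masks$artery_mask, c(1, 0, 0), 0.5)
    png::writePNG(over, file.path(sdir, "overlay.png"))
    utils::write.csv(s$masks$diagnostics,
                     file.path(sdir, "cluster_diagnostics.csv"),
                     row.names = FALSE)
  }
  manifest <- list(selected_wavelength_nm = res$band$wavelength,
                   failed_subjects = res$failed,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(adir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Emit report tables for an analyzed cohort
#'
#' Builds the per-subject summary table (five readings, their mean / SD /
#' SE at report precision, and the vessel-region image mean / SD) and the
#' agreement summary, as CSV under `dir/report`.
#'
#' @param config Pipeline configuration.
#' @param dir Directory holding simulate + analyze outputs.
#' @return Invisibly, the summary tibble.
#' @export
run_report <- function(config = default_pipeline_config(), dir) {
  adir <- file.path(dir, "analysis")
  if (!file.exists(file.path(adir, "region_stats.csv"))) {
    stop("no analysis outputs under ", adir, "; run run_analyze() first",
         call. = FALSE)
  }
  readings <- tibble::as_tibble(utils::read.csv(file.path(dir, "readings.csv")))
  region <- tibble::as_tibble(utils::read.csv(file.path(adir, "region_stats.csv")))
  stats <- cohort_reading_stats(readings)
  wide_readings <- readings |>
    dplyr::mutate(reading = paste0("R", .data$reading_index)) |>
    dplyr::select("subject_id", "reading", "spo2") |>
    tidyr::pivot_wider(names_from = "reading", values_from = "spo2")
  img <- region |>
    dplyr::filter(.data$region == "vessel") |>
    dplyr::select("subject_id", image_mean = "mean", image_sd = "sd")
  summary <- wide_readings |>
    dplyr::inner_join(
      dplyr::select(stats, "subject_id", mean = "mean_rounded",
                    sd = "sd_rounded", se = "se_rounded"),
      by = "subject_id") |>
    dplyr::left_join(img, by = "subject_id")
  rdir <- file.path(dir, "report")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary, file.path(rdir, "subject_summary.csv"),
                   row.names = FALSE)
  file.copy(file.path(adir, "agreement.csv"),
            file.path(rdir, "agreement.csv"), overwrite = TRUE)
  invisible(summary)
}
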