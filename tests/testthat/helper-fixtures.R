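# Small in-code fixtures shared across the suite.

# a tiny deterministic cube with distinct values per voxel
make_cube <- function(rows = 4, cols = 5, bands = 3,
                      wavelengths = seq(500, 700, length.out = bands),
                      kind = "raw") {
  vals <- array(seq_len(rows * cols * bands), dim = c(rows, cols, bands))
  hyper_cube(vals, wavelengths, kind = kind)
}

# desk-scale phantom configuration for unit tests
small_phantom <- function(noise = TRUE, seed = 1L, ...) {
  phantom_config(height = 48, width = 48,
                 band_grid = seq(400, 900, length.out = 24),
                 dark_offset_sd = if (noise) 2 else 0,
                 shot_noise_scale = if (noise) 0.01 else 0,
                 seed = seed, ...)
}

# exhaustive 2-partition oracle for scalar k-means inertia
exhaustive_two_means <- function(x) {
  n <- length(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {   # non-empty proper subsets, up to symmetry
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    a <- x[grp]; b <- x[!grp]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best) best <- sse
  }
  best
}

# printed five-reading rows of the two study tables with their printed stats
study_table_rows <- function() {
  r <- oximeter_readings()
  stats <- cohort_reading_stats(
    tibble::tibble(subject_id = paste0("T", r$group, "_", r$patient),
                   spo2 = r$spo2))
  printed <- tibble::tribble(
    ~subject_id, ~p_mean, ~p_sd, ~p_se,
    "T1_P1", 96.4, 0.89, 0.40,
    "T1_P2", 95.6, 0.55, 0.24,
    "T1_P3", 98.6, 0.55, 0.24,
    "T1_P4", 90.6, 0.89, 0.40,
    "T1_P5", 96.6, 0.55, 0.24,
    "T1_P6", 96.4, 0.89, 0.40,
    "T1_P7", 90.4, 0.55, 0.24,
    "T1_P8", 96.4, 0.89, 0.40,
    "T2_P1", 96.6, 0.55, 0.24,
    "T2_P2", 95.8, 0.45, 0.20,
    "T2_P3", 98.6, 0.55, 0.24,
    "T2_P4", 90.6, 0.89, 0.40,
    "T2_P5", 96.6, 0.55, 0.24,
    "T2_P6", 96.8, 0.45, 0.20,
    "T2_P7", 90.4, 0.55, 0.24)
  dplyr::inner_join(stats, printed, by = "subject_id")
}
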