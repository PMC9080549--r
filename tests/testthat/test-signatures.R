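test_that("ROI signatures equal hand-computed per-band means", {
  cube <- make_cube(4, 4, 3, kind = "reflectance")
  mask <- matrix(FALSE, 4, 4); mask[1:3, 1:3] <- TRUE
  sig <- roi_signature(cube, mask, subject_id = "X")
  manual <- vapply(1:3, function(b) {
    acc <- 0
    for (r in 1:3) for (c in 1:3) acc <- acc + cube$values[r, c, b]
    acc / 9
  }, numeric(1))
  expect_equal(sig$reflectance_pct, manual)
  expect_equal(unique(sig$n_pixels), 9L)

  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  sig1 <- roi_signature(cube, one)
  expect_equal(sig1$reflectance_pct, cube$values[2, 3, ])

  const <- hyper_cube(array(42, c(2, 2, 3)), c(500, 600, 700), "reflectance")
  expect_equal(roi_signature(const)$reflectance_pct, rep(42, 3))
  expect_error(roi_signature(cube, matrix(FALSE, 4, 4)), "valid pixel")
})

test_that("moving average spreads an impulse and preserves constants and ramps", {
  expect_equal(moving_average(rep(3, 20), 10), rep(3, 20))

  x <- rep(0, 40); x[20] <- 1
  y <- moving_average(x, 10)
  inw <- which(y > 0)
  expect_length(inw, 10)
  expect_equal(y[inw], rep(1 / 10, 10))
  expect_equal(sum(y[inw]), 1)

  ramp <- seq(2, 40, by = 2)
  sm <- moving_average(ramp, 5)          # odd window: interior fixed points
  expect_equal(sm[3:18], ramp[3:18])

  expect_error(moving_average(1:5, 6), "exceeds")
  # affine commutation
  withr::with_seed(3, z <- runif(30))
  expect_equal(moving_average(2 * z + 5, 7), 2 * moving_average(z, 7) + 5)
})

test_that("a constructed perfect correlate band is always selected", {
  wl <- seq(560, 700, by = 10)
  spo2 <- tibble::tibble(subject_id = paste0("S", 1:5),
                         spo2 = c(90, 92, 94, 96, 98))
  sigs <- purrr::map_dfr(1:5, function(i) {
    refl <- rep(40, length(wl))
    refl[wl == 610] <- 0.5 * spo2$spo2[i] + 3
    tibble::tibble(subject_id = paste0("S", i), wavelength_nm = wl,
                   reflectance_pct = refl)
  })
  res <- select_optimum_band(sigs, spo2)
  expect_equal(res$wavelength, 610)
  expect_equal(res$criterion_value, 1.0)

  single <- select_optimum_band(sigs, spo2, search_range = c(655, 665))
  expect_equal(single$wavelength, 660)
})

test_that("band selection errors on degenerate inputs", {
  wl <- c(600, 610)
  sigs <- purrr::map_dfr(1:3, function(i)
    tibble::tibble(subject_id = paste0("S", i), wavelength_nm = wl,
                   reflectance_pct = c(i, 2 * i)))
  flat <- tibble::tibble(subject_id = paste0("S", 1:3), spo2 = c(95, 95, 95))
  expect_error(select_optimum_band(sigs, flat), "all equal")
  two <- sigs[sigs$subject_id != "S3", ]
  expect_error(select_optimum_band(two, flat), ">= 3 subjects")
  shifted <- sigs
  shifted$wavelength_nm[shifted$subject_id == "S3"] <- c(600, 611)
  expect_error(
    select_optimum_band(shifted,
                        tibble::tibble(subject_id = paste0("S", 1:3),
                                       spo2 = c(90, 95, 99))),
    "common wavelength")
})

test_that("selection is invariant to shared per-band reflectance offsets", {
  wl <- seq(560, 700, by = 5)
  withr::with_seed(14, {
    spo2 <- tibble::tibble(subject_id = paste0("S", 1:6),
                           spo2 = c(88, 90, 92, 94, 96, 98))
    slope <- 0.2 * exp(-(wl - 620)^2 / 800)
    sigs <- purrr::map_dfr(1:6, function(i)
      tibble::tibble(subject_id = paste0("S", i), wavelength_nm = wl,
                     reflectance_pct = 40 + slope * spo2$spo2[i] +
                       rnorm(length(wl), sd = 0.01)))
    offsets <- runif(length(wl), -5, 5)
  })
  base <- select_optimum_band(sigs, spo2)
  shifted <- sigs |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(reflectance_pct = reflectance_pct + offsets) |>
    dplyr::ungroup()
  res <- select_optimum_band(shifted, spo2)
  expect_equal(res$wavelength, base$wavelength)
  expect_equal(res$curve$criterion, base$curve$criterion, tolerance = 1e-9)
})

test_that("tidy and glance summarize an optimum_band fit", {
  wl <- seq(560, 700, by = 10)
  sigs <- purrr::map_dfr(1:4, function(i)
    tibble::tibble(subject_id = paste0("S", i), wavelength_nm = wl,
                   reflectance_pct = wl * 0.01 * i))
  spo2 <- tibble::tibble(subject_id = paste0("S", 1:4),
                         spo2 = c(90, 93, 95, 98))
  res <- select_optimum_band(sigs, spo2)
  expect_named(tidy(res), c("wavelength_nm", "criterion", "between_subject_sd"))
  expect_equal(glance(res)$criterion, res$criterion_value)
})
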