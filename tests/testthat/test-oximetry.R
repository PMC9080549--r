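test_that("every printed study table row is reproduced at table precision", {
  rows <- study_table_rows()
  expect_equal(nrow(rows), 15)
  expect_equal(rows$mean_rounded, rows$p_mean)
  expect_equal(rows$sd_rounded, rows$p_sd)
  expect_equal(rows$se_rounded, rows$p_se)
})

test_that("reading statistics use the sample SD and SE = SD / sqrt(n)", {
  st <- reading_stats(c(97, 96, 97, 95, 97))
  expect_equal(st$mean, 96.4)
  expect_equal(st$sd, sd(c(97, 96, 97, 95, 97)))
  expect_equal(st$se, st$sd / sqrt(5))
  expect_equal(st$sd_rounded, 0.89)
  expect_equal(st$se_rounded, 0.40)

  allsame <- reading_stats(c(96, 96, 96))
  expect_equal(allsame$sd, 0)
  expect_equal(allsame$se, 0)
  expect_error(reading_stats(97), ">= 2")
})

test_that("region statistics match hand arithmetic and a brute-force loop", {
  img <- band_image(matrix(0.5, 4, 4), 610, kind = "filtered")
  st <- region_stats(img, matrix(TRUE, 4, 4))
  expect_equal(st$mean, 0.5)
  expect_equal(st$sd, 0)

  two <- band_image(matrix(c(0.4, 0.6, 9, 9), 2, 2), 610, kind = "filtered")
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  st2 <- region_stats(two, mask)
  expect_equal(st2$mean, 0.5)
  expect_equal(st2$sd, sqrt(0.02), tolerance = 1e-9)  # ~0.1414
  expect_equal(st2$n_pixels, 2L)

  withr::with_seed(19, v <- matrix(runif(25), 5, 5))
  m <- matrix(v > 0.3, 5, 5)
  st3 <- region_stats(band_image(v, 610, kind = "filtered"), m)
  sel <- c()
  for (r in 1:5) for (c in 1:5) if (m[r, c]) sel <- c(sel, v[r, c])
  expect_equal(st3$mean, mean(sel))
  expect_equal(st3$sd, sd(sel))
  expect_error(region_stats(band_image(v, 610, kind = "filtered"),
                            matrix(FALSE, 5, 5)), "no valid")
})

test_that("exact linear data is fitted exactly and degenerate data rejected", {
  means <- c(0.2, 0.4, 0.6, 0.8)
  data <- tibble::tibble(region_mean = means, spo2 = 2 * means + 90)
  fit <- fit_spo2_calibration(data)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 90)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  expect_equal(fit$r, 1)
  expect_equal(tidy(fit)$estimate, c(90, 2))
  expect_equal(glance(fit)$n, 4)

  same <- tibble::tibble(region_mean = rep(0.5, 3), spo2 = c(90, 95, 99))
  expect_error(fit_spo2_calibration(same), "degenerate")
  expect_error(fit_spo2_calibration(data[1:2, ]), ">= 3")
})

test_that("estimate_spo2 applies the line, clips, and closes the OLS loop", {
  fit <- fit_spo2_calibration(
    tibble::tibble(region_mean = c(0.2, 0.5, 0.8), spo2 = c(88, 94, 99)))
  ident <- structure(list(slope = 1, intercept = 0, r = 1, rmse = 0, n = 3),
                     class = "spo2_calibration")
  expect_equal(estimate_spo2(ident, c(75, 93))$spo2_est, c(75, 93))
  expect_true(estimate_spo2(ident, 150)$clipped)
  expect_equal(estimate_spo2(ident, 150)$spo2_est, 100)
  # training-point round trip equals the fitted value
  expect_equal(estimate_spo2(fit, 0.5)$spo2_est,
               unname(fitted(fit$fit)[2]))
})

test_that("agreement metrics follow their definitions", {
  same <- agreement_report(c(95, 96, 97), c(95, 96, 97))
  expect_equal(same$bias, 0)
  expect_equal(same$rmse, 0)
  offset <- agreement_report(c(96, 97, 98), c(95, 96, 97))
  expect_equal(offset$bias, 1)
  expect_equal(offset$rmse, 1)
  expect_equal(offset$mae, 1)

  flat <- agreement_report(c(95, 95), c(94, 96))
  expect_true(is.na(flat$r))

  withr::with_seed(23, { a <- runif(10, 90, 99); b <- runif(10, 90, 99) })
  rep <- agreement_report(a, b)
  expect_equal(rep$bias, mean(a - b))
  expect_equal(rep$mae, mean(abs(a - b)))
  expect_equal(rep$rmse, sqrt(mean((a - b)^2)))
  expect_equal(rep$r, cor(a, b))
  expect_error(agreement_report(a, b[1:5]), "equal length")
})

test_that("leave-one-out estimates refit without the held-out subject", {
  data <- tibble::tibble(subject_id = paste0("S", 1:5),
                         region_mean = c(0.2, 0.35, 0.5, 0.65, 0.8),
                         spo2 = c(88, 91, 94, 96.5, 99))
  loo <- loo_spo2_estimates(data)
  fit1 <- fit_spo2_calibration(data[-1, ])
  expect_equal(loo$spo2_loo[1], estimate_spo2(fit1, data$region_mean[1])$spo2_est)
  expect_error(loo_spo2_estimates(data[1:3, ]), ">= 4")
})
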