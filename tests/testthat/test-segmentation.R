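test_that("k-means closed forms: k = 1 and k = number of distinct values", {
  x <- c(0, 0.1, 0.2, 5, 5.1, 5.2)
  one <- kmeans_lloyd(x, k = 1, seed = 1)
  expect_equal(as.vector(one$centroids), mean(x))
  expect_equal(one$inertia, sum((x - mean(x))^2))

  full <- suppressWarnings(kmeans_lloyd(x, k = 10, seed = 1))
  expect_equal(full$k, 6)              # reduced to distinct values
  expect_equal(full$inertia, 0)
  expect_setequal(as.vector(full$centroids), x)
})

test_that("best-of-restarts matches the exhaustive 2-partition optimum", {
  x <- c(0, 0.1, 0.2, 5, 5.1, 5.2)
  fit <- kmeans_lloyd(x, k = 2, seed = 3, n_init = 10)
  expect_equal(fit$inertia, exhaustive_two_means(x))

  hits <- 0
  withr::with_seed(17, seeds_and_data <- lapply(1:100, function(i)
    list(seed = sample.int(1e6, 1), x = runif(sample(4:8, 1), 0, 10))))
  for (case in seeds_and_data) {
    fit <- kmeans_lloyd(case$x, k = 2, seed = case$seed, n_init = 20)
    opt <- exhaustive_two_means(case$x)
    expect_gte(fit$inertia, opt - 1e-9)   # never below the true optimum
    if (fit$inertia <= opt + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("Lloyd inertia is non-increasing within a run and reproducible", {
  withr::with_seed(9, x <- c(rnorm(200), rnorm(200, 4), rnorm(100, 9)))
  fit <- kmeans_lloyd(x, k = 5, seed = 21, n_init = 3)
  expect_true(all(diff(fit$inertia_trace) <= 1e-9))
  again <- kmeans_lloyd(x, k = 5, seed = 21, n_init = 3)
  expect_identical(fit$labels, again$labels)
  expect_identical(fit$centroids, again$centroids)
  # every point is assigned to its nearest centroid; inertia recomputes
  d2 <- outer(x, as.vector(fit$centroids), function(a, b) (a - b)^2)
  expect_equal(fit$labels, max.col(-d2, ties.method = "first"))
  expect_equal(fit$inertia, sum(d2[cbind(seq_along(x), fit$labels)]),
               tolerance = 1e-9)
})

test_that("k-means agrees with stats::kmeans on well-separated data", {
  withr::with_seed(30, x <- c(rnorm(100, 0, 0.1), rnorm(100, 5, 0.1)))
  ours <- kmeans_lloyd(x, k = 2, seed = 2, n_init = 10)
  ref <- stats::kmeans(x, centers = 2, nstart = 10, algorithm = "Lloyd")
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
})

test_that("vein and artery clusters are recovered from a clean phantom", {
  cfg <- small_phantom(noise = FALSE, seed = 5)
  cap <- render_phantom(cfg)
  cal <- calibrate_cube(cap$measured, cap$white, cap$dark)
  norm <- normalize_image(extract_band(cal, 610))
  model <- suppressWarnings(kmeans_lloyd(as.vector(norm$values), k = 10, seed = 42))
  masks <- label_vessels(model, norm)
  expect_gte(dice_coefficient(masks$vein_mask, cap$truth$vein_mask), 0.7)
  expect_gte(dice_coefficient(masks$artery_mask, cap$truth$artery_mask), 0.7)
  expect_false(any(masks$vein_mask & masks$artery_mask))
  expect_named(masks$diagnostics,
               c("cluster", "mean_intensity", "pixel_fraction", "elongation",
                 "candidate"))
})

test_that("single-vessel and background-only images degrade as specified", {
  cfg <- small_phantom(noise = FALSE, seed = 6, vessels = list(
    vessel_spec(cbind(row = rep(24, 5), col = seq(8, 40, length.out = 5)),
                radius = 4, saturation = 0.7, role = "vein")))
  cap <- render_phantom(cfg)
  cal <- calibrate_cube(cap$measured, cap$white, cap$dark)
  norm <- normalize_image(extract_band(cal, 610))
  model <- suppressWarnings(kmeans_lloyd(as.vector(norm$values), k = 10, seed = 1))
  expect_warning(masks <- label_vessels(model, norm), "artery mask left empty")
  expect_true(any(masks$vein_mask))
  expect_false(any(masks$artery_mask))

  # radial gradient: every intensity slice is an annulus, elongation ~ 1
  ctr <- outer((1:48 - 24.5)^2, (1:48 - 24.5)^2, "+")
  radial <- band_image(sqrt(ctr) / max(sqrt(ctr)), 610)
  m2 <- suppressWarnings(kmeans_lloyd(as.vector(radial$values), k = 10, seed = 1))
  expect_error(label_vessels(m2, radial), "shape test")
})

test_that("overlay blends exactly at the alpha endpoints and midpoint", {
  withr::with_seed(13, comp <- array(runif(4 * 4 * 3), dim = c(4, 4, 3)))
  mask <- matrix(FALSE, 4, 4); mask[2, 2:3] <- TRUE
  expect_identical(overlay_mask(comp, mask, c(1, 0, 0), 0), comp)

  full <- overlay_mask(comp, mask, c(0.2, 0.4, 0.6), 1)
  for (ch in 1:3) expect_true(all(full[, , ch][mask] == c(0.2, 0.4, 0.6)[ch]))

  half <- overlay_mask(comp, mask, c(1, 0, 0), 0.5)
  for (ch in 1:3) {
    expect_equal(half[, , ch][mask],
                 0.5 * comp[, , ch][mask] + 0.5 * c(1, 0, 0)[ch])
    expect_equal(half[, , ch][!mask], comp[, , ch][!mask])
  }
  expect_error(overlay_mask(comp, matrix(TRUE, 3, 3), c(1, 0, 0), 0.5))
})
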