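test_that("ENVI write/read round trip is lossless", {
  cube <- make_cube(5, 4, 6, kind = "reflectance")
  cube$values <- cube$values + 0.123456789
  path <- file.path(withr::local_tempdir(), "cube")
  write_envi(cube, path)
  back <- read_envi(paste0(path, ".hdr"))
  expect_identical(back$values, cube$values)
  expect_identical(back$wavelengths, cube$wavelengths)
  expect_identical(back$kind, "reflectance")
})

test_that("BSQ and BIL encodings of one cube read identically", {
  cube <- make_cube(3, 4, 5)
  dir <- withr::local_tempdir()
  write_envi(cube, file.path(dir, "bsq"))
  # hand-build the BIL twin: line-major, band, then sample fastest
  bil_vec <- as.vector(aperm(cube$values, c(2, 3, 1)))
  writeBin(bil_vec, file.path(dir, "bil"), size = 8, endian = "little")
  hdr <- readLines(file.path(dir, "bsq.hdr"))
  writeLines(sub("interleave = bsq", "interleave = bil", hdr),
             file.path(dir, "bil.hdr"))
  a <- read_envi(file.path(dir, "bsq.hdr"))
  b <- read_envi(file.path(dir, "bil.hdr"))
  expect_identical(a$values, b$values)
})

test_that("integer ENVI dialects are supported", {
  dir <- withr::local_tempdir()
  vals <- array(sample.int(1000, 24), dim = c(2, 3, 4))
  writeBin(as.integer(as.vector(aperm(vals, c(2, 1, 3)))),
           file.path(dir, "int16"), size = 2, endian = "little")
  writeLines(c("ENVI", "samples = 3", "lines = 2", "bands = 4",
               "data type = 2", "interleave = bsq", "byte order = 0",
               "wavelength = { 500, 550, 600, 650 }"),
             file.path(dir, "int16.hdr"))
  cube <- read_envi(file.path(dir, "int16.hdr"))
  expect_equal(cube$values, vals, ignore_attr = TRUE)
})

test_that("malformed headers produce named errors", {
  dir <- withr::local_tempdir()
  cube <- make_cube(2, 2, 3)
  write_envi(cube, file.path(dir, "c"))
  hdr <- readLines(file.path(dir, "c.hdr"))
  writeLines(hdr[!grepl("^wavelength =", hdr)], file.path(dir, "nowl.hdr"))
  file.copy(file.path(dir, "c"), file.path(dir, "nowl"))
  expect_error(read_envi(file.path(dir, "nowl.hdr")), "wavelength")

  writeLines(sub("bands = 3", "bands = 2", hdr), file.path(dir, "badn.hdr"))
  file.copy(file.path(dir, "c"), file.path(dir, "badn"))
  expect_error(read_envi(file.path(dir, "badn.hdr")), "wavelengths")

  writeLines(sub("interleave = bsq", "interleave = bip", hdr),
             file.path(dir, "bip.hdr"))
  file.copy(file.path(dir, "c"), file.path(dir, "bip"))
  expect_error(read_envi(file.path(dir, "bip.hdr")), "unsupported")
})

test_that("nearest_band matches an exhaustive scan and honours the tie rule", {
  cube <- hyper_cube(array(0, dim = c(1, 1, 4)), c(600, 605, 610, 615))
  expect_identical(nearest_band(cube, 610), 3L)
  tie <- hyper_cube(array(0, dim = c(1, 1, 2)), c(600, 620))
  expect_identical(nearest_band(tie, 610), 1L)
  expect_error(nearest_band(tie, 200), "outside")

  grid128 <- 400 + 4.68 * (0:127)
  cube128 <- hyper_cube(array(0, dim = c(1, 1, 128)), grid128)
  scan <- which(abs(grid128 - 610) == min(abs(grid128 - 610)))[1]
  expect_identical(nearest_band(cube128, 610), scan)

  withr::with_seed(5, {
    for (i in 1:1000) {
      wl <- sort(runif(sample(2:30, 1), 400, 1000))
      wl <- wl[!duplicated(wl)]
      cube <- hyper_cube(array(0, dim = c(1, 1, length(wl))), wl)
      target <- runif(1, min(wl) - 50, max(wl) + 50)
      d <- abs(wl - target)
      expect_identical(nearest_band(cube, target), which(d == min(d))[1])
    }
  })
})

test_that("visible composite averages equal-width thirds", {
  const <- hyper_cube(array(7, dim = c(3, 3, 12)),
                      seq(410, 690, length.out = 12))
  comp <- visible_composite(const)
  expect_true(all(comp == 0))  # constant channels min-max to zero

  # energy only below 500 nm -> blue channel dominates
  wl <- seq(410, 690, length.out = 12)
  vals <- array(0, dim = c(3, 3, 12))
  vals[, , wl < 500] <- 5
  vals[2, 2, ] <- vals[2, 2, ] + 1  # spatial structure so scaling is non-trivial
  blue_heavy <- hyper_cube(vals, wl)
  comp <- visible_composite(blue_heavy)
  expect_true(mean(comp[, , 3]) >= mean(comp[, , 1]))

  # brute-force per-pixel oracle on a 4 x 4 x 12 cube
  withr::with_seed(8, {
    vals <- array(runif(4 * 4 * 12), dim = c(4, 4, 12))
  })
  cube <- hyper_cube(vals, wl)
  comp <- visible_composite(cube, 400, 700)
  edges <- seq(400, 700, length.out = 4)
  for (third in 1:3) {
    sel <- wl >= edges[third] & (wl < edges[third + 1] | third == 3)
    ch <- matrix(0, 4, 4)
    for (r in 1:4) for (c in 1:4) ch[r, c] <- mean(vals[r, c, sel])
    ch <- (ch - min(ch)) / (max(ch) - min(ch))
    expect_equal(comp[, , 4 - third], ch, tolerance = 1e-12)
  }

  few <- hyper_cube(array(1, dim = c(2, 2, 3)), c(410, 450, 800))
  expect_error(visible_composite(few), ">= 3 bands")
})
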