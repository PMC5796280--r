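# Thermal-frame model: calibration, histogram, background estimate,
# BCT, binarization, particle filtering, CP counting.

test_that("temperature/intensity conversion is affine, rounded half-up, clipped", {
  calib <- temperature_calibration(0, 51)
  expect_identical(temperature_to_intensity(0, calib), 0L)
  expect_identical(temperature_to_intensity(51, calib), 255L)
  expect_identical(temperature_to_intensity(25.5, calib), 128L)  # 127.5 rounds up
  expect_identical(temperature_to_intensity(-10, calib), 0L)
  expect_identical(temperature_to_intensity(100, calib), 255L)
  expect_equal(intensity_to_temperature(0, calib), 0)
  expect_equal(intensity_to_temperature(255, calib), 51)
  expect_equal(intensity_to_temperature(128, calib), 25.6)
  expect_error(intensity_to_temperature(256, calib), class = "thermonest_input_error")
  expect_error(temperature_calibration(20, 20), class = "thermonest_config_error")
  expect_error(temperature_calibration(30, 10), class = "thermonest_config_error")
})

test_that("conversion round trip errs by at most half a calibration step", {
  calib <- temperature_calibration(0, 51)
  step <- 51 / 255
  temps <- seq(0, 51, by = 0.07)
  back <- intensity_to_temperature(temperature_to_intensity(temps, calib), calib)
  expect_lte(max(abs(back - temps)), step / 2 + 1e-12)
  # intensities survive a full round trip exactly
  ints <- 0:255
  expect_identical(temperature_to_intensity(intensity_to_temperature(ints, calib), calib),
                   as.integer(ints))
})

test_that("histogram counts every pixel exactly once", {
  f <- make_frame(40L, nrow = 10L, ncol = 10L)
  h <- compute_histogram(f)
  expect_identical(h[41L], 100L)
  expect_identical(sum(h), 100L)
  expect_identical(sum(h != 0L), 1L)

  two <- matrix(c(rep(30L, 60), rep(200L, 40)), nrow = 10)
  h2 <- compute_histogram(thermal_frame(two))
  expect_identical(h2[31L], 60L)
  expect_identical(h2[201L], 40L)
  expect_identical(sum(h2), 100L)

  f320 <- thermal_frame(matrix(7L, 240, 320))
  expect_identical(sum(compute_histogram(f320)), 76800L)
})

test_that("histogram conservation holds on random frames", {
  set.seed(11)
  for (k in 1:20) {
    nr <- sample(1:50, 1); nc <- sample(1:50, 1)
    px <- matrix(sample(0:255, nr * nc, replace = TRUE), nr)
    expect_identical(sum(compute_histogram(thermal_frame(px))), nr * nc)
  }
})

test_that("background estimate returns the dominant histogram mode", {
  calib <- temperature_calibration(0, 51)
  # constant frame at 18 degC
  f <- thermal_frame(matrix(temperature_to_intensity(18, calib), 20, 20), calib)
  expect_equal(estimate_background_temperature(f), 18, tolerance = 0.11)

  # bimodal: tall background peak at 90 beats a warm-body peak at 190
  px <- matrix(c(rep(90L, 700), rep(190L, 300)), nrow = 25)
  expect_equal(estimate_background_temperature(thermal_frame(px, calib)),
               intensity_to_temperature(90, calib))

  # noisy floor plus a hen blob covering 10% of pixels
  set.seed(3)
  temps <- matrix(rnorm(76800, mean = 18, sd = 0.3), 240, 320)
  temps[1:96, 1:80] <- rnorm(96 * 80, mean = 38, sd = 0.3)
  f2 <- thermal_frame(matrix(temperature_to_intensity(temps, calib), 240), calib)
  expect_lt(abs(estimate_background_temperature(f2) - 18), 0.5)
})

test_that("pure-noise background recovery is within 0.5 degC in >=99% of replicates", {
  calib <- temperature_calibration(0, 51)
  set.seed(77)
  mus <- runif(100, 14, 20)
  err <- vapply(mus, function(mu) {
    px <- matrix(temperature_to_intensity(rnorm(160 * 120, mu, 0.3), calib), 120)
    abs(estimate_background_temperature(thermal_frame(px, calib)) - mu)
  }, numeric(1))
  expect_gte(mean(err <= 0.5), 0.99)
})

test_that("BCT is the shifted background temperature in grayscale", {
  calib <- temperature_calibration(0, 51)
  expect_identical(compute_bct(18, 0, calib), temperature_to_intensity(18, calib))
  expect_identical(compute_bct(18, 5, calib), 115L)  # 23 degC at 0.2 degC/step
  for (shift in c(1, 3, 5)) {
    expect_identical(compute_bct(18, shift, calib),
                     temperature_to_intensity(18 + shift, calib))
  }
  expect_warning(bct <- compute_bct(50, 5, calib), "clipped")
  expect_identical(bct, 255L)
  expect_error(compute_bct(18, -1, calib), class = "thermonest_config_error")
})

test_that("binarization is strictly greater-than the threshold", {
  px <- matrix(as.integer(c(10, 20, 20, 30)), 2)
  expect_identical(as.vector(binarize(px, 20)), c(0L, 0L, 0L, 1L))
  expect_identical(sum(binarize(px, 5)), 4L)
  expect_identical(sum(binarize(px, 30)), 0L)
  f <- make_frame(90L, blobs = list(list(rows = 10:29, cols = 10:34, intensity = 200L)))
  b <- binarize(f, 150)
  expect_identical(sum(b), 500L)
  expect_identical(which(b == 1L), which(f$pixels == 200L))
})

test_that("CP is non-increasing in the threshold", {
  set.seed(5)
  px <- matrix(sample(0:255, 900, replace = TRUE), 30)
  cps <- vapply(0:255, function(b) count_colored_pixels(binarize(px, b)), numeric(1))
  expect_true(all(diff(cps) <= 0))
  expect_identical(cps[256], 0)
})

test_that("particle filter removes small components and is idempotent", {
  bin <- matrix(0L, 60, 60)
  bin[2:4, 2] <- 1L                    # area 3
  bin[10:16, 10] <- 1L                 # area 7
  bin[30:59, 30:59] <- 1L              # area 900
  out <- filter_small_particles(bin, 50)
  expect_identical(sum(out), 900L)
  expect_identical(out, filter_small_particles(out, 50))
  expect_identical(filter_small_particles(bin, 0), bin)
  expect_lte(sum(out), sum(bin))
  # salt noise plus one blob
  set.seed(9)
  salt <- matrix(0L, 100, 100)
  salt[cbind(seq(5, 95, by = 10), seq(5, 95, by = 10))] <- 1L
  salt[40:69, 40:69] <- 1L
  expect_identical(sum(filter_small_particles(salt, 50)), 900L)
})

test_that("labeling splits 8-connected particles and conserves CP", {
  bin <- matrix(0L, 40, 40)
  bin[2:11, 2:11] <- 1L
  bin[20:24, 20:24] <- 1L
  ps <- label_particles(bin)
  expect_identical(nrow(ps), 2L)
  expect_setequal(ps$area, c(100L, 25L))
  expect_identical(sum(ps$area), count_colored_pixels(bin))
  # diagonal-touching pixels merge under 8-connectivity
  diag2 <- matrix(0L, 4, 4); diag2[1, 1] <- 1L; diag2[2, 2] <- 1L
  expect_identical(nrow(label_particles(diag2)), 1L)
  # empty image
  expect_identical(nrow(label_particles(matrix(0L, 5, 5))), 0L)
})

test_that("labeling agrees with a flood-fill oracle on random images", {
  set.seed(21)
  for (k in 1:25) {
    bin <- matrix(rbinom(12 * 15, 1, 0.35), 12, 15)
    ps <- label_particles(bin)
    expect_identical(sort(ps$area), as.integer(oracle_label8_areas(bin)))
    expect_identical(sum(ps$area), count_colored_pixels(bin))
  }
})

test_that("particle centroids and moments match direct computation", {
  bin <- matrix(0L, 20, 20)
  bin[5:8, 3:12] <- 1L
  ps <- label_particles(bin)
  xy <- particle_coords(ps, 1L)
  expect_equal(ps$centroid_row, mean(xy[, "row"]))
  expect_equal(ps$centroid_col, mean(xy[, "col"]))
  expect_equal(ps$mu_rr, mean((xy[, "row"] - mean(xy[, "row"]))^2))
  expect_equal(ps$mu_rc, 0)
})
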