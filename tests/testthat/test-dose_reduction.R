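# NPS estimation, the pixel-value/variance curve, and noise synthesis.

test_that("NPS of white noise is flat and satisfies Parseval", {
  set.seed(1)
  img <- matrix(rnorm(512 * 512, 100, 10), 512, 512)
  e <- estimate_nps(img, 0.2, 128)
  # integral = variance x pixel area
  expect_equal(nps_integral(e), var(as.vector(img)) * 0.2^2,
               tolerance = 0.02)
  # flat: radial profile stays near its own mean
  r <- radial_nps(e, 12)
  expect_lt(max(abs(r$nps / mean(r$nps) - 1)), 0.1)
  # constant image -> zero NPS
  e0 <- estimate_nps(matrix(5, 256, 256), 0.2, 64)
  expect_lt(max(e0$nps), 1e-20)
  expect_error(estimate_nps(matrix(0, 100, 100), 0.2, 100), "power of two")
  expect_error(estimate_nps(matrix(0, 64, 64), 0.2, 64), "fewer than 4")
})

test_that("NPS of filtered noise follows the squared filter transfer", {
  set.seed(2)
  img <- matrix(rnorm(1024 * 1024), 1024, 1024)
  sigma <- 0.3; pitch <- 0.2
  blurred <- tomonodule:::apply_mtf(img, list(type = "gaussian",
                                              sigma = sigma), pitch)
  e <- estimate_nps(blurred, pitch, 128)
  # bin the measured NPS and the analytic |H|^2 over the same pixels;
  # frequencies below 0.15 cycles/mm are excluded (ROI detrending removes
  # power there by construction)
  r <- tomonodule:::freq_radius(128, 128, pitch)
  H2 <- exp(-2 * pi^2 * sigma^2 * r^2)^2
  # below ~15% transfer the rectangular-window sidelobe leakage of the
  # neighbouring strong frequencies dominates the residual true power
  sel <- r > 0.15 & H2 > 0.15
  bins <- cut(r[sel], 12)
  got <- tapply(e$nps[sel], bins, mean)
  want <- tapply(H2[sel], bins, mean)
  ratio <- got / want
  ratio <- ratio / (sum(got) / sum(want))
  expect_lt(max(abs(ratio - 1)), 0.05)
})

test_that("variance curve recovers proportionality and the electronic intercept", {
  # pure quantum: variance proportional to mean, through the origin
  d0 <- detector_model(electronic_sd = 0)
  ff0 <- generate_flat_fields(d0, c(0.25, 0.5, 0.75, 1), 2, c(256, 256),
                              seed = 3)
  vc0 <- fit_variance_curve(ff0)
  k <- vc0$knots
  slope <- sum(k$mean * k$variance) / sum(k$mean^2)
  expect_lt(max(abs(k$variance - slope * k$mean) / k$variance), 0.03)
  # electronic noise appears as the affine intercept
  d1 <- detector_model(electronic_sd = 4)
  ff1 <- generate_flat_fields(d1, c(0.25, 0.5, 0.75, 1), 2, c(256, 256),
                              seed = 3)
  fit <- lm(variance ~ mean, fit_variance_curve(ff1)$knots)
  expect_equal(unname(coef(fit)[1]), 16, tolerance = 0.05)
  # single level is rejected
  expect_error(fit_variance_curve(data.frame(mean = 100, variance = 5)),
               "3 dose levels")
})

test_that("make_noise_image hits the variance-curve target", {
  vc <- fit_variance_curve(data.frame(mean = c(100, 500, 1000),
                                      variance = c(6, 22, 40)))
  n <- 1024
  w_low <- matrix(1, n, n); w_high <- matrix(1, n, n)
  s <- 0.5
  # flat pixel map: variance = vc(s*v0) - s^2 vc(v0)
  v0 <- 1000
  noise <- make_noise_image(c(n, n), w_low, w_high, s, vc,
                            matrix(v0, n, n), seed = 5)
  target <- predict(vc, s * v0) - s^2 * predict(vc, v0)
  expect_equal(var(as.vector(noise)), target, tolerance = 0.02)
  expect_equal(mean(noise), 0, tolerance = 0.01)
  # two plateaus get their own local targets
  pm <- cbind(matrix(1000, n, n / 2), matrix(500, n, n / 2))
  noise2 <- make_noise_image(c(n, n), w_low, w_high, s, vc, pm, seed = 6)
  for (half in list(1:(n / 2), (n / 2 + 1):n)) {
    v <- pm[1, half[1]]
    tgt <- predict(vc, s * v) - s^2 * predict(vc, v)
    expect_equal(var(as.vector(noise2[, half])), tgt, tolerance = 0.05)
  }
  # s = 1 with identical spectra: exactly zero
  z <- make_noise_image(c(64, 64), matrix(1, 64, 64), matrix(1, 64, 64), 1,
                        vc, matrix(1000, 64, 64), seed = 7)
  expect_true(all(z == 0))
  # inconsistent calibration is refused
  expect_error(make_noise_image(c(64, 64), matrix(0.1, 64, 64),
                                matrix(1, 64, 64), 0.9, vc,
                                matrix(1000, 64, 64), seed = 8),
               "inconsistent")
})

test_that("dose reduction matches a directly simulated low-dose flat field", {
  d <- detector_model()
  ff <- generate_flat_fields(d, c(0.25, 0.32, 0.5, 0.71, 1), 2,
                             c(256, 256), seed = 3)
  cal <- flat_field_calibration(ff, roi_size = 64)
  g <- system_geometry(n_projections = 3, detector_size = c(256, 256))
  pix <- array(0, dim = c(256, 256, 3))
  orig <- generate_flat_fields(d, 1, 3, c(256, 256), seed = 21)
  for (i in 1:3) pix[, , i] <- orig$images[[i]]
  p <- projection_set(pix, g)
  s <- 0.5
  red <- simulate_dose_reduction(p, s, cal, seed = 11)
  expect_equal(red$dose_fraction, 0.5)
  v_red <- mean(apply(red$pixels, 3, function(m) var(as.vector(m))))
  oracle <- generate_flat_fields(d, s, 4, c(256, 256), seed = 99)
  v_orc <- flat_field_stats(oracle)$variance
  expect_equal(v_red, v_orc, tolerance = 0.05)
  # mean scales with s
  expect_equal(mean(red$pixels), s * mean(p$pixels), tolerance = 0.01)
  # s = 1 is a no-op
  expect_identical(simulate_dose_reduction(p, 1, cal, seed = 1)$pixels,
                   p$pixels)
  # reproducibility
  red2 <- simulate_dose_reduction(p, s, cal, seed = 11)
  expect_identical(red$pixels, red2$pixels)
})

test_that("noise variance decreases monotonically with the dose fraction", {
  d <- detector_model()
  ff <- generate_flat_fields(d, c(0.25, 0.32, 0.5, 0.71, 1), 2,
                             c(256, 256), seed = 3)
  cal <- flat_field_calibration(ff, roi_size = 64)
  g <- system_geometry(n_projections = 2, detector_size = c(256, 256))
  orig <- generate_flat_fields(d, 1, 1, c(256, 256), seed = 31)
  p <- projection_set(array(rep(orig$images[[1]], 2), dim = c(256, 256, 2)), g)
  vars <- vapply(c(0.32, 0.5, 0.8), function(s) {
    r <- simulate_dose_reduction(p, s, cal, seed = 13)
    var(as.vector(r$pixels))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("two-step reduction composes to the direct one", {
  d <- detector_model()
  ff <- generate_flat_fields(d, c(0.25, 0.32, 0.5, 0.71, 1), 2,
                             c(256, 256), seed = 3)
  cal <- flat_field_calibration(ff, roi_size = 64)
  g <- system_geometry(n_projections = 2, detector_size = c(256, 256))
  orig <- generate_flat_fields(d, 1, 2, c(256, 256), seed = 41)
  p <- projection_set(array(c(orig$images[[1]], orig$images[[2]]),
                            dim = c(256, 256, 2)), g)
  two <- simulate_dose_reduction(
    simulate_dose_reduction(p, 0.5, cal, seed = 5), 0.64, cal, seed = 6)
  one <- simulate_dose_reduction(p, 0.32, cal, seed = 7)
  v2 <- mean(apply(two$pixels, 3, function(m) var(as.vector(m))))
  v1 <- mean(apply(one$pixels, 3, function(m) var(as.vector(m))))
  expect_equal(two$dose_fraction, 0.32)
  expect_equal(v2, v1, tolerance = 0.07)
})
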