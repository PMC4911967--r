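# Acquisition: sweep geometry, exposure arithmetic, nodule insertion.

test_that("focal spots span the sweep uniformly along the vertical axis", {
  g <- system_geometry(sid = 1800, half_angle = 15, n_projections = 60)
  th <- projection_angles(g)
  expect_equal(th[1], -15)
  expect_equal(th[60], 15)
  expect_equal(diff(th), rep(diff(th)[1], 59))
  fs <- focal_spot_positions(g)
  expect_equal(dim(fs), c(60L, 3L))
  expect_true(all(fs[, 1] == 0))
  expect_true(all(fs[, 3] == 1800))
  # closed-form tangent at the sweep end
  expect_equal(unname(fs[60, 2]), 1800 * tan(15 * pi / 180), tolerance = 1e-12)
  expect_equal(unname(fs[60, 2]), 482.3, tolerance = 1e-4)
  # central ray
  g0 <- system_geometry(n_projections = 3)
  expect_equal(focal_spot_positions(g0)[2, ], c(x = 0, y = 0, z = 1800))
})

test_that("per-projection tube load follows Renard quantisation and the floor", {
  expect_equal(renard_round_down(0.4167), 0.40)
  expect_equal(renard_round_down(c(1, 0.25, 3.14, 80.1)),
               c(1, 0.25, 2.5, 80))
  # scout 2.5 mAs x ratio 10 over 60 -> 0.4167 -> 0.40
  expect_equal(per_projection_tube_load(exposure_settings(2.5), 60), 0.40)
  # scout 0.5 -> 0.0833, clamped to the 0.25 floor
  expect_equal(per_projection_tube_load(exposure_settings(0.5), 60), 0.25)
  # exactly on a step and at the floor
  expect_equal(per_projection_tube_load(exposure_settings(1.5), 60), 0.25)
  # alternative order quantises the total first
  expect_equal(per_projection_tube_load(exposure_settings(2.5), 60,
                                        order = "round_then_divide"),
               25 / 60)
})

test_that("attenuation factor implements the lung-subtracted exponential", {
  expect_equal(attenuation_factor(0.16, 0.03, 0), 1)
  expect_equal(attenuation_factor(0.16, 0.03, 10), exp(-0.13), tolerance = 1e-12)
  expect_equal(attenuation_factor(0.16, 0.03, 10), 0.8781, tolerance = 1e-4)
  expect_lte(attenuation_factor(0.16, 0.03, 25), 1)
  expect_error(attenuation_factor(0.16, 0.03, -1), "nonnegative")
})

test_that("insertion leaves the stack unchanged in degenerate limits", {
  g <- system_geometry(n_projections = 5, detector_size = c(128, 64))
  p0 <- uniform_projections(g)
  e <- ellipsoid("n", c(0.1, 0.1, 30), 8, 1.2, theta = 20, sd_motion = 0)
  # nodule attenuation equal to lung: invisible
  ei <- e; ei$mu <- 0.03
  expect_identical(insert_nodule(p0, ei, insertion_config(seed = 1))$pixels,
                   p0$pixels)
  # infinite scatter-to-primary: contrast fully scattered away
  pinf <- insert_nodule(p0, e, insertion_config(spr = 1e12, seed = 1))
  expect_lt(max(abs(pinf$pixels - p0$pixels)), 1e-8)
  # fixed seed: bit-reproducible
  em <- e; em$sd_motion <- 0.2
  a <- insert_nodule(p0, em, insertion_config(seed = 7))
  b <- insert_nodule(p0, em, insertion_config(seed = 7))
  expect_identical(a$pixels, b$pixels)
  # out of field of view names the projection
  far <- ellipsoid("far", c(500, 0, 30), 8, 1.2)
  expect_error(insert_nodule(p0, far, insertion_config(seed = 1)),
               "projection 1")
})

test_that("parallel-beam central pixel matches the analytic chord exponential", {
  g <- system_geometry(sid = 1e7, n_projections = 2,
                       detector_size = c(64, 64), half_angle = 1e-6)
  p <- uniform_projections(g)
  e <- ellipsoid("s", c(0.1, 0.1, 100), 8, 1, sd_motion = 0)
  pn <- insert_nodule(p, e, insertion_config(mtf_model = NULL, spr = 0,
                                             seed = 1))
  # pixel (32, 33) is centred on (x, y) = (0.1, 0.1): chord = d_eq
  expect_equal(pn$pixels[32, 33, 1] / 1000, exp(-0.13 * 0.8),
               tolerance = 1e-6)
})

test_that("projected nodule displacement follows the magnification law", {
  g <- system_geometry(n_projections = 3, detector_size = c(256, 64))
  p <- uniform_projections(g)
  z <- 60
  e <- ellipsoid("p", c(0.1, 0.1, z), 1.5, 1, mu = 2, sd_motion = 0)
  pn <- insert_nodule(p, e, insertion_config(mtf_model = NULL, spr = 0,
                                             seed = 1))
  M <- g$sid / (g$sid - z)
  for (i in 1:3) {
    dP <- pn$pixels[, , i] - 1000
    w <- which(dP == min(dP), arr.ind = TRUE)[1, ]
    th <- pn$angles[i] * pi / 180
    y_pred <- 0.1 * M - g$sid * tan(th) * z / (g$sid - z)
    y_got <- (g$detector_size[1] * g$pixel_pitch / 2) -
      (w[1] - 0.5) * g$pixel_pitch
    expect_lt(abs(y_got - y_pred), g$pixel_pitch)
  }
})

test_that("signal deficit grows strictly with nodule size", {
  g <- system_geometry(n_projections = 3, detector_size = c(160, 120))
  p0 <- uniform_projections(g)
  defs <- vapply(c(4, 8, 12), function(d) {
    e <- ellipsoid("n", c(0, 0, 30), d, 1.2, theta = 45, sd_motion = 0)
    pn <- insert_nodule(p0, e, insertion_config(seed = 1))
    sum(p0$pixels - pn$pixels)
  }, numeric(1))
  expect_true(all(diff(defs) > 0))
})

test_that("motion shifts are half-normal in magnitude with zero mean direction", {
  set.seed(9)
  sh <- t(replicate(20000, tomonodule:::motion_shift(0.2)))
  expect_lt(max(abs(colMeans(sh))), 0.005)
  mag <- sqrt(rowSums(sh^2))
  expect_equal(mean(mag), 0.2 * sqrt(2 / pi), tolerance = 0.02)
  expect_equal(sqrt(mean(mag^2)), 0.2, tolerance = 0.02)
})
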