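# Synthetic detector, flat fields, lung-like backgrounds, observer model.

test_that("flat-field means scale linearly and variances are affine in dose", {
  d <- detector_model()
  ff <- generate_flat_fields(d, c(0.25, 0.5, 0.75, 1), 2, c(256, 256),
                             seed = 3)
  st <- flat_field_stats(ff)
  # mean halves with the level
  expect_equal(st$mean[st$level == 0.5] / st$mean[st$level == 1], 0.5,
               tolerance = 0.005)
  # affine variance: regression intercept recovers the electronic noise
  fit <- lm(variance ~ mean, st)
  expect_equal(unname(coef(fit)[1]), d$electronic_sd^2, tolerance = 0.10)
  # pure quantum detector: relative variance ~ 1/level
  d0 <- detector_model(electronic_sd = 0)
  st0 <- flat_field_stats(generate_flat_fields(d0, c(0.25, 1), 2,
                                               c(256, 256), seed = 5))
  rel <- st0$variance / st0$mean^2
  expect_equal(rel[st0$level == 0.25] / rel[st0$level == 1], 4,
               tolerance = 0.05)
})

test_that("implied DQE increases with dose level", {
  d <- detector_model()
  st <- flat_field_stats(generate_flat_fields(
    d, c(0.25, 0.4, 0.63, 1), 2, c(256, 256), seed = 3))
  # zero-frequency DQE surrogate: mean^2 / (variance x quanta)
  dqe <- st$mean^2 / (st$variance * st$level)
  expect_true(all(diff(dqe[order(st$level)]) > 0))
})

test_that("background stacks are reproducible with lung-like texture", {
  g <- system_geometry(n_projections = 3, detector_size = c(96, 96))
  d <- detector_model()
  b1 <- generate_background(g, d, texture_params(amplitude = 0.15), seed = 4)
  b2 <- generate_background(g, d, texture_params(amplitude = 0.15), seed = 4)
  expect_identical(b1$pixels, b2$pixels)
  # amplitude 0 collapses to a flat-field stack: coarse-block means are flat
  b0 <- generate_background(g, d, texture_params(amplitude = 0), seed = 4)
  block_means <- function(img) {
    sapply(split(as.vector(img),
                 rep(1:16, each = length(img) / 16)), mean)
  }
  rel0 <- sd(block_means(b0$pixels[, , 1])) / mean(b0$pixels[, , 1])
  rel1 <- sd(block_means(b1$pixels[, , 1])) / mean(b1$pixels[, , 1])
  expect_lt(rel0, 0.01)
  expect_gt(rel1, 3 * rel0)
})

test_that("power-law texture has the configured spectral exponent", {
  fld <- tomonodule:::power_law_field(c(256, 256), 3, 4)
  sp <- Mod(stats::fft(fld))^2
  r <- tomonodule:::freq_radius(256, 256, 1)
  sel <- r > 0.02 & r < 0.4
  slope <- unname(coef(lm(log(sp[sel]) ~ log(r[sel])))[2])
  expect_equal(slope, -3, tolerance = 0.15)
})

test_that("observer model is exact when all noise terms vanish", {
  nods <- generate_nodule_set(nodule_set_spec(
    d_eq_list = c(4, 8, 12), position_list = default_nodule_positions(5)))
  nt <- nodule_table(nods)
  op <- observer_params(bias_full_dose = 0, extra_bias_low_dose = 0,
                        sigma_intra = 0, sigma_observer = 0,
                        sigma_nodule = 0, nonmeasurable = c(-30, 0, 0),
                        seed = 2)
  m <- simulate_measurements(nt, c(1, 0.5), op)
  expect_equal(nrow(m), 4 * 15 * 2 * 2)
  expect_false(any(m$nonmeasurable))
  merged <- merge(m, nt[, c("id", "major_axis")],
                  by.x = "nodule_id", by.y = "id")
  expect_equal(merged$measured_diameter, merged$major_axis)
})

test_that("non-measurable outcomes follow the visibility ordering", {
  nods <- generate_nodule_set(nodule_set_spec())
  nt <- nodule_table(nods)
  op <- observer_params(seed = 7)
  m <- simulate_measurements(nt, c(1, 0.5, 0.32), op)
  cnt <- count_nonmeasurable(m)
  # largest nodules always measurable
  expect_true(all(cnt$n_nonmeasurable[cnt$size_group == "12mm"] == 0))
  # smallest group: counts non-increasing in dose fraction per observer
  for (o in 1:4) {
    sub <- cnt[cnt$observer_id == o & cnt$size_group == "4mm", ]
    sub <- sub[order(sub$dose_level), ]
    expect_true(all(diff(sub$n_nonmeasurable) <= 0))
  }
  # flags identical across rounds
  key <- paste(m$observer_id, m$nodule_id, m$dose_level)
  split_nm <- split(m$nonmeasurable, key)
  expect_true(all(vapply(split_nm, function(v) length(unique(v)) == 1,
                         logical(1))))
  # huge size slope: nothing non-measurable
  op2 <- observer_params(nonmeasurable = c(3.5, 100, 1.32), seed = 7)
  m2 <- simulate_measurements(nt, c(1, 0.5, 0.32), op2)
  expect_false(any(m2$nonmeasurable))
})

test_that("intraobserver estimator recovers the generating sigma", {
  nt <- nodule_table(generate_nodule_set(nodule_set_spec(d_eq_list = 8)))
  est <- vapply(1:100, function(i) {
    op <- observer_params(n_observers = 2, sigma_intra = 0.2,
                          sigma_observer = 0, sigma_nodule = 0.3,
                          nonmeasurable = c(-30, 0, 0), seed = 5000 + i)
    m <- simulate_measurements(nt, 1, op)
    mean(intraobserver_variability(m)$value)
  }, numeric(1))
  expect_equal(mean(est), 0.2, tolerance = 0.05)
})
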