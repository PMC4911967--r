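# Synthetic inputs: a quantum-plus-electronic detector model producing
# flat-field calibration sets, lung-like textured background projections,
# and a stochastic observer model producing two-round diameter
# measurements with non-measurable outcomes.

#' Detector model
#'
#' Raw pixel value = gain x (detector-blurred Poisson quanta) + zero-mean
#' Gaussian electronic noise. The electronic noise is dose independent, so
#' the implied DQE falls as the dose is lowered - the behaviour the
#' dose-reduction simulation must reproduce.
#'
#' @param gain Raw units per detected quantum.
#' @param quantum_fluence_at_ref Quanta per mm^2 at reference (full) dose.
#' @param electronic_sd Electronic noise SD, raw units.
#' @param blur_sigma Detector blur (Gaussian PSF sigma), mm.
#' @param pixel_pitch Pixel pitch, mm.
#' @return An object of class `"detector_model"`.
#' @export
detector_model <- function(gain = 0.2, quantum_fluence_at_ref = 125000,
                           electronic_sd = 4, blur_sigma = 0.18,
                           pixel_pitch = 0.2) {
  stopifnot(gain > 0, quantum_fluence_at_ref > 0, electronic_sd >= 0,
            blur_sigma >= 0, pixel_pitch > 0)
  structure(list(gain = gain,
                 quantum_fluence_at_ref = quantum_fluence_at_ref,
                 electronic_sd = electronic_sd, blur_sigma = blur_sigma,
                 pixel_pitch = pixel_pitch),
            class = "detector_model")
}

# One detector readout of a (possibly non-uniform) expected quanta map.
detector_readout <- function(d, lambda) {
  q <- matrix(stats::rpois(length(lambda), as.vector(lambda)),
              nrow(lambda), ncol(lambda))
  if (d$blur_sigma > 0) {
    q <- apply_mtf(q, list(type = "gaussian", sigma = d$blur_sigma),
                   d$pixel_pitch)
  }
  d$gain * q + matrix(stats::rnorm(length(lambda), 0, d$electronic_sd),
                      nrow(lambda), ncol(lambda))
}

#' Generate flat-field images at a set of dose levels
#'
#' @param d A [detector_model()].
#' @param dose_fractions Relative dose levels in (0, 1.5].
#' @param n_per_level Images per level.
#' @param shape Length-2 (rows, cols).
#' @param seed Integer seed.
#' @return An object of class `"flat_field_set"`: `images` (list of
#'   matrices), `levels` (per image), the detector and pitch.
#' @export
generate_flat_fields <- function(d, dose_fractions, n_per_level = 2L,
                                 shape = c(256L, 256L), seed = 1L) {
  stopifnot(inherits(d, "detector_model"),
            all(dose_fractions > 0 & dose_fractions <= 1.5))
  lambda0 <- d$quantum_fluence_at_ref * d$pixel_pitch^2
  images <- list(); levels <- numeric(0)
  for (lv in dose_fractions) {
    for (j in seq_len(n_per_level)) {
      img <- with_seed(derive_seed(seed, "flat", lv, j), {
        detector_readout(d, matrix(lv * lambda0, shape[1], shape[2]))
      })
      images[[length(images) + 1L]] <- img
      levels <- c(levels, lv)
    }
  }
  structure(list(images = images, levels = levels, detector = d,
                 pixel_pitch = d$pixel_pitch),
            class = "flat_field_set")
}

#' Per-level mean and variance of a flat-field set
#' @param flats A [generate_flat_fields()] result.
#' @return Data frame with columns `level`, `mean`, `variance`.
#' @export
flat_field_stats <- function(flats) {
  stopifnot(inherits(flats, "flat_field_set"))
  lev <- sort(unique(flats$levels))
  do.call(rbind, lapply(lev, function(lv) {
    idx <- which(flats$levels == lv)
    data.frame(level = lv,
               mean = mean(vapply(flats$images[idx], mean, numeric(1))),
               variance = mean(vapply(flats$images[idx],
                                      function(m) stats::var(as.vector(m)),
                                      numeric(1))))
  }))
}

#' Texture parameters for the lung-like background
#'
#' @param amplitude Log-amplitude of the multiplicative texture (0 gives a
#'   pure flat-field stack).
#' @param exponent Power-law exponent of the 3-D texture spectrum
#'   (power ~ f^-exponent).
#' @param n_voxels Length-3 texture grid (x, y, z).
#' @return A list of class `"texture_params"`.
#' @export
texture_params <- function(amplitude = 0.15, exponent = 3,
                           n_voxels = c(48L, 48L, 16L)) {
  stopifnot(amplitude >= 0, exponent >= 0, length(n_voxels) == 3)
  structure(list(amplitude = amplitude, exponent = exponent,
                 n_voxels = as.integer(n_voxels)),
            class = "texture_params")
}

#' Generate a lung-like background projection stack
#'
#' A single 3-D power-law Gaussian texture is projected per focal spot
#' (vertical shear proportional to depth and tube angle, then summation
#' over depth), so the texture moves consistently with parallax across the
#' sweep. The projected texture multiplies the expected quanta of the
#' detector model before Poisson sampling, giving a smooth low-frequency
#' lung-like modulation on top of flat-field exposure.
#'
#' @param g A [system_geometry()].
#' @param d A [detector_model()].
#' @param texture A [texture_params()].
#' @param dose_fraction Relative exposure level.
#' @param mAs_per_projection Metadata, mAs.
#' @param seed Integer seed.
#' @return A [projection_set()].
#' @export
generate_background <- function(g, d, texture = texture_params(),
                                dose_fraction = 1, mAs_per_projection = NA,
                                seed = 1L) {
  stopifnot(inherits(g, "system_geometry"), inherits(d, "detector_model"),
            inherits(texture, "texture_params"))
  nv <- texture$n_voxels
  vol <- power_law_field(nv, texture$exponent, derive_seed(seed, "texture"))
  nr <- g$detector_size[1]; nc <- g$detector_size[2]
  angles <- projection_angles(g) * pi / 180
  lambda0 <- dose_fraction * d$quantum_fluence_at_ref * d$pixel_pitch^2
  # texture voxel depth positions (mm), centred mid-way source-detector
  z_mm <- (seq_len(nv[3]) - (nv[3] + 1) / 2) * (g$sid / 4) / nv[3] + g$sid / 4
  # vertical voxel pitch in mm on the detector grid
  y_pitch_vox <- nr * g$pixel_pitch / nv[2]
  pix <- array(0, dim = c(nr, nc, g$n_projections))
  for (i in seq_len(g$n_projections)) {
    tproj <- matrix(0, nv[2], nv[1])
    for (k in seq_len(nv[3])) {
      shift_vox <- z_mm[k] * tan(angles[i]) / y_pitch_vox
      Wr <- resample_operator(seq_len(nv[2]) + shift_vox, nv[2])
      tproj <- tproj + Wr %*% t(vol[, , k])
    }
    tproj <- tproj / sqrt(nv[3])
    tex <- resample_image(tproj,
                          seq(1, nv[2], length.out = nr),
                          seq(1, nv[1], length.out = nc))
    tex <- tex / max(stats::sd(tex), 1e-12)
    lam <- lambda0 * exp(texture$amplitude * tex - texture$amplitude^2 / 2)
    pix[, , i] <- with_seed(derive_seed(seed, "readout", i),
                            detector_readout(d, lam))
  }
  projection_set(pmax(pix, 0), g, mAs_per_projection, dose_fraction)
}

#' Observer-model parameters
#'
#' Measurements are generated as
#' `major_axis + bias(group, dose) + b_obs + u_nodule + eps_round` with
#' `b_obs ~ N(0, sigma_observer^2)` per observer,
#' `u_nodule ~ N(0, sigma_nodule^2)` per observer-nodule pair, and
#' `eps ~ N(0, sigma_intra^2)` per round. A nodule is declared
#' non-measurable (identically in both rounds) with probability
#' `plogis(intercept - slope_size * d_eq - slope_dose * dose_fraction)`;
#' the draws share one latent visibility per (observer, nodule), so a
#' nodule non-measurable at some dose is also non-measurable at every
#' lower dose.
#'
#' The default bias and sigma values are illustrative: they sit inside the
#' ranges reported for human thoracic radiologists performing this task
#' (underestimation of a few tenths of a millimetre, growing at low dose
#' for some observers), but they are modelling choices, not fits to any
#' observer's data.
#'
#' @param n_observers Number of simulated observers (>= 2).
#' @param bias_full_dose Additive bias, mm, per size group (ascending
#'   `d_eq` order) at full dose.
#' @param extra_bias_low_dose Additional bias, mm, at dose fractions below
#'   `low_dose_threshold`, applied to `extra_bias_observers`.
#' @param extra_bias_observers Indices of the observers receiving the
#'   extra low-dose bias.
#' @param low_dose_threshold Dose fraction below which the extra bias
#'   applies.
#' @param sigma_intra Round-to-round measurement SD, mm.
#' @param sigma_observer Between-observer SD, mm.
#' @param sigma_nodule Observer-by-nodule interaction SD, mm.
#' @param nonmeasurable Logistic coefficients
#'   `c(intercept, slope_size, slope_dose)` for the non-measurable model
#'   (`slope_size` per mm of `d_eq`, `slope_dose` per unit dose fraction).
#' @param seed Integer seed.
#' @return An object of class `"observer_params"`.
#' @export
observer_params <- function(n_observers = 4L,
                            bias_full_dose = c(-0.4, -0.25, -0.15),
                            extra_bias_low_dose = -0.2,
                            extra_bias_observers = c(1L, 3L),
                            low_dose_threshold = 0.4,
                            sigma_intra = 0.2,
                            sigma_observer = 0.1,
                            sigma_nodule = 0.3,
                            nonmeasurable = c(intercept = 3.5,
                                              slope_size = 0.82,
                                              slope_dose = 1.32),
                            seed = 1L) {
  stopifnot(n_observers >= 2, sigma_intra >= 0, sigma_observer >= 0,
            sigma_nodule >= 0, length(nonmeasurable) == 3)
  structure(list(n_observers = as.integer(n_observers),
                 bias_full_dose = bias_full_dose,
                 extra_bias_low_dose = extra_bias_low_dose,
                 extra_bias_observers = as.integer(extra_bias_observers),
                 low_dose_threshold = low_dose_threshold,
                 sigma_intra = sigma_intra, sigma_observer = sigma_observer,
                 sigma_nodule = sigma_nodule,
                 nonmeasurable = unname(nonmeasurable),
                 seed = as.integer(seed)),
            class = "observer_params")
}

#' Simulate the two-round measurement study
#'
#' @param nodules List of [ellipsoid()] objects or a [nodule_table()].
#' @param dose_levels Dose fractions presented (e.g. `c(1, 0.5, 0.32)`).
#' @param op An [observer_params()].
#' @param n_rounds Measurement rounds (default 2).
#' @return A measurement table: one row per (observer, nodule, dose,
#'   round) with `measured_diameter` (mm, `NA` when non-measurable), a
#'   `nonmeasurable` flag, and the logged `section_index` within the
#'   10-section presentation window.
#' @export
simulate_measurements <- function(nodules, dose_levels, op, n_rounds = 2L) {
  stopifnot(inherits(op, "observer_params"), length(dose_levels) >= 1)
  nt <- if (is.data.frame(nodules)) nodules else nodule_table(nodules)
  stopifnot(nrow(nt) >= 1)
  groups <- sort(unique(nt$d_eq))
  bias_g <- rep(op$bias_full_dose, length.out = length(groups))
  coef <- op$nonmeasurable
  n_nod <- nrow(nt)
  n_dose <- length(dose_levels)
  with_seed(derive_seed(op$seed, "observer-study"), {
    b_obs <- stats::rnorm(op$n_observers, 0, op$sigma_observer)
    # cell grid: rounds vary fastest, then dose, nodule, observer
    cells <- expand.grid(round = seq_len(n_rounds),
                         dose_i = seq_len(n_dose),
                         nod = seq_len(n_nod),
                         obs = seq_len(op$n_observers))
    s <- dose_levels[cells$dose_i]
    d_eq <- nt$d_eq[cells$nod]
    gi <- match(d_eq, groups)
    # per (observer, nodule) effect, shared across doses and rounds
    key_on <- (cells$obs - 1L) * n_nod + cells$nod
    u_on <- stats::rnorm(op$n_observers * n_nod, 0, op$sigma_nodule)
    # non-measurable via a shared per-(observer, nodule) latent visibility:
    # marginally Bernoulli(logistic(...)) at each dose, identical across
    # rounds, and nested across doses (a nodule invisible at one dose is
    # invisible at every lower dose)
    nm_draw <- stats::runif(op$n_observers * n_nod)
    p_cell <- stats::plogis(coef[1] - coef[2] * d_eq - coef[3] * s)
    nm <- nm_draw[key_on] < p_cell
    bias <- bias_g[gi] + ifelse(
      s < op$low_dose_threshold & cells$obs %in% op$extra_bias_observers,
      op$extra_bias_low_dose, 0)
    eps <- stats::rnorm(nrow(cells), 0, op$sigma_intra)
    meas <- nt$major_axis[cells$nod] + bias + b_obs[cells$obs] +
      u_on[key_on] + eps
    sect <- sample(4:6, nrow(cells), replace = TRUE,
                   prob = c(0.15, 0.7, 0.15))
    out <- data.frame(
      observer_id = cells$obs,
      nodule_id = nt$id[cells$nod],
      size_group = as.character(nt$size_group[cells$nod]),
      dose_level = s, round = cells$round,
      measured_diameter = ifelse(nm, NA_real_, meas),
      nonmeasurable = nm,
      section_index = ifelse(nm, NA_integer_, sect))
    out$size_group <- factor(out$size_group, levels = paste0(groups, "mm"))
    out
  })
}

#' Ground-truth diameters for a nodule set
#' @param nodules List of ellipsoids or a [nodule_table()].
#' @return Data frame `nodule_id`, `size_group`, `true_diameter` (the
#'   major-axis length, mm).
#' @export
nodule_truths <- function(nodules) {
  nt <- if (is.data.frame(nodules)) nodules else nodule_table(nodules)
  data.frame(nodule_id = nt$id, size_group = nt$size_group,
             true_diameter = nt$major_axis)
}
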