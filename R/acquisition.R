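# Tomosynthesis acquisition: system geometry, exposure arithmetic, raw
# projection containers, and analytic nodule insertion.
#
# Conventions: the detector lies in the plane z = 0 with its centre at the
# patient-frame origin; the focal spot travels vertically at depth z = sid.
# Image row 1 is the top of the detector (largest y); pixel centres sit at
# half-pixel offsets. Raw pixel values are linear in detected exposure
# (pre-logarithm), so a nodule inserts multiplicatively.

#' Tomosynthesis system geometry
#'
#' @param sid Source-to-detector distance, mm.
#' @param half_angle Half of the angular sweep, degrees; focal-spot angles
#'   span `[-half_angle, +half_angle]` inclusive, uniformly.
#' @param n_projections Number of projection radiographs (>= 2).
#' @param pixel_pitch Detector pixel pitch, mm.
#' @param detector_size Length-2 integer, (rows, cols).
#' @return An object of class `"system_geometry"`.
#' @export
system_geometry <- function(sid = 1800, half_angle = 15, n_projections = 60L,
                            pixel_pitch = 0.2,
                            detector_size = c(2022L, 2022L)) {
  stopifnot(sid > 0, half_angle > 0, n_projections >= 2, pixel_pitch > 0,
            length(detector_size) == 2, all(detector_size >= 1))
  structure(list(sid = sid, half_angle = half_angle,
                 n_projections = as.integer(n_projections),
                 pixel_pitch = pixel_pitch,
                 detector_size = as.integer(detector_size),
                 tube_motion_axis = "y"),
            class = "system_geometry")
}

#' Projection angles of the sweep
#' @param g A [system_geometry()].
#' @return Numeric vector of angles, degrees, uniform over
#'   `[-half_angle, +half_angle]` inclusive.
#' @export
projection_angles <- function(g) {
  seq(-g$half_angle, g$half_angle, length.out = g$n_projections)
}

#' Focal-spot positions along the vertical tube sweep
#'
#' The tube moves vertically at depth `sid`; at angle theta the focal spot
#' sits at (0, sid * tan(theta), sid).
#'
#' @param g A [system_geometry()].
#' @return `n_projections` x 3 matrix of patient-frame positions, mm.
#' @export
focal_spot_positions <- function(g) {
  th <- projection_angles(g) * pi / 180
  cbind(x = 0, y = g$sid * tan(th), z = g$sid)
}

#' Exposure settings for the sweep
#'
#' @param scout_mAs Tube load of the conventional PA scout radiograph, mAs.
#' @param dose_ratio Tomosynthesis-to-scout tube-load ratio (10 in the
#'   clinical protocol modelled here).
#' @param min_mAs_per_projection Floor on the per-projection tube load, mAs.
#' @param tube_voltage Tube voltage, kVp (metadata only).
#' @return An object of class `"exposure_settings"`.
#' @export
exposure_settings <- function(scout_mAs, dose_ratio = 10,
                              min_mAs_per_projection = 0.25,
                              tube_voltage = 120) {
  stopifnot(scout_mAs > 0, dose_ratio > 0, min_mAs_per_projection > 0,
            tube_voltage > 0)
  structure(list(scout_mAs = scout_mAs, dose_ratio = dose_ratio,
                 min_mAs_per_projection = min_mAs_per_projection,
                 tube_voltage = tube_voltage),
            class = "exposure_settings")
}

# R10 preferred-number mantissas.
.renard_r10 <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)

#' Round down to the closest Renard (R10) preferred-number step
#'
#' Maps `x` to the largest value of the R10 series
#' (..., 0.25, 0.32, 0.40, 0.50, 0.63, 0.80, 1.0, 1.25, ...) not
#' exceeding `x`.
#' @param x Positive numeric.
#' @return The R10 step, same length as `x`.
#' @export
#' @examples
#' renard_round_down(0.4167)  # 0.40
renard_round_down <- function(x) {
  stopifnot(all(x > 0))
  vapply(x, function(v) {
    k <- floor(log10(v) + 1e-12)
    m <- v / 10^k
    if (m < 1) { k <- k - 1; m <- v / 10^k }
    cand <- .renard_r10[.renard_r10 <= m * (1 + 1e-9)]
    if (length(cand) == 0) cand <- .renard_r10[length(.renard_r10)] / 10
    max(cand) * 10^k
  }, numeric(1))
}

#' Per-projection tube load
#'
#' The scout tube load times the dose ratio gives the total sweep load; it
#' is distributed evenly over the projections, quantised down to the
#' closest Renard R10 step, and clamped to the minimum per-projection load.
#' The order of quantisation and division is configurable because the
#' clinical description admits both readings; the default quantises the
#' per-projection value.
#'
#' @param e An [exposure_settings()].
#' @param n_projections Number of projections.
#' @param order `"divide_then_round"` (default) or `"round_then_divide"`.
#' @return Tube load per projection, mAs.
#' @export
#' @examples
#' per_projection_tube_load(exposure_settings(2.5), 60)  # 0.40
#' per_projection_tube_load(exposure_settings(0.5), 60)  # clamped to 0.25
per_projection_tube_load <- function(e, n_projections,
                                     order = c("divide_then_round",
                                               "round_then_divide")) {
  stopifnot(inherits(e, "exposure_settings"), n_projections >= 1)
  order <- match.arg(order)
  total <- e$scout_mAs * e$dose_ratio
  per <- switch(order,
    divide_then_round = renard_round_down(total / n_projections),
    round_then_divide = renard_round_down(total) / n_projections)
  max(e$min_mAs_per_projection, per)
}

#' Raw projection stack
#'
#' @param pixels 3-D numeric array (rows, cols, n_projections) of raw
#'   pixel values, nonnegative, linear in detected exposure.
#' @param geometry A [system_geometry()] consistent with the array.
#' @param mAs_per_projection Tube load per projection, mAs.
#' @param dose_fraction Relative dose, 1 for an original acquisition.
#' @return An object of class `"projection_set"` carrying the pixels,
#'   per-projection angles and focal spots, and acquisition metadata.
#' @export
projection_set <- function(pixels, geometry, mAs_per_projection = NA_real_,
                           dose_fraction = 1) {
  stopifnot(inherits(geometry, "system_geometry"),
            length(dim(pixels)) == 3,
            dim(pixels)[3] == geometry$n_projections,
            dose_fraction > 0, dose_fraction <= 1)
  if (min(pixels) < 0) stop("raw projection pixels must be nonnegative")
  structure(list(pixels = pixels, geometry = geometry,
                 angles = projection_angles(geometry),
                 focal_spots = focal_spot_positions(geometry),
                 mAs_per_projection = mAs_per_projection,
                 dose_fraction = dose_fraction),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<projection_set> %d projections of %d x %d px, +-%g deg, dose fraction %.3g\n",
    d[3], d[1], d[2], x$geometry$half_angle, x$dose_fraction))
  invisible(x)
}

# Detector coordinate maps (1-based indices; row 1 = top = largest y).
detector_x <- function(g, cols = seq_len(g$detector_size[2])) {
  (cols - 0.5) * g$pixel_pitch - g$detector_size[2] * g$pixel_pitch / 2
}
detector_y <- function(g, rows = seq_len(g$detector_size[1])) {
  g$detector_size[1] * g$pixel_pitch / 2 - (rows - 0.5) * g$pixel_pitch
}
# Inverse maps: patient-frame detector coordinates -> fractional indices.
detector_col <- function(g, x) {
  (x + g$detector_size[2] * g$pixel_pitch / 2) / g$pixel_pitch + 0.5
}
detector_row <- function(g, y) {
  (g$detector_size[1] * g$pixel_pitch / 2 - y) / g$pixel_pitch + 0.5
}

#' Nodule attenuation factor along a ray
#'
#' The nodule replaces lung tissue, so the effective attenuation
#' coefficient is the difference `mu_nodule - mu_lung`; the factor is
#' `exp(-(mu_nodule - mu_lung) * path_length / 10)` (coefficients in
#' cm^-1, path in mm).
#'
#' @param mu_nodule Nodule linear attenuation coefficient, cm^-1.
#' @param mu_lung Lung-tissue linear attenuation coefficient, cm^-1.
#' @param path_length Chord length through the nodule, mm (>= 0).
#' @return Multiplicative factor on the primary signal, <= 1 when
#'   `mu_nodule >= mu_lung`.
#' @export
attenuation_factor <- function(mu_nodule, mu_lung, path_length) {
  if (any(path_length < 0)) stop("path_length must be nonnegative")
  exp(-(mu_nodule - mu_lung) * path_length / 10)
}

#' Insertion configuration
#'
#' @param mu_lung Lung attenuation coefficient, cm^-1 (default 0.03).
#' @param mtf_model Detector MTF applied to the inserted signal:
#'   `NULL` for none, `list(type = "gaussian", sigma = <mm>)` (default
#'   sigma 0.25 mm), or `list(type = "tabulated", f, mtf)`.
#' @param spr Scatter-to-primary ratio; the inserted contrast is scaled by
#'   `1 / (1 + spr)`. Scalar, or one value per projection.
#' @param seed Integer seed for the per-projection motion shifts.
#' @return An object of class `"insertion_config"`.
#' @export
insertion_config <- function(mu_lung = 0.03,
                             mtf_model = list(type = "gaussian", sigma = 0.25),
                             spr = 0.4, seed = 1L) {
  stopifnot(mu_lung >= 0, all(spr >= 0))
  structure(list(mu_lung = mu_lung, mtf_model = mtf_model, spr = spr,
                 seed = as.integer(seed)),
            class = "insertion_config")
}

# Draw one motion displacement: direction uniform on the 3-D sphere,
# magnitude |N(0, sd^2)| (half-normal).
motion_shift <- function(sd) {
  if (sd <= 0) return(c(0, 0, 0))
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  abs(stats::rnorm(1, 0, sd)) * v
}

#' Insert an ellipsoid nodule into a raw projection stack
#'
#' For each projection the nodule centre receives a seeded random motion
#' displacement, rays are traced from the focal spot to every pixel in a
#' window around the projected nodule, the multiplicative attenuation
#' factor is applied to form the signal increment
#' `dP = P * (A - 1)`, the increment is blurred with the detector MTF,
#' scaled by `1 / (1 + spr)` for scatter contrast loss, and added back.
#' Pixels outside the blurred footprint are untouched.
#'
#' @param p A [projection_set()].
#' @param e An [ellipsoid()] whose centre lies between source and detector.
#' @param cfg An [insertion_config()].
#' @return A new [projection_set()] with the nodule present.
#' @export
insert_nodule <- function(p, e, cfg = insertion_config()) {
  stopifnot(inherits(p, "projection_set"), inherits(e, "ellipsoid"),
            inherits(cfg, "insertion_config"))
  g <- p$geometry
  if (e$center[3] <= 0 || e$center[3] >= g$sid) {
    stop("nodule centre must lie between the detector plane and the source")
  }
  spr <- rep(cfg$spr, length.out = g$n_projections)
  blur_sigma <- if (!is.null(cfg$mtf_model) &&
                    identical(cfg$mtf_model$type %||% "gaussian", "gaussian"))
    cfg$mtf_model$sigma else if (is.null(cfg$mtf_model)) 0 else 0.5
  shifts <- with_seed(derive_seed(cfg$seed, "motion", e$id), {
    t(vapply(seq_len(g$n_projections), function(i) motion_shift(e$sd_motion),
             numeric(3)))
  })
  out <- p$pixels
  for (i in seq_len(g$n_projections)) {
    f <- p$focal_spots[i, ]
    ctr <- e$center + shifts[i, ]
    ei <- e
    ei$center <- ctr
    # projected centre on the detector plane
    t0 <- g$sid / (g$sid - ctr[3])
    pd <- f + (ctr - f) * t0
    half_mm <- e$major_axis / 2 * t0 + 4 * blur_sigma + 8 * g$pixel_pitch
    rows <- floor(detector_row(g, pd[2] + half_mm)):
            ceiling(detector_row(g, pd[2] - half_mm))
    cols <- floor(detector_col(g, pd[1] - half_mm)):
            ceiling(detector_col(g, pd[1] + half_mm))
    rows_in <- rows[rows >= 1 & rows <= g$detector_size[1]]
    cols_in <- cols[cols >= 1 & cols <= g$detector_size[2]]
    if (length(rows_in) == 0 || length(cols_in) == 0) {
      stop(sprintf("nodule %s is outside the field of view in projection %d",
                   e$id, i))
    }
    xs <- detector_x(g, cols_in)
    ys <- detector_y(g, rows_in)
    nr <- length(rows_in); nc <- length(cols_in)
    dirs <- cbind(rep(xs, each = nr) - f[1],
                  rep(ys, times = nc) - f[2],
                  -f[3])
    dirs <- dirs / sqrt(rowSums(dirs^2))
    chords <- chord_length(ei, f, dirs)
    A <- attenuation_factor(e$mu, cfg$mu_lung, chords)
    dP <- matrix(0, nr, nc)
    dP[] <- out[rows_in, cols_in, i] * (A - 1)
    dP <- apply_mtf(dP, cfg$mtf_model, g$pixel_pitch)
    out[rows_in, cols_in, i] <- out[rows_in, cols_in, i] +
      dP / (1 + spr[i])
  }
  p$pixels <- out
  p
}
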