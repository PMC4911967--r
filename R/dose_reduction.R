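# Simulated dose reduction: add NPS-shaped, DQE-corrected noise to scaled
# raw projections so the result has the noise of a genuinely lower-dose
# acquisition.
#
# Flat-field calibration supplies (a) the pixel-value/variance relationship
# across dose levels (the DQE correction: at the low doses of tomosynthesis
# projections, variance is not proportional to pixel value because the
# dose-independent electronic noise gains weight) and (b) the 2-D noise
# power spectrum per level (the spectral shape of the added noise).

#' Estimate the 2-D noise power spectrum of a flat-field image
#'
#' Mean detrended periodogram over half-overlapping square ROIs. Each ROI
#' is detrended with a second-order 2-D polynomial before the DFT. The
#' normalisation is chosen so that the sum of the NPS over frequency bins
#' times the frequency-bin area equals the image variance times the pixel
#' area (Parseval).
#'
#' @param flat_field Numeric matrix of raw pixel values.
#' @param pixel_pitch Pixel pitch, mm.
#' @param roi_size ROI side in pixels (a power of two).
#' @return An object of class `"nps_estimate"`: the `roi_size` x
#'   `roi_size` NPS matrix (DFT bin order), its frequency axes
#'   (cycles/mm), the pitch and the number of ROIs averaged.
#' @export
estimate_nps <- function(flat_field, pixel_pitch, roi_size = 128L) {
  stopifnot(is.matrix(flat_field), pixel_pitch > 0)
  roi_size <- as.integer(roi_size)
  if (bitwAnd(roi_size, roi_size - 1L) != 0L || roi_size < 4L) {
    stop("roi_size must be a power of two")
  }
  if (nrow(flat_field) < roi_size || ncol(flat_field) < roi_size) {
    stop("image smaller than roi_size")
  }
  step <- roi_size %/% 2L
  r0 <- seq(1L, nrow(flat_field) - roi_size + 1L, by = step)
  c0 <- seq(1L, ncol(flat_field) - roi_size + 1L, by = step)
  if (length(r0) * length(c0) < 4L) {
    stop("fewer than 4 ROIs available; use a larger image or smaller ROI")
  }
  # second-order polynomial detrending basis, shared across ROIs
  u <- seq(-1, 1, length.out = roi_size)
  X <- cbind(1, rep(u, times = roi_size), rep(u, each = roi_size))
  X <- cbind(X, X[, 2]^2, X[, 3]^2, X[, 2] * X[, 3])
  Q <- qr.Q(qr(X))
  acc <- matrix(0, roi_size, roi_size)
  n_roi <- 0L
  for (i in r0) for (j in c0) {
    roi <- flat_field[i:(i + roi_size - 1L), j:(j + roi_size - 1L)]
    v <- as.vector(roi)
    v <- v - Q %*% crossprod(Q, v)
    acc <- acc + Mod(stats::fft(matrix(v, roi_size, roi_size)))^2
    n_roi <- n_roi + 1L
  }
  nps <- acc / n_roi * pixel_pitch^4 / roi_size^2
  structure(list(nps = nps,
                 f_row = fft_freq(roi_size, pixel_pitch),
                 f_col = fft_freq(roi_size, pixel_pitch),
                 pixel_pitch = pixel_pitch, roi_size = roi_size,
                 n_roi = n_roi),
            class = "nps_estimate")
}

#' Integral of an NPS over frequency
#'
#' Equals image variance times pixel area for a well-normalised estimate.
#' @param x An [estimate_nps()] result.
#' @return Scalar, (raw units)^2 mm^2.
#' @export
nps_integral <- function(x) {
  stopifnot(inherits(x, "nps_estimate"))
  sum(x$nps) / (x$roi_size * x$pixel_pitch)^2
}

#' Radially averaged NPS
#'
#' @param x An [estimate_nps()] result.
#' @param n_bins Number of radial frequency bins up to Nyquist.
#' @return Data frame with bin-centre frequency (cycles/mm) and mean NPS.
#' @export
radial_nps <- function(x, n_bins = 32L) {
  stopifnot(inherits(x, "nps_estimate"))
  r <- freq_radius(x$roi_size, x$roi_size, x$pixel_pitch)
  f_nyq <- 1 / (2 * x$pixel_pitch)
  keep <- r > 0 & r <= f_nyq
  bins <- cut(r[keep], breaks = seq(0, f_nyq, length.out = n_bins + 1L))
  data.frame(
    freq = tapply(r[keep], bins, mean),
    nps = tapply(x$nps[keep], bins, mean))
}

#' Fit the pixel-value/variance relationship of a detector
#'
#' Pools per-level flat-field means and variances into a monotone
#' piecewise-linear mapping pixel value -> variance (constant
#' extrapolation beyond the calibrated range). For a quantum-plus-
#' electronic detector the true relationship is affine in the mean, so the
#' interpolant is exact up to estimation noise.
#'
#' @param stats Data frame with columns `mean` and `variance`, one row per
#'   calibrated dose level (>= 3 levels), or a [generate_flat_fields()]
#'   result.
#' @return An object of class `"variance_curve"` with the knots and an
#'   interpolating function.
#' @export
fit_variance_curve <- function(stats) {
  if (inherits(stats, "flat_field_set")) stats <- flat_field_stats(stats)
  stopifnot(is.data.frame(stats), all(c("mean", "variance") %in% names(stats)))
  if (nrow(stats) < 3) stop("at least 3 dose levels are required")
  o <- order(stats$mean)
  m <- stats$mean[o]; v <- stats$variance[o]
  if (any(diff(m) <= 0)) stop("per-level mean pixel values must be strictly increasing")
  if (any(diff(v) <= 0)) stop("per-level variances must be strictly increasing")
  structure(list(knots = data.frame(mean = m, variance = v),
                 fun = stats::approxfun(m, v, rule = 2)),
            class = "variance_curve")
}

#' @export
#' @param object A `"variance_curve"`.
#' @param newdata Pixel values at which to evaluate the curve.
#' @param ... Unused.
#' @rdname fit_variance_curve
predict.variance_curve <- function(object, newdata, ...) {
  object$fun(newdata)
}

#' Flat-field calibration for dose-reduction simulation
#'
#' Bundles per-level mean pixel value, variance and NPS with the fitted
#' variance curve. The synthetic detector model is stationary across
#' projection angles, so a single calibration set serves every angle; a
#' per-angle calibration (list of such objects) can be supplied for
#' detectors where that does not hold.
#'
#' @param flats A [generate_flat_fields()] result.
#' @param roi_size NPS ROI side, pixels.
#' @return An object of class `"flat_field_calibration"`.
#' @export
flat_field_calibration <- function(flats, roi_size = 128L) {
  stopifnot(inherits(flats, "flat_field_set"))
  st <- flat_field_stats(flats)
  lev <- st$level
  nps <- vector("list", length(lev))
  for (k in seq_along(lev)) {
    idx <- which(flats$levels == lev[k])
    acc <- NULL
    for (i in idx) {
      e <- estimate_nps(flats$images[[i]], flats$pixel_pitch, roi_size)
      acc <- if (is.null(acc)) e else { acc$nps <- acc$nps + e$nps; acc }
    }
    acc$nps <- acc$nps / length(idx)
    nps[[k]] <- acc
  }
  structure(list(dose_levels = lev, mean_value = st$mean,
                 variance = st$variance, nps = nps,
                 variance_curve = fit_variance_curve(st),
                 pixel_pitch = flats$pixel_pitch),
            class = "flat_field_calibration")
}

# Bilinear resampling of a DFT-ordered NPS onto the spectrum grid of an
# nr x nc image with the same pixel pitch.
nps_resample <- function(nps_est, nr, nc) {
  n <- nps_est$roi_size
  sh <- function(m) m[c((n / 2 + 1):n, 1:(n / 2)), c((n / 2 + 1):n, 1:(n / 2))]
  S <- sh(nps_est$nps)
  f_in <- sort(fft_freq(n, nps_est$pixel_pitch))
  interp_axis <- function(f_out) {
    i <- findInterval(f_out, f_in, all.inside = TRUE)
    w <- (f_out - f_in[i]) / (f_in[i + 1] - f_in[i])
    w <- pmin(pmax(w, 0), 1)
    list(i = i, w = w)
  }
  fr <- sort(fft_freq(nr, nps_est$pixel_pitch))
  fc <- sort(fft_freq(nc, nps_est$pixel_pitch))
  ar <- interp_axis(fr); ac <- interp_axis(fc)
  out <- (1 - ar$w) * ((1 - rep(ac$w, each = nr)) * S[ar$i, ac$i] +
                       rep(ac$w, each = nr) * S[ar$i, ac$i + 1]) +
         ar$w * ((1 - rep(ac$w, each = nr)) * S[ar$i + 1, ac$i] +
                 rep(ac$w, each = nr) * S[ar$i + 1, ac$i + 1])
  out <- matrix(out, nr, nc)
  # back to DFT bin order
  ro <- order(order(fft_freq(nr, nps_est$pixel_pitch)))
  co <- order(order(fft_freq(nc, nps_est$pixel_pitch)))
  out[ro, co, drop = FALSE]
}

#' Synthesise the dose-reduction noise image
#'
#' White Gaussian noise is shaped in the Fourier domain by
#' `sqrt(max(0, W_low - s^2 * W_high))`, the NPS difference between the
#' flat fields matched to the scaled and the original radiograph; after
#' inverse transformation the field is rescaled per pixel so its local
#' variance equals `variance_curve(s * pixel) - s^2 * variance_curve(pixel)`,
#' which carries the DQE corrections into regions of differing exposure.
#'
#' @param shape Length-2 integer (rows, cols).
#' @param nps_low,nps_high [estimate_nps()] results (or matrices already on
#'   the image spectrum grid) for the flat fields matched to the scaled and
#'   the original radiograph.
#' @param s Target dose fraction in (0, 1].
#' @param variance_curve A [fit_variance_curve()] result.
#' @param pixel_map The original radiograph (raw values), same shape.
#' @param seed Integer seed.
#' @return Zero-mean noise image of dimension `shape`.
#' @export
make_noise_image <- function(shape, nps_low, nps_high, s, variance_curve,
                             pixel_map, seed) {
  stopifnot(length(shape) == 2, s > 0, s <= 1,
            inherits(variance_curve, "variance_curve"),
            all(dim(pixel_map) == shape))
  nr <- shape[1]; nc <- shape[2]
  as_spec <- function(x) {
    if (inherits(x, "nps_estimate")) nps_resample(x, nr, nc)
    else { stopifnot(all(dim(x) == shape)); x }
  }
  W_low <- as_spec(nps_low)
  W_high <- as_spec(nps_high)
  W_diff <- W_low - s^2 * W_high
  n_neg <- sum(W_diff < 0)
  if (n_neg > 0.5 * length(W_diff)) {
    stop("NPS difference negative over more than half of the frequencies; ",
         "calibration is inconsistent with the requested dose fraction")
  }
  if (n_neg > 0.01 * length(W_diff)) {
    message(sprintf("make_noise_image: clamped %d negative NPS-difference bins",
                    n_neg))
  }
  W_diff <- pmax(W_diff, 0)
  mean_power <- mean(W_diff)
  if (mean_power <= 0) return(matrix(0, nr, nc))
  white <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  shaped <- Re(stats::fft(stats::fft(white) * sqrt(W_diff),
                          inverse = TRUE)) / (nr * nc)
  shaped <- shaped / sqrt(mean_power)  # unit-variance field, NPS shape kept
  target_var <- pmax(0, predict(variance_curve, s * pixel_map) -
                        s^2 * predict(variance_curve, pixel_map))
  shaped * sqrt(target_var)
}

#' Dose-reduction plan: flat-field levels matched to one projection
#'
#' @param cal A [flat_field_calibration()].
#' @param mean_pixel_value Mean raw value of the projection.
#' @param s Target dose fraction.
#' @return List with the indices of the calibration levels closest in mean
#'   pixel value to the original and to the scaled radiograph.
#' @export
match_calibration_levels <- function(cal, mean_pixel_value, s) {
  stopifnot(inherits(cal, "flat_field_calibration"))
  list(matched_high = which.min(abs(cal$mean_value - mean_pixel_value)),
       matched_low = which.min(abs(cal$mean_value - s * mean_pixel_value)))
}

#' Simulate acquisition at a lower dose
#'
#' Scales every raw projection by the dose fraction `s` and adds a
#' [make_noise_image()] noise field built from the calibration levels
#' matched to that projection, so the output has the noise magnitude and
#' spectrum of an acquisition at `s` times the dose.
#'
#' @param p A [projection_set()].
#' @param s Dose fraction in (0, 1]; `s = 1` returns the input unchanged.
#' @param cal A [flat_field_calibration()], or a list of them with an
#'   `angles` attribute for per-angle calibration.
#' @param seed Integer seed; each projection uses a derived sub-seed.
#' @return A new [projection_set()] with `dose_fraction` multiplied by `s`.
#' @export
simulate_dose_reduction <- function(p, s, cal, seed) {
  stopifnot(inherits(p, "projection_set"), s > 0, s <= 1)
  if (s == 1) return(p)
  per_angle <- !inherits(cal, "flat_field_calibration")
  if (per_angle) {
    cal_angles <- attr(cal, "angles")
    if (is.null(cal_angles) || !all(vapply(cal, inherits, TRUE,
                                          "flat_field_calibration"))) {
      stop("cal must be a flat_field_calibration or a list of them with an ",
           "'angles' attribute")
    }
    if (max(abs(p$angles)) > max(abs(cal_angles)) + 1e-6) {
      stop("calibration does not cover the projection angles")
    }
  }
  out <- p$pixels
  nr <- dim(out)[1]; nc <- dim(out)[2]
  for (i in seq_len(dim(out)[3])) {
    ci <- if (per_angle) cal[[which.min(abs(cal_angles - p$angles[i]))]] else cal
    m <- mean(out[, , i])
    lv <- match_calibration_levels(ci, m, s)
    noise <- make_noise_image(
      c(nr, nc), ci$nps[[lv$matched_low]], ci$nps[[lv$matched_high]], s,
      ci$variance_curve, out[, , i], derive_seed(seed, "dose-noise", i))
    out[, , i] <- s * out[, , i] + noise
  }
  p$pixels <- pmax(out, 0)
  p$dose_fraction <- p$dose_fraction * s
  p$dose_reduction <- list(s = s, seed = seed)
  p
}
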