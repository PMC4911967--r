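# Limited-angle reconstruction: filtered shift-and-add back-projection of
# the projection stack onto coronal planes at fixed depths.
#
# For a plane at depth z from the detector, material at that depth appears
# in projection i displaced vertically by -(sid*tan(theta_i)) * z/(sid-z)
# and magnified by M = sid/(sid-z). Each projection is therefore resampled
# onto an object-plane grid (undoing shift and magnification, separable
# cubic interpolation with reflected edges), filtered along the tube-motion
# axis with an apodised ramp, and averaged.

#' Reconstruction filter specification
#'
#' @param type `"hann-ramp"` (ramp `|f|` apodised by a Hann window up to
#'   Nyquist; the standard limited-angle tomosynthesis choice) or
#'   `"identity"` (plain shift-and-add).
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(type = c("hann-ramp", "identity")) {
  structure(list(type = match.arg(type)), class = "filter_spec")
}

# 1-D filter transfer function on the DFT frequency grid.
filter_transfer <- function(fs, f, pitch) {
  f_nyq <- 1 / (2 * pitch)
  switch(fs$type,
    identity = rep(1, length(f)),
    "hann-ramp" = {
      h <- abs(f) / f_nyq * 0.5 * (1 + cos(pi * f / f_nyq))
      # renormalise so the mean passband gain is 1 (keeps contrast scale)
      h / mean(h)
    })
}

#' Coronal section stack
#'
#' @param sections 3-D array (rows, cols, n_depths), object-plane pixels.
#' @param depths Strictly increasing depths from the detector plane, mm.
#' @param pixel_pitch Object-plane pixel pitch, mm.
#' @param provenance Free-form metadata (source projection-set info).
#' @return An object of class `"section_stack"`.
#' @export
section_stack <- function(sections, depths, pixel_pitch, provenance = NULL) {
  stopifnot(length(dim(sections)) == 3, dim(sections)[3] == length(depths),
            length(depths) >= 1, pixel_pitch > 0)
  if (length(depths) > 1 && any(diff(depths) <= 0)) {
    stop("depths must be strictly increasing")
  }
  spacing <- if (length(depths) > 1) diff(depths)[1] else NA_real_
  structure(list(sections = sections, depths = depths, spacing = spacing,
                 pixel_pitch = pixel_pitch, provenance = provenance),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d sections of %d x %d px, depths %.1f..%.1f mm\n",
              length(x$depths), dim(x$sections)[1], dim(x$sections)[2],
              min(x$depths), max(x$depths)))
  invisible(x)
}

#' Reconstruct coronal sections by filtered shift-and-add
#'
#' @param p A [projection_set()].
#' @param depths Depths of the section planes, mm, inside `(0, sid)`.
#' @param filter A [filter_spec()] (default Hann-apodised ramp).
#' @param normalize_magnification If `TRUE` (default) sections are on an
#'   object-plane grid (true millimetres at depth `z`); if `FALSE` plain
#'   vertical shift-and-add in detector coordinates.
#' @return A [section_stack()].
#' @export
reconstruct <- function(p, depths, filter = filter_spec("hann-ramp"),
                        normalize_magnification = TRUE) {
  stopifnot(inherits(p, "projection_set"), inherits(filter, "filter_spec"))
  g <- p$geometry
  if (any(depths <= 0 | depths >= g$sid)) {
    stop("section depths must lie strictly between the detector and the source")
  }
  nr <- dim(p$pixels)[1]; nc <- dim(p$pixels)[2]
  x_obj <- detector_x(g, seq_len(nc))
  y_obj <- detector_y(g, seq_len(nr))
  h <- filter_transfer(filter, fft_freq(nr, g$pixel_pitch), g$pixel_pitch)
  out <- array(0, dim = c(nr, nc, length(depths)))
  for (k in seq_along(depths)) {
    z <- depths[k]
    M <- if (normalize_magnification) g$sid / (g$sid - z) else 1
    acc <- matrix(0, nr, nc)
    Wc <- resample_operator(detector_col(g, M * x_obj), nc)
    for (i in seq_len(g$n_projections)) {
      tn <- tan(p$angles[i] * pi / 180)
      y_det <- if (normalize_magnification) M * (y_obj - z * tn) else
        y_obj - g$sid * tn * z / (g$sid - z)
      Wr <- resample_operator(detector_row(g, y_det), nr)
      acc <- acc + Wr %*% p$pixels[, , i] %*% t(Wc)
    }
    acc <- acc / g$n_projections
    if (filter$type != "identity") {
      acc <- Re(stats::mvfft(stats::mvfft(acc) * h, inverse = TRUE)) / nr
    }
    out[, , k] <- acc
  }
  section_stack(out, depths, g$pixel_pitch,
                provenance = list(dose_fraction = p$dose_fraction,
                                  mAs_per_projection = p$mAs_per_projection,
                                  n_projections = g$n_projections))
}

#' Sharpness of a region across the section stack
#'
#' Sum of squared vertical (tube-motion direction) gradients in a square
#' window; out-of-focus structures are smeared vertically, so the in-focus
#' section maximises this functional.
#'
#' @param s A [section_stack()].
#' @param center_px Length-2 (row, col) of the window centre, pixels.
#' @param half_window Window half-size, pixels.
#' @return Numeric vector, one value per section.
#' @export
sharpness_profile <- function(s, center_px, half_window = 10L) {
  stopifnot(inherits(s, "section_stack"))
  nr <- dim(s$sections)[1]; nc <- dim(s$sections)[2]
  rows <- max(1, center_px[1] - half_window):min(nr, center_px[1] + half_window)
  cols <- max(1, center_px[2] - half_window):min(nc, center_px[2] + half_window)
  vapply(seq_along(s$depths), function(k) {
    w <- s$sections[rows, cols, k]
    sum(diff(w)^2)
  }, numeric(1))
}

#' Index of the in-focus section for a region
#' @inheritParams sharpness_profile
#' @return Integer section index maximising [sharpness_profile()] (ties to
#'   the lower index).
#' @export
in_focus_section <- function(s, center_px, half_window = 10L) {
  which.max(sharpness_profile(s, center_px, half_window))
}

#' Extract the case presentation window around a nodule
#'
#' Returns `n_sections` consecutive sections with the nodule's in-focus
#' section (the one nearest its centre depth) at a central position, and a
#' circular ROI annotation centred on the projected nodule centre. At the
#' stack edges the window is shifted inwards (with a message) so it stays
#' complete.
#'
#' @param s A [section_stack()].
#' @param nodule An [ellipsoid()].
#' @param n_sections Window length (default 10).
#' @param roi_radius ROI radius, mm; equal for every nodule by design.
#' @return A [section_stack()] of `n_sections` sections whose `provenance`
#'   carries `focus_index` (within the window), `roi_center_px` and
#'   `roi_radius_mm`.
#' @export
extract_case_window <- function(s, nodule, n_sections = 10L,
                                roi_radius = 15) {
  stopifnot(inherits(s, "section_stack"), inherits(nodule, "ellipsoid"))
  n <- length(s$depths)
  if (n < n_sections) stop("stack has fewer sections than the window")
  z <- nodule$center[3]
  if (z < min(s$depths) - (s$spacing %||% 0) ||
      z > max(s$depths) + (s$spacing %||% 0)) {
    stop("nodule depth outside the stack range")
  }
  focus <- which.min(abs(s$depths - z))
  # central position: index 5 of 10 (the nodule in focus in one of the
  # central images)
  central <- ceiling(n_sections / 2)
  start <- focus - central + 1L
  if (start < 1L || start + n_sections - 1L > n) {
    start <- min(max(start, 1L), n - n_sections + 1L)
    message("extract_case_window: window shifted to stay inside the stack")
  }
  idx <- start:(start + n_sections - 1L)
  g_row <- detector_row_from_pitch(s, nodule$center[2])
  g_col <- detector_col_from_pitch(s, nodule$center[1])
  section_stack(s$sections[, , idx, drop = FALSE], s$depths[idx],
                s$pixel_pitch,
                provenance = c(s$provenance,
                               list(focus_index = focus - start + 1L,
                                    roi_center_px = c(round(g_row), round(g_col)),
                                    roi_radius_mm = roi_radius)))
}

# Object-plane coordinate maps for a section stack (same convention as the
# detector: row 1 = top).
detector_row_from_pitch <- function(s, y) {
  nr <- dim(s$sections)[1]
  (nr * s$pixel_pitch / 2 - y) / s$pixel_pitch + 0.5
}
detector_col_from_pitch <- function(s, x) {
  nc <- dim(s$sections)[2]
  (x + nc * s$pixel_pitch / 2) / s$pixel_pitch + 0.5
}

#' Measure a nodule diameter on a section by full width at half contrast
#'
#' Samples the section along the major-axis direction through the nodule
#' centre (cubic interpolation), takes the contrast as the signal deficit
#' relative to the profile baseline (median of the outer quarters), and
#' returns the distance between the half-maximum crossings bracketing the
#' peak (linear interpolation at the crossings).
#'
#' @param s A [section_stack()] (one of its sections).
#' @param section_index Which section to measure on.
#' @param nodule The [ellipsoid()] (centre and orientation define the
#'   profile line).
#' @param profile_half_length Half-length of the sampled profile, mm.
#' @param step Sampling step along the profile, mm.
#' @return Measured diameter, mm (NA if no half-contrast crossing exists).
#' @export
measure_diameter_fwhc <- function(s, section_index, nodule,
                                  profile_half_length = NULL, step = 0.05) {
  stopifnot(inherits(s, "section_stack"), inherits(nodule, "ellipsoid"))
  if (is.null(profile_half_length)) profile_half_length <- nodule$major_axis
  th <- nodule$theta * pi / 180
  u <- seq(-profile_half_length, profile_half_length, by = step)
  xs <- nodule$center[1] + u * cos(th)
  ys <- nodule$center[2] + u * sin(th)
  img <- s$sections[, , section_index]
  rows <- detector_row_from_pitch(s, ys)
  cols <- detector_col_from_pitch(s, xs)
  # non-separable path: interpolate columns first, then pick per-sample rows
  prof <- vapply(seq_along(u), function(i) {
    Wr <- resample_operator(rows[i], nrow(img))
    Wc <- resample_operator(cols[i], ncol(img))
    as.numeric(Wr %*% img %*% t(Wc))
  }, numeric(1))
  n <- length(prof)
  tails <- c(prof[seq_len(floor(n / 4))], prof[(n - floor(n / 4) + 1):n])
  baseline <- stats::median(tails)
  contrast <- baseline - prof  # nodule is a signal deficit
  pk <- which.max(contrast)
  half <- contrast[pk] / 2
  if (contrast[pk] <= 0) return(NA_real_)
  left <- NA_real_; right <- NA_real_
  for (i in pk:2) {
    if (contrast[i - 1] < half && contrast[i] >= half) {
      frac <- (half - contrast[i - 1]) / (contrast[i] - contrast[i - 1])
      left <- u[i - 1] + frac * step
      break
    }
  }
  for (i in pk:(n - 1)) {
    if (contrast[i + 1] < half && contrast[i] >= half) {
      frac <- (half - contrast[i + 1]) / (contrast[i] - contrast[i + 1])
      right <- u[i + 1] - frac * step
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}
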