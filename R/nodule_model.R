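# Ellipsoid nodule population: geometry, generation, ray-chord queries.
#
# Nodules are homogeneous ellipsoids with two equal minor axes. Size is
# controlled by the volume-equivalent sphere diameter d_eq and the
# major/minor axis-length ratio; the major axis lies in the coronal (x-y)
# plane, rotated by theta from the lateral (x) axis. Coordinates are
# patient-frame millimetres: x lateral, y vertical (cranio-caudal, the
# tube-motion direction), z posteroanterior depth from the detector plane.

#' Major-axis length of a volume-preserving ellipsoid
#'
#' For an ellipsoid with two equal minor axes whose volume equals that of a
#' sphere of diameter `d_eq`, the full axis lengths are
#' `major = d_eq * ratio^(2/3)` and `minor = d_eq * ratio^(-1/3)`, so that
#' `major * minor^2 = d_eq^3` exactly.
#'
#' @param d_eq Volume-equivalent sphere diameter, mm (> 0).
#' @param ratio Major/minor axis-length ratio (>= 1).
#' @return Major-axis full length, mm.
#' @seealso [minor_axis_length()], [ellipsoid()]
#' @export
#' @examples
#' major_axis_length(4, 1.1)   # ~4.26 mm
#' major_axis_length(12, 1.5)  # ~15.72 mm
major_axis_length <- function(d_eq, ratio) {
  stopifnot(all(d_eq > 0))
  if (any(ratio < 1)) {
    stop("axis ratio must be >= 1 (the minor axis may not exceed the major)")
  }
  d_eq * ratio^(2 / 3)
}

#' Minor-axis length of a volume-preserving ellipsoid
#' @inheritParams major_axis_length
#' @return Minor-axis full length, mm (both minor axes are equal).
#' @export
minor_axis_length <- function(d_eq, ratio) {
  stopifnot(all(d_eq > 0))
  if (any(ratio < 1)) {
    stop("axis ratio must be >= 1 (the minor axis may not exceed the major)")
  }
  d_eq * ratio^(-1 / 3)
}

#' Construct an ellipsoid nodule
#'
#' @param id Character identifier.
#' @param center Length-3 numeric, patient-frame position, mm.
#' @param d_eq Volume-equivalent diameter, mm.
#' @param ratio Major/minor axis-length ratio (>= 1).
#' @param theta In-plane rotation of the major axis within the coronal
#'   plane, degrees from the lateral (x) axis towards the vertical (y) axis.
#' @param mu Linear attenuation coefficient, cm^-1 (default 0.16, a typical
#'   solid-nodule value at chest-tomosynthesis beam quality).
#' @param sd_motion Standard deviation of the per-projection positional
#'   shift modelling patient motion blur, mm.
#' @return An object of class `"ellipsoid"`.
#' @export
ellipsoid <- function(id, center, d_eq, ratio, theta = 0, mu = 0.16,
                      sd_motion = 0) {
  stopifnot(length(center) == 3, is.numeric(center), d_eq > 0, mu > 0,
            sd_motion >= 0)
  structure(list(
    id = as.character(id), center = as.numeric(center), d_eq = d_eq,
    ratio = ratio,
    major_axis = major_axis_length(d_eq, ratio),
    minor_axis = minor_axis_length(d_eq, ratio),
    theta = theta, mu = mu, sd_motion = sd_motion
  ), class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid %s> d_eq %.2f mm, axes %.2f x %.2f mm, theta %.1f deg, mu %.2f /cm\n",
    x$id, x$d_eq, x$major_axis, x$minor_axis, x$theta, x$mu))
  invisible(x)
}

# Rotation matrix whose columns are the ellipsoid body axes in the patient
# frame: major axis in the coronal plane at `theta`, second minor axis
# perpendicular in-plane, third minor axis along depth (z).
ellipsoid_axes <- function(e) {
  th <- e$theta * pi / 180
  cbind(c(cos(th), sin(th), 0),
        c(-sin(th), cos(th), 0),
        c(0, 0, 1))
}

#' Specification of a nodule population
#'
#' Describes the factorial nodule set of the study: size groups (one per
#' `d_eq`), a fixed list of positions shared across groups, axis ratios
#' spread deterministically and uniformly over `ratio_range` within each
#' group, a per-position in-plane orientation shared across groups, and a
#' per-position motion-blur SD drawn from a truncated normal.
#'
#' @param d_eq_list Volume-equivalent diameters, mm (one size group each).
#' @param position_list Matrix (n x 3) or list of length-3 vectors, mm.
#' @param ratio_range Length-2 numeric, inclusive range of axis ratios.
#' @param sd_motion_mean Target mean motion SD, mm.
#' @param sd_motion_range Length-2 clipping range for the motion SD, mm.
#' @param mu Nodule attenuation coefficient, cm^-1.
#' @param seed Integer seed controlling orientation and motion-SD draws.
#' @return An object of class `"nodule_set_spec"`.
#' @export
nodule_set_spec <- function(d_eq_list = c(4, 8, 12),
                            position_list = default_nodule_positions(),
                            ratio_range = c(1.1, 1.5),
                            sd_motion_mean = 0.20,
                            sd_motion_range = c(0.13, 0.32),
                            mu = 0.16,
                            seed = 1L) {
  if (is.list(position_list)) {
    position_list <- do.call(rbind, position_list)
  }
  position_list <- as.matrix(position_list)
  stopifnot(ncol(position_list) == 3, nrow(position_list) >= 1,
            length(ratio_range) == 2, ratio_range[1] >= 1,
            ratio_range[2] >= ratio_range[1],
            sd_motion_range[1] <= sd_motion_mean,
            sd_motion_mean <= sd_motion_range[2])
  structure(list(
    d_eq_list = d_eq_list, position_list = position_list,
    n_positions = nrow(position_list),
    ratio_range = ratio_range, sd_motion_mean = sd_motion_mean,
    sd_motion_range = sd_motion_range, mu = mu, seed = as.integer(seed)
  ), class = "nodule_set_spec")
}

#' Default nodule positions
#'
#' The study placed nodules at 27 lung positions in high-dose areas of the
#' projection radiographs; the actual anatomical coordinates are not
#' published, so a deterministic 3 x 3 x 3 grid spanning a plausible lung
#' volume (x lateral +-120 mm, y vertical +-150 mm, z depth 80-160 mm from
#' the detector) stands in. Positions are configuration inputs and can be
#' replaced freely.
#'
#' @param n Number of positions (default 27).
#' @return An `n` x 3 matrix of patient-frame coordinates, mm.
#' @export
default_nodule_positions <- function(n = 27L) {
  g <- expand.grid(x = c(-120, 0, 120), y = c(-150, 0, 150),
                   z = c(80, 120, 160))
  m <- as.matrix(g)[rep(seq_len(27), length.out = n), , drop = FALSE]
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Generate the ellipsoid nodule population
#'
#' Within each size group the axis ratios are spaced deterministically and
#' uniformly over `ratio_range` (a single nodule takes the lower bound), so
#' the printed min/max major-axis lengths of a group are exact. The
#' in-plane orientation `theta` is drawn once per position, uniform on
#' [0, 180) degrees, and shared by the size groups, as is the per-position
#' motion SD (truncated normal with mean `sd_motion_mean`, clipped to
#' `sd_motion_range`). Nodules at the same position therefore correspond to
#' each other in shape and orientation across size groups.
#'
#' @param spec A [nodule_set_spec()].
#' @return List of [ellipsoid()] objects, length
#'   `length(d_eq_list) * n_positions`, ordered by size group then position.
#' @export
generate_nodule_set <- function(spec) {
  stopifnot(inherits(spec, "nodule_set_spec"))
  n_pos <- spec$n_positions
  ratios <- if (n_pos == 1L) spec$ratio_range[1] else
    seq(spec$ratio_range[1], spec$ratio_range[2], length.out = n_pos)
  draws <- with_seed(derive_seed(spec$seed, "nodule-set"), {
    theta <- stats::runif(n_pos, 0, 180)
    # truncated-normal motion SD: resample rejected draws, cap attempts
    sdm <- rep(NA_real_, n_pos)
    sigma <- diff(spec$sd_motion_range) / 4
    for (i in seq_len(n_pos)) {
      for (try in 1:100) {
        v <- stats::rnorm(1, spec$sd_motion_mean, sigma)
        if (v >= spec$sd_motion_range[1] && v <= spec$sd_motion_range[2]) {
          sdm[i] <- v
          break
        }
      }
      if (is.na(sdm[i])) sdm[i] <- spec$sd_motion_mean
    }
    list(theta = theta, sdm = sdm)
  })
  out <- vector("list", length(spec$d_eq_list) * n_pos)
  k <- 0L
  for (gi in seq_along(spec$d_eq_list)) {
    d <- spec$d_eq_list[gi]
    for (pi in seq_len(n_pos)) {
      k <- k + 1L
      out[[k]] <- ellipsoid(
        id = sprintf("g%d_p%02d", gi, pi),
        center = spec$position_list[pi, ],
        d_eq = d, ratio = ratios[pi],
        theta = draws$theta[pi], mu = spec$mu,
        sd_motion = draws$sdm[pi])
    }
  }
  out
}

#' Flatten a nodule list to a table
#'
#' @param nodules List of [ellipsoid()] objects.
#' @return Data frame with one row per nodule: id, center_x/y/z, d_eq,
#'   ratio, major_axis, minor_axis, theta, mu, sd_motion, size_group.
#' @export
nodule_table <- function(nodules) {
  if (inherits(nodules, "ellipsoid")) nodules <- list(nodules)
  df <- do.call(rbind, lapply(nodules, function(e) {
    data.frame(id = e$id, center_x = e$center[1], center_y = e$center[2],
               center_z = e$center[3], d_eq = e$d_eq, ratio = e$ratio,
               major_axis = e$major_axis, minor_axis = e$minor_axis,
               theta = e$theta, mu = e$mu, sd_motion = e$sd_motion)
  }))
  df$size_group <- factor(df$d_eq, levels = sort(unique(df$d_eq)),
                          labels = paste0(sort(unique(df$d_eq)), "mm"))
  df
}

#' Write / read a nodule table
#'
#' CSV is the flat interchange format; JSON mirrors the same records.
#' @param nodules List of ellipsoids or a [nodule_table()] data frame.
#' @param path Output file; extension selects the format (.csv or .json).
#' @return `path`, invisibly (for `write_nodule_table`); for
#'   `read_nodule_table`, a list of [ellipsoid()] objects.
#' @export
write_nodule_table <- function(nodules, path) {
  df <- if (is.data.frame(nodules)) nodules else nodule_table(nodules)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_nodule_table
#' @param path File written by [write_nodule_table()].
#' @export
read_nodule_table <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  lapply(seq_len(nrow(df)), function(i) {
    ellipsoid(df$id[i], c(df$center_x[i], df$center_y[i], df$center_z[i]),
              df$d_eq[i], df$ratio[i], df$theta[i], df$mu[i],
              df$sd_motion[i])
  })
}

#' Chord length of a ray through an ellipsoid
#'
#' Closed-form quadratic intersection of the (infinite) ray line with the
#' rotated, translated ellipsoid; returns the Euclidean length of the
#' segment inside, 0 on a miss.
#'
#' @param e An [ellipsoid()].
#' @param ray_origin Length-3 numeric, mm.
#' @param ray_direction Length-3 unit vector, or an n x 3 matrix of unit
#'   rows for vectorised evaluation.
#' @return Chord length(s), mm.
#' @export
chord_length <- function(e, ray_origin, ray_direction) {
  stopifnot(inherits(e, "ellipsoid"), length(ray_origin) == 3)
  D <- if (is.matrix(ray_direction)) ray_direction else
    matrix(ray_direction, nrow = 1)
  stopifnot(ncol(D) == 3)
  nrm <- sqrt(rowSums(D^2))
  if (any(nrm < 1e-12)) stop("ray direction must be a non-zero vector")
  if (any(abs(nrm - 1) > 1e-8)) {
    stop("ray direction must be normalised to unit length")
  }
  R <- ellipsoid_axes(e)
  semi <- c(e$major_axis, e$minor_axis, e$minor_axis) / 2
  p0 <- as.numeric(crossprod(R, ray_origin - e$center)) / semi
  Ds <- (D %*% R) / rep(semi, each = nrow(D))
  a <- rowSums(Ds^2)
  # re-centre each ray at its closest approach to the ellipsoid centre
  # (in the scaled frame) so the quadratic keeps full precision even for
  # origins millions of mm away
  tc <- -as.numeric(Ds %*% p0) / a
  P <- matrix(p0, nrow(D), 3, byrow = TRUE) + tc * Ds
  b <- 2 * rowSums(Ds * P)
  c0 <- rowSums(P^2) - 1
  disc <- b^2 - 4 * a * c0
  out <- ifelse(disc > 0, sqrt(pmax(disc, 0)) / a, 0)
  if (!is.matrix(ray_direction)) out[1] else out
}
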