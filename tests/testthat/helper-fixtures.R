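# Shared fixtures: small geometries, uniform projection stacks, and the
# fine-step line-integral oracle for ray-ellipsoid chords.

# A reduced detector tall enough for the +-15 deg parallax of shallow
# nodules; keeps matrix sizes desk-scale.
small_geometry <- function(n_projections = 15L, rows = 360L, cols = 220L,
                           ...) {
  system_geometry(n_projections = n_projections,
                  detector_size = c(rows, cols), ...)
}

uniform_projections <- function(g, value = 1000) {
  projection_set(array(value, dim = c(g$detector_size, g$n_projections)), g)
}

# Independent chord oracle: sample the ellipsoid indicator along the ray
# at `step` mm and sum. Brackets the ray around the closest approach to
# the nodule centre so the scan stays short.
chord_oracle <- function(e, origin, direction, step = 0.001) {
  direction <- direction / sqrt(sum(direction^2))
  tc <- sum((e$center - origin) * direction)
  tt <- seq(tc - e$major_axis, tc + e$major_axis, by = step)
  pts <- outer(tt, direction) + matrix(origin, length(tt), 3, byrow = TRUE)
  R <- cbind(c(cos(e$theta * pi / 180), sin(e$theta * pi / 180), 0),
             c(-sin(e$theta * pi / 180), cos(e$theta * pi / 180), 0),
             c(0, 0, 1))
  semi <- c(e$major_axis, e$minor_axis, e$minor_axis) / 2
  q <- sweep(pts, 2, e$center) %*% R
  sum(rowSums(sweep(q, 2, semi, "/")^2) < 1) * step
}

# Measurement table with prescribed round-1 diameters (one observer, one
# stratum) for estimator arithmetic checks.
flat_measurement_table <- function(values, dose = 1, observer = 1L,
                                   round = 1L, group = "8mm") {
  data.frame(observer_id = observer,
             nodule_id = sprintf("n%02d", seq_along(values)),
             size_group = group, dose_level = dose, round = round,
             measured_diameter = values,
             nonmeasurable = is.na(values),
             section_index = 5L)
}

# Complete-case table for the repeated-measures ANOVA: `n` nodules
# measured at each dose level, iid N(true, sd) diameters.
anova_table <- function(n, doses = c(1, 0.5, 0.32), true = 10, sd = 0.2) {
  ids <- sprintf("n%02d", seq_len(n))
  df <- expand.grid(nodule_id = ids, dose_level = doses,
                    stringsAsFactors = FALSE)
  data.frame(observer_id = 1L, nodule_id = df$nodule_id, size_group = "8mm",
             dose_level = df$dose_level, round = 1L,
             measured_diameter = true + rnorm(nrow(df), 0, sd),
             nonmeasurable = FALSE, section_index = 5L)
}

anova_truths <- function(n, true = 10) {
  data.frame(nodule_id = sprintf("n%02d", seq_len(n)), size_group = "8mm",
             true_diameter = true)
}
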