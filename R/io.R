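# File interfaces: projection stacks as an array container with a JSON
# sidecar, and section stacks as 16-bit TIFF series with JSON metadata.

#' Write / read a projection stack
#'
#' The container is a directory holding `pixels.rds` (the raw array,
#' R serialisation) and `meta.json` (geometry, per-projection angles and
#' focal spots, tube load, dose fraction) so the acquisition metadata
#' stays human-readable alongside the pixel data.
#'
#' @param p A [projection_set()].
#' @param path Directory to create/overwrite.
#' @return `path` invisibly; `read_projection_set()` returns the
#'   reconstituted [projection_set()].
#' @export
write_projection_set <- function(p, path) {
  stopifnot(inherits(p, "projection_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(p$pixels, file.path(path, "pixels.rds"))
  g <- p$geometry
  jsonlite::write_json(list(
    geometry = list(sid = g$sid, half_angle = g$half_angle,
                    n_projections = g$n_projections,
                    pixel_pitch = g$pixel_pitch,
                    detector_size = g$detector_size),
    angles = p$angles, focal_spots = p$focal_spots,
    mAs_per_projection = p$mAs_per_projection,
    dose_fraction = p$dose_fraction),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  g <- system_geometry(sid = meta$geometry$sid,
                       half_angle = meta$geometry$half_angle,
                       n_projections = meta$geometry$n_projections,
                       pixel_pitch = meta$geometry$pixel_pitch,
                       detector_size = meta$geometry$detector_size)
  projection_set(readRDS(file.path(path, "pixels.rds")), g,
                 mAs_per_projection = meta$mAs_per_projection,
                 dose_fraction = meta$dose_fraction)
}

#' Write / read a section stack as a 16-bit TIFF series
#'
#' Each section becomes `section_NN.tif` (16-bit grayscale, linearly
#' rescaled to the stack's range, which is recorded in `meta.json` along
#' with depths, pixel pitch and provenance), the format reading
#' workstations expect. Requires the `tiff` package. The 16-bit
#' quantisation limits the round trip to ~1.5e-5 of the dynamic range.
#'
#' @param s A [section_stack()].
#' @param path Directory to create/overwrite.
#' @return `path` invisibly; `read_section_stack()` returns the
#'   reconstituted [section_stack()].
#' @export
write_section_stack <- function(s, path) {
  stopifnot(inherits(s, "section_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  lo <- min(s$sections); hi <- max(s$sections)
  scale <- if (hi > lo) hi - lo else 1
  for (k in seq_along(s$depths)) {
    img <- (s$sections[, , k] - lo) / scale
    tiff::writeTIFF(img, file.path(path, sprintf("section_%02d.tif", k)),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(list(depths = s$depths,
                            pixel_pitch = s$pixel_pitch,
                            value_min = lo, value_scale = scale,
                            provenance = s$provenance),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_section_stack
#' @export
read_section_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import")
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^section_\\d+\\.tif$",
                           full.names = TRUE))
  imgs <- lapply(files, function(f)
    tiff::readTIFF(f) * meta$value_scale + meta$value_min)
  arr <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
  section_stack(arr, meta$depths, meta$pixel_pitch,
                provenance = meta$provenance)
}
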