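# End-to-end study orchestration: nodules -> background + insertion ->
# dose reduction -> reconstruction -> case windows -> simulated
# measurements -> statistics, from one configuration with a single master
# seed and a manifest of every artifact.

#' Effective dose at a fractional dose level
#'
#' The examination-level effective dose scales linearly with the dose
#' fraction from the configured baseline (0.12 mSv for the full chest
#' tomosynthesis examination, excluding the scout).
#'
#' @param dose_fraction Relative dose in (0, 1].
#' @param baseline_mSv Effective dose of the full-dose examination, mSv.
#' @return List with `mSv` (exact) and `mSv_reported` (rounded to two
#'   decimals, the convention used when quoting examination doses).
#' @export
#' @examples
#' effective_dose(0.5)$mSv_reported   # 0.06
#' effective_dose(0.32)$mSv_reported  # 0.04
effective_dose <- function(dose_fraction, baseline_mSv = 0.12) {
  stopifnot(dose_fraction > 0, baseline_mSv > 0)
  e <- baseline_mSv * dose_fraction
  list(mSv = e, mSv_reported = round(e, 2))
}

#' Study configuration
#'
#' Bundles every stage's parameters. The defaults reproduce the study
#' layout (3 size groups x 27 positions x dose fractions 1/0.5/0.32, four
#' observers, two rounds) at full detector size; `run_study()` accepts a
#' reduced geometry for desk-scale runs.
#'
#' @param geometry A [system_geometry()].
#' @param exposure An [exposure_settings()].
#' @param nodule_spec A [nodule_set_spec()].
#' @param dose_fractions Descending dose fractions, first equal to 1.
#' @param detector A [detector_model()].
#' @param observers An [observer_params()].
#' @param insertion An [insertion_config()].
#' @param texture A [texture_params()].
#' @param calibration_levels Flat-field dose levels for the calibration.
#' @param section_spacing Reconstruction depth spacing, mm.
#' @param baseline_mSv Effective dose of the full-dose examination, mSv.
#' @param out_dir Output directory for rendered artifacts.
#' @param seed Master seed; every stochastic stage derives a sub-seed.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(geometry = system_geometry(),
                         exposure = exposure_settings(scout_mAs = 2.5),
                         nodule_spec = nodule_set_spec(),
                         dose_fractions = c(1, 0.5, 0.32),
                         detector = detector_model(),
                         observers = observer_params(),
                         insertion = insertion_config(),
                         texture = texture_params(),
                         calibration_levels = c(0.25, 0.32, 0.5, 0.71, 1),
                         section_spacing = 5,
                         baseline_mSv = 0.12,
                         out_dir = tempfile("tomostudy"),
                         seed = 1L) {
  stopifnot(abs(dose_fractions[1] - 1) < 1e-12,
            !is.unsorted(rev(dose_fractions)))
  structure(list(geometry = geometry, exposure = exposure,
                 nodule_spec = nodule_spec, dose_fractions = dose_fractions,
                 detector = detector, observers = observers,
                 insertion = insertion, texture = texture,
                 calibration_levels = calibration_levels,
                 section_spacing = section_spacing,
                 baseline_mSv = baseline_mSv,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full study replica
#'
#' Generates the nodule population, simulates the measurement study and
#' its statistics, and (unless `dry_run`) renders each case's image chain:
#' lung-like background projections, nodule insertion, dose reduction to
#' each fraction, reconstruction, and the 10-section presentation window,
#' cached to disk per case. The manifest lists every series (one per
#' nodule and dose level) with its seed and a checksum.
#'
#' With `dry_run = TRUE` (default) the image chain is planned but not
#' rendered: the manifest and the measurement statistics are produced in
#' full, which is sufficient for the study bookkeeping (the stochastic
#' observer model reads the ground-truth geometry, not the pixels).
#'
#' @param cfg A [study_config()].
#' @param dry_run Skip image rendering.
#' @param render_cases Optional character vector of nodule ids to render
#'   when `dry_run = FALSE` (default: all).
#' @return The manifest, invisibly also written to
#'   `file.path(cfg$out_dir, "manifest.json")`.
#' @export
run_study <- function(cfg, dry_run = TRUE, render_cases = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  nodules <- generate_nodule_set(cfg$nodule_spec)
  nt <- nodule_table(nodules)
  write_nodule_table(nt, file.path(cfg$out_dir, "nodules.csv"))

  # study factorial: one image series per nodule and dose level
  series <- expand.grid(nodule_id = nt$id,
                        dose_fraction = cfg$dose_fractions,
                        stringsAsFactors = FALSE)
  series$series_id <- sprintf("%s_d%03.0f", series$nodule_id,
                              100 * series$dose_fraction)
  series$seed <- vapply(series$series_id, function(id)
    derive_seed(cfg$seed, "series", id), integer(1))
  series$effective_dose_mSv <- vapply(series$dose_fraction, function(s)
    effective_dose(s, cfg$baseline_mSv)$mSv_reported, numeric(1))

  mAs <- per_projection_tube_load(cfg$exposure, cfg$geometry$n_projections)

  rendered <- NULL
  if (!dry_run) {
    rendered <- render_image_chain(cfg, nodules, series, mAs, render_cases)
    series$checksum <- rendered$checksum[match(series$series_id,
                                               rendered$series_id)]
  } else {
    series$checksum <- vapply(seq_len(nrow(series)), function(i)
      hash_string(paste(series$series_id[i], series$seed[i],
                        series$effective_dose_mSv[i])), character(1))
  }

  meas <- simulate_measurements(nt, cfg$dose_fractions, cfg$observers)
  utils::write.csv(meas, file.path(cfg$out_dir, "measurements.csv"),
                   row.names = FALSE)
  truths <- nodule_truths(nt)
  stats_dir <- file.path(cfg$out_dir, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  # estimators needing >= 2 nodules/observers/doses are skipped (with a
  # message) for deliberately tiny configurations
  try_stat <- function(f) tryCatch(f(), error = function(e) {
    message("run_study: statistic skipped: ", conditionMessage(e))
    NULL
  })
  st <- list(accuracy = try_stat(function() accuracy(meas, truths)),
             intraobserver = try_stat(function()
               intraobserver_variability(meas)),
             interobserver = try_stat(function()
               interobserver_variability(meas)),
             internodule = try_stat(function()
               internodule_variability(meas, truths)),
             nonmeasurable = count_nonmeasurable(meas))
  for (nm in names(st)) {
    if (!is.null(st[[nm]])) {
      utils::write.csv(st[[nm]], file.path(stats_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  anova_res <- try_stat(function() rm_anova_abs_diff(meas, truths))

  manifest <- list(
    n_nodules = nrow(nt),
    n_size_groups = length(unique(nt$d_eq)),
    n_positions = cfg$nodule_spec$n_positions,
    dose_fractions = cfg$dose_fractions,
    effective_doses_mSv = vapply(cfg$dose_fractions, function(s)
      effective_dose(s, cfg$baseline_mSv)$mSv_reported, numeric(1)),
    mAs_per_projection = mAs,
    n_series = nrow(series),
    n_observers = cfg$observers$n_observers,
    n_measurement_rows = nrow(meas),
    seed = cfg$seed,
    rendered = !dry_run,
    series = series)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, stats = st, anova = anova_res,
                 measurements = meas, nodules = nt))
}

#' Build a study configuration from a YAML file
#'
#' Each top-level key maps to the matching [study_config()] argument;
#' structured keys (`geometry`, `exposure`, `nodule_spec`, `detector`,
#' `observers`, `insertion`, `texture`) hold the arguments of the
#' corresponding constructor, with omitted fields taking the package
#' defaults. `nodule_spec$position_list` may be an inline list of
#' `[x, y, z]` triples.
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
study_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  if (!is.null(y$nodule_spec$position_list)) {
    y$nodule_spec$position_list <-
      do.call(rbind, lapply(y$nodule_spec$position_list, unlist))
  }
  args <- list(
    geometry = build(system_geometry, y$geometry),
    exposure = if (is.null(y$exposure)) exposure_settings(scout_mAs = 2.5)
               else build(exposure_settings, y$exposure),
    nodule_spec = build(nodule_set_spec, y$nodule_spec),
    detector = build(detector_model, y$detector),
    observers = build(observer_params, y$observers),
    insertion = build(insertion_config, y$insertion),
    texture = build(texture_params, y$texture))
  for (k in c("dose_fractions", "calibration_levels", "section_spacing",
              "baseline_mSv", "out_dir", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(study_config, args)
}

# Render the image chain for the requested cases; returns checksums.
render_image_chain <- function(cfg, nodules, series, mAs, render_cases) {
  g <- cfg$geometry
  flats <- generate_flat_fields(
    cfg$detector, cfg$calibration_levels, n_per_level = 2L,
    shape = pmin(g$detector_size, 256L),
    seed = derive_seed(cfg$seed, "calibration"))
  cal <- flat_field_calibration(
    flats, roi_size = min(64L, 2^floor(log2(min(g$detector_size) / 2))))
  ids <- if (is.null(render_cases)) unique(series$nodule_id) else render_cases
  proj_dir <- file.path(cfg$out_dir, "sections")
  dir.create(proj_dir, showWarnings = FALSE)
  out <- NULL
  for (id in ids) {
    e <- nodules[[which(vapply(nodules, `[[`, "", "id") == id)]]
    bg <- generate_background(g, cfg$detector, cfg$texture,
                              mAs_per_projection = mAs,
                              seed = derive_seed(cfg$seed, "background", id))
    cfg_ins <- cfg$insertion
    cfg_ins$seed <- derive_seed(cfg$seed, "insertion", id)
    p_full <- insert_nodule(bg, e, cfg_ins)
    z0 <- e$center[3]
    depths <- z0 + cfg$section_spacing * (-6:6)
    depths <- depths[depths > 0 & depths < g$sid]
    for (s in cfg$dose_fractions) {
      sid0 <- series$series_id[series$nodule_id == id &
                               series$dose_fraction == s]
      p <- if (s < 1) {
        simulate_dose_reduction(p_full, s, cal,
                                seed = derive_seed(cfg$seed, "dose", sid0))
      } else p_full
      sec <- reconstruct(p, depths)
      win <- extract_case_window(sec, e)
      path <- file.path(proj_dir, paste0(sid0, ".rds"))
      saveRDS(win, path)
      out <- rbind(out, data.frame(
        series_id = sid0,
        checksum = substr(unname(tools::md5sum(path)), 1, 12)))
    }
  }
  out
}
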