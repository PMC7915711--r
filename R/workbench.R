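#' Default pipeline configuration
#'
#' A nested list describing one full run of the simulation pipeline:
#' lens design, fluence prediction, wire-phantom PA acquisition,
#' beamforming, and rendering.  All stochastic stages carry explicit
#' integer seeds; there is no implicit entropy.
#'
#' @param illumination `"lens"`, `"bare"`, or `"uniform"` target weighting.
#' @param seed base seed; stage seeds are derived deterministically.
#' @return A `run_config` list.
#' @export
default_run_config <- function(illumination = "lens", seed = 1) {
  structure(list(
    lens = list(),                       # lens_design() arguments
    array = list(),                      # convex_array() arguments
    pulse = list(center_frequency_mhz = 6.75, fractional_bandwidth = 0.66,
                 sampling_rate_mhz = 40),
    phantom = list(angle_start_deg = -75, angle_stop_deg = 75,
                   angle_step_deg = 15, radius_start_mm = 5,
                   radius_stop_mm = 55, radius_step_mm = 10),
    medium = "milk3",
    illumination = illumination,
    fluence = list(n_photons = 5000,
                   grid = list(xlim = c(-40, 40), ylim = c(-8, 8),
                               zlim = c(0, 60), voxel_size_mm = 2)),
    beamform = list(aperture_size = 64, weighting = "none",
                    dynamic_range_db = 35, pixel_spacing_mm = 0.25,
                    range_step_mm = 0.1),
    seeds = list(fluence = seed, noise = seed + 1),
    stages = list(fluence = TRUE, simulate = TRUE, beamform = TRUE,
                  render = TRUE)),
    class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as JSON; unknown top-level fields are
#' rejected with the list of valid names.
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_run_config` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config()
  bad <- setdiff(names(cfg), names(base))
  if (length(bad)) {
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         "; valid fields are: ", paste(names(base), collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(unclass(base), cfg)
  class(out) <- "run_config"
  validate_run_config(out)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

validate_run_config <- function(config) {
  if (!config$illumination %in% c("lens", "bare", "uniform")) {
    stop("illumination must be one of lens/bare/uniform", call. = FALSE)
  }
  if (!config$medium %in% c("milk3", "transparent")) {
    stop("unknown medium preset '", config$medium, "'", call. = FALSE)
  }
  seeds <- unlist(config$seeds)
  if (any(seeds != round(seeds))) {
    stop("all seeds must be explicit integers", call. = FALSE)
  }
  if (config$illumination %in% c("lens", "bare") &&
      !isTRUE(config$stages$fluence)) {
    stop("stage 'fluence' is disabled but illumination '",
         config$illumination, "' requires a fluence grid; enable the ",
         "fluence stage or set illumination = \"uniform\"", call. = FALSE)
  }
  config
}

#' Run the full simulation pipeline
#'
#' Executes the enabled stages in dependency order -- lens design report,
#' Monte Carlo fluence, wire-phantom PA acquisition, beamforming, sector
#' rendering -- writing each artifact under `out_dir` together with a
#' manifest (config hash, seeds, artifact paths and MD5 checksums, package
#' version).  Reruns with an identical config produce byte-identical
#' numeric artifacts.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory, created if missing.
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("patrus_")) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  lens <- do.call(lens_design, config$lens)
  array <- do.call(convex_array, config$array)
  pulse <- do.call(synthesize_pulse, config$pulse)

  tr <- trace_lateral(lens, n_rays = 1001)
  el <- trace_elevation(lens)
  report <- list(fov_full_angle_deg = tr$fov_full_angle_deg,
                 n_tir = tr$n_tir,
                 deviation_angle_deg = el$deviation_angle_deg,
                 crossing_depth_mm = el$crossing_depth_mm)
  p <- file.path(out_dir, "lens_report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
  artifacts$lens_report <- p

  fluence <- NULL
  if (isTRUE(config$stages$fluence) && config$illumination != "uniform") {
    fluence <- simulate_fluence(source = config$illumination,
                                medium = medium_preset(config$medium),
                                grid = config$fluence$grid,
                                n_photons = config$fluence$n_photons,
                                seed = config$seeds$fluence,
                                lens = lens)
    p <- file.path(out_dir, "fluence.rds")
    saveRDS(fluence, p, version = 2)
    artifacts$fluence_grid <- p
  }

  rf <- NULL
  if (isTRUE(config$stages$simulate)) {
    phantom <- do.call(make_wire_phantom, config$phantom)
    illum <- if (is.null(fluence)) "uniform" else fluence
    rf <- simulate_pa_rf(phantom, array, pulse, illumination = illum)
    p <- file.path(out_dir, "pa_rf.rds")
    saveRDS(rf, p, version = 2)
    artifacts$pa_rf <- p
    pt <- file.path(out_dir, "phantom.tsv")
    utils::write.table(phantom$targets, pt, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    artifacts$phantom <- pt
  }

  if (isTRUE(config$stages$beamform)) {
    if (is.null(rf)) {
      stop("stage 'beamform' needs the RF frame from stage 'simulate'; ",
           "enable the simulate stage", call. = FALSE)
    }
    sl <- das_beamform(rf, array,
                       aperture_size = config$beamform$aperture_size,
                       weighting = config$beamform$weighting,
                       range_step_mm = config$beamform$range_step_mm)
    sl <- envelope_logcompress(sl, config$beamform$dynamic_range_db)
    p <- file.path(out_dir, "pa_scanlines.rds")
    saveRDS(sl, p, version = 2)
    artifacts$pa_scanlines <- p
    if (isTRUE(config$stages$render)) {
      img <- scan_convert(sl, array, config$beamform$pixel_spacing_mm)
      p <- file.path(out_dir, "pa_image.pgm")
      save_bmode_pgm(img, p)
      artifacts$pa_image <- p
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("patrus")),
    config = unclass(config),
    config_md5 = config_hash(config),
    seeds = config$seeds,
    artifacts = artifacts,
    checksums = as.list(tools::md5sum(unlist(artifacts))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write seeded fixture files
#'
#' Deterministically writes one of the named phantom / medium / config
#' fixtures used throughout the examples and tests.
#'
#' @param name `"wires66"` (the 66-wire radial phantom, TSV),
#'   `"single_target"` (one wire at (0, 25) mm, TSV), `"milk3"` (scattering
#'   medium preset, JSON), or `"intestine_slab"` (wall-layer transmission
#'   preset, JSON).
#' @param dir output directory.
#' @param seed integer recorded in the fixture for provenance.
#' @return The path of the written file.
#' @export
fixtures <- function(name, dir = tempdir(), seed = 1) {
  valid <- c("wires66", "single_target", "milk3", "intestine_slab")
  if (!name %in% valid) {
    stop("unknown fixture '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(name, if (name %in% c("milk3", "intestine_slab"))
    ".json" else ".tsv"))
  if (name == "wires66") {
    ph <- make_wire_phantom()
    utils::write.table(cbind(seed = seed, ph$targets), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else if (name == "single_target") {
    ph <- make_wire_phantom(0, 0, 15, 25, 25, 10)
    utils::write.table(cbind(seed = seed, ph$targets), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else if (name == "milk3") {
    m <- medium_preset("milk3")
    jsonlite::write_json(c(unclass(m), list(seed = seed)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(list(thickness_mm = 3,
                              wavelength_nm = intestine_table$wavelength_nm,
                              fraction = intestine_table$fraction,
                              seed = seed),
                         path, digits = NA)
  }
  path
}

#' Export a B-mode image as an ASCII PGM
#'
#' @param image a `bmode_image`.
#' @param path output file (`.pgm`).
#' @return The path, invisibly.
#' @export
save_bmode_pgm <- function(image, path) {
  stopifnot(inherits(image, "bmode_image"))
  g <- round(255 * t(image$intensity[rev(seq_len(nrow(image$intensity))), ]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(g), ncol(g)), "255"), con)
  write(as.integer(g), con, ncolumns = 16)
  invisible(path)
}

#' Export an overlay image as PNG
#'
#' @param image an `overlay_image` from [overlay()].
#' @param path output file (`.png`).
#' @return The path, invisibly.
#' @export
save_overlay_png <- function(image, path) {
  stopifnot(inherits(image, "overlay_image"))
  png::writePNG(image$rgb[rev(seq_len(dim(image$rgb)[1])), , ], path)
  invisible(path)
}

#' Export array element geometry as delimited text
#'
#' @param array a [convex_array()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
save_array_geometry <- function(array, path) {
  stopifnot(inherits(array, "convex_array"))
  df <- data.frame(element = seq_len(array$n_elements),
                   x_mm = array$element_positions[, 1],
                   z_mm = array$element_positions[, 2],
                   normal_angle_deg = array$element_angles_deg)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a beam profile as CSV
#'
#' @param profile a `beam_profile`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
save_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "beam_profile"))
  utils::write.table(data.frame(position_mm = profile$positions_mm,
                                intensity = profile$intensity),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
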