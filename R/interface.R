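# Configuration, file I/O and the reproducible pipeline runner binding
# simulation, calibration and reconstruction. YAML for human-edited configs,
# JSON for machine artifacts, float TIFF for frames and stacks.

.config_schema <- list(
  array = c("ring_radius_um", "intersection_mm", "sensor_mm", "lens_diameter_um",
            "focal_central_um", "focal_edge_um", "tilt_deg", "stop", "sensor"),
  phantom = c("type", "seed", "n_layers", "beads_per_layer", "layer_spacing_um",
              "bead_diameter_um", "lateral_extent_um", "z_center_um",
              "grid_pitch_um", "grid_extent_um", "z_um", "zrange",
              "noise"),
  pipeline = c("zrange", "background_radius_px", "feature_mask",
               "feature_window_px", "feature_opening_px", "normalize_shading",
               "rescale", "shift_method", "foveated_min", "blend_min",
               "focus_measure", "psf_fwhm_um", "edof"),
  io = c("out_dir", "frame", "aperture", "stack_dir", "calibration"),
  version = NULL)

#' Read and validate a run configuration (YAML)
#'
#' Unknown keys at the top or section level are rejected so typos fail fast.
#'
#' @param path YAML file path.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a config list.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown)) {
    .clf_error(sprintf("unknown config section(s): %s", paste(unknown, collapse = ", ")),
               "clf_schema_error")
  }
  for (sec in intersect(names(config), names(.config_schema))) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) {
      .clf_error(sprintf("unknown key(s) in `%s`: %s", sec, paste(bad, collapse = ", ")),
                 "clf_schema_error")
    }
  }
  structure(config, class = c("run_config", "list"))
}

# ---- artifact I/O -----------------------------------------------------------

#' Save / load frames and stacks as 32-bit float TIFF
#'
#' Frames round-trip losslessly at float precision; stacks are multi-page
#' TIFFs (one page per z layer).
#'
#' @param frame a `capture_frame`.
#' @param path file path.
#' @return readers return the stored object; writers return `path` invisibly.
#' @export
save_frame_tiff <- function(frame, path) {
  # values are stored shifted into [0, 1] with a power-of-two scale (the
  # division is exact in binary floating point); offset and scale go to the
  # JSON sidecar so readers restore physical values
  off <- min(0, min(frame$image))
  img <- frame$image - off
  sc <- 2^ceiling(log2(max(img, 1e-12)))
  tiff::writeTIFF(img / sc, path, bits.per.sample = 32, reduce = FALSE)
  meta <- frame$metadata
  meta$pixel_pitch <- frame$pixel_pitch
  meta$value_scale <- sc
  meta$value_offset <- off
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  pitch <- if (!is.null(meta$pixel_pitch)) meta$pixel_pitch else 1
  if (!is.null(meta$value_scale)) img <- img * meta$value_scale
  if (!is.null(meta$value_offset)) img <- img + meta$value_offset
  meta$pixel_pitch <- NULL
  meta$value_scale <- NULL
  meta$value_offset <- NULL
  capture_frame(img, pitch, metadata = meta)
}

#' @rdname save_frame_tiff
#' @param stack 3D array (y, x, z) or list of matrices.
#' @export
save_stack_tiff <- function(stack, path) {
  pages <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  off <- min(0, min(unlist(lapply(pages, min))))
  sc <- 2^ceiling(log2(max(unlist(lapply(pages, max)) - off, 1e-12)))
  tiff::writeTIFF(lapply(pages, function(p) (p - off) / sc), path,
                  bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(value_scale = sc, value_offset = off,
                            n_pages = length(pages)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_frame_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  sc <- 1; off <- 0
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$value_scale)) sc <- meta$value_scale
    if (!is.null(meta$value_offset)) off <- meta$value_offset
  }
  array(unlist(pages), c(dim(pages[[1]]), length(pages))) * sc + off
}

#' Run one pipeline command
#'
#' * `simulate`: render the configured phantom (bead layers, PSF calibration
#'   stack or grid target) plus the aperture frame, with ground-truth JSON
#'   sidecars.
#' * `calibrate`: segment the aperture frame, localize the PSF stack, fit
#'   translation and magnification models, write calibration JSON.
#' * `reconstruct`: run the five-stage pipeline on a frame, write the volume,
#'   shading and zone stacks and a provenance record.
#' * `characterize`: geometry report (per-lenslet NA, conjugate ranges, mean
#'   magnification, zone extents; optionally the wave-optics EDOF ratio).
#'
#' All randomness is seeded from the config; a run writes its effective
#' config next to its outputs.
#'
#' @param command one of `"simulate"`, `"calibrate"`, `"reconstruct"`,
#'   `"characterize"`.
#' @param config a [read_run_config()] list.
#' @param out_dir output directory (created if missing).
#' @return named list of written paths (invisibly), plus key objects.
#' @export
run_pipeline <- function(command = c("simulate", "calibrate", "reconstruct",
                                     "characterize"),
                         config, out_dir) {
  command <- match.arg(command)
  config <- validate_run_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arr <- array_from_config(config$array %||% list())
  written <- list()
  if (command == "simulate") {
    ph <- config$phantom %||% list()
    type <- ph$type %||% "beads"
    seed <- ph$seed %||% 1L
    nm <- if (!is.null(ph$noise)) noise_model(ph$noise$photon_scale %||% 0,
                                              ph$noise$read_sigma %||% 0,
                                              ph$noise$offset %||% 0,
                                              ph$noise$seed %||% seed)
    fwhm <- config$pipeline$psf_fwhm_um %||% .default_psf_fwhm_um
    if (type == "beads") {
      scn <- bead_layers_phantom(ph$n_layers %||% 3, ph$beads_per_layer %||% 12,
                                 ph$layer_spacing_um %||% 170,
                                 ph$bead_diameter_um %||% 15.4,
                                 ph$lateral_extent_um %||% 250,
                                 ph$z_center_um %||% 3000, seed = seed)
      fr <- render_capture(scn, arr, psf_fwhm = fwhm, noise = nm)
      fr$metadata$truth <- list(layer_z_um = attr(scn, "layer_z_um"),
                                emitters = scn$emitters)
      p <- file.path(out_dir, "beads_frame.tif")
      save_frame_tiff(fr, p); written$frame <- p
    } else if (type == "grid") {
      scn <- grid_target_scene(ph$grid_pitch_um %||% 100, ph$grid_extent_um %||% 400,
                               ph$z_um %||% 3000)
      fr <- render_capture(scn, arr, psf_fwhm = fwhm, noise = nm)
      fr$metadata$truth <- list(z_um = ph$z_um %||% 3000)
      p <- file.path(out_dir, "grid_frame.tif")
      save_frame_tiff(fr, p); written$frame <- p
    } else if (type == "psf_stack") {
      zr <- ph$zrange %||% list(z_min_um = 2000, z_max_um = 4000, step_um = 100)
      stk <- psf_calibration_stack_scene(depth_range(zr$z_min_um, zr$z_max_um,
                                                     zr$step_um),
                                         bead_diameter = ph$bead_diameter_um %||% 2.5)
      for (el in stk) {
        fr <- render_capture(el$scene, arr, psf_fwhm = fwhm, noise = nm)
        fr$metadata$z_um <- el$z
        p <- file.path(out_dir, sprintf("psf_z%06.0f.tif", el$z))
        save_frame_tiff(fr, p)
      }
      written$stack_dir <- out_dir
    } else .clf_error(sprintf("unknown phantom type '%s'", type), "clf_schema_error")
    ap <- render_aperture_frame(arr)
    p <- file.path(out_dir, "aperture_frame.tif")
    save_frame_tiff(ap, p); written$aperture <- p
  } else if (command == "calibrate") {
    io <- config$io %||% list()
    stack_dir <- io$stack_dir %||% .clf_error("io$stack_dir required", "clf_missing_input")
    ap_path <- io$aperture %||% file.path(stack_dir, "aperture_frame.tif")
    if (!file.exists(ap_path)) .clf_error(sprintf("missing aperture frame %s", ap_path),
                                          "clf_missing_input")
    mask <- segment_apertures(read_frame_tiff(ap_path))
    files <- sort(list.files(stack_dir, pattern = "^psf_z.*\\.tif$", full.names = TRUE))
    if (!length(files)) .clf_error("no PSF frames found", "clf_missing_input")
    stack <- lapply(files, function(f) {
      fr <- read_frame_tiff(f)
      list(z = fr$metadata$z_um, frame = fr)
    })
    loc <- localize_psfs(stack, mask)
    model <- fit_translation_model(loc)
    mag <- fit_magnification("parametric", sensor_distance = arr$sensor_distance)
    p <- file.path(out_dir, "calibration.json")
    write_calibration(model, mag, p); written$calibration <- p
    utils::write.csv(loc, file.path(out_dir, "localizations.csv"), row.names = FALSE)
  } else if (command == "reconstruct") {
    io <- config$io %||% list()
    pl <- config$pipeline %||% list()
    frame <- read_frame_tiff(io$frame %||% .clf_error("io$frame required", "clf_missing_input"))
    mask <- segment_apertures(read_frame_tiff(io$aperture %||%
                                                .clf_error("io$aperture required", "clf_missing_input")))
    cal <- read_calibration(io$calibration %||%
                              .clf_error("io$calibration required", "clf_missing_input"))
    zr <- pl$zrange %||% list(z_min_um = 2000, z_max_um = 4000, step_um = 100)
    vol <- reconstruct(frame, mask, cal$translation, cal$magnification,
                       depth_range(zr$z_min_um, zr$z_max_um, zr$step_um),
                       background_radius = pl$background_radius_px,
                       feature_mask = pl$feature_mask %||% TRUE,
                       normalize_shading = pl$normalize_shading %||% FALSE,
                       rescale = pl$rescale %||% TRUE,
                       shift_method = pl$shift_method %||% "interp")
    written$volume <- save_stack_tiff(vol$stack, file.path(out_dir, "volume.tif"))
    written$shading <- save_stack_tiff(vol$shading, file.path(out_dir, "shading.tif"))
    written$zones <- save_stack_tiff(vol$zones, file.path(out_dir, "zones.tif"))
    prov <- vol$provenance
    prov$z_um <- vol$z_um
    prov$object_pixel_um <- vol$object_pixel_um
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    written$provenance <- file.path(out_dir, "provenance.json")
  } else if (command == "characterize") {
    lens_rows <- lapply(arr$lenslets, function(l) {
      cr <- conjugate_object_range(l, arr$sensor_distance)
      tibble::tibble(lens_id = l$id, tilt_deg = l$tilt_deg,
                     na_fmax = lenslet_na(l),
                     na_fmid = lenslet_na(l, (l$focal_min + l$focal_max) / 2),
                     z_near_um = cr[1], z_far_um = cr[2], span_um = cr[2] - cr[1])
    })
    report <- do.call(rbind, lens_rows)
    utils::write.csv(report, file.path(out_dir, "lenslets.csv"), row.names = FALSE)
    ze <- zone_extents(arr)
    utils::write.csv(ze, file.path(out_dir, "zones.csv"), row.names = FALSE)
    summ <- list(mean_magnification = mean_magnification(arr),
                 zone_means_um = as.list(attr(ze, "means")))
    if (isTRUE(config$pipeline$edof)) {
      er <- edof_ratio(arr)
      summ$edof_ratio <- er$ratio
      summ$edof_log_range_um <- er$log_range_um
      summ$edof_spherical_range_um <- er$spherical_range_um
    }
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    written$report <- file.path(out_dir, "lenslets.csv")
  }
  cfg_out <- unclass(config)
  cfg_out$version <- as.character(utils::packageVersion("compoundlf"))
  yaml::write_yaml(cfg_out, file.path(out_dir, "effective_config.yaml"))
  written$config <- file.path(out_dir, "effective_config.yaml")
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
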