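# Synthetic-data generator: bead-layer scenes, PSF calibration stacks, grid
# targets, the forward renderer producing full-sensor capture frames, the
# aperture-mask frame, and the Poisson + Gaussian noise model. Default bead
# sizes follow the physical phantoms the design targets: 2.5 um calibration
# beads and 15.4 um beads in three coverslip-spaced layers.

#' Construct a scene of point/bead emitters
#'
#' @param emitters tibble with columns `x_um`, `y_um`, `z_um`, `diameter_um`,
#'   `intensity`.
#' @param background_level constant background flux per pixel.
#' @param extent optional 3D bounding box, list(x, y, z) of length-2 ranges.
#' @return object of class `scene`.
#' @export
scene <- function(emitters, background_level = 0, extent = NULL) {
  .check_nonneg(background_level, "background_level")
  stopifnot(all(c("x_um", "y_um", "z_um", "diameter_um", "intensity") %in% names(emitters)))
  .check_nonneg(emitters$diameter_um, "diameter_um")
  .check_nonneg(emitters$intensity, "intensity")
  if (is.null(extent)) {
    extent <- list(x = range(emitters$x_um), y = range(emitters$y_um),
                   z = range(emitters$z_um))
  }
  structure(list(emitters = tibble::as_tibble(emitters),
                 background_level = background_level, extent = extent),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d emitters, z in [%g, %g] um, background %g\n",
              nrow(x$emitters), min(x$emitters$z_um), max(x$emitters$z_um),
              x$background_level))
  invisible(x)
}

#' Multi-layer fluorescent bead phantom
#'
#' Beads placed uniformly at random in each layer, with rejection sampling to
#' keep bead centres at least one diameter apart. Layer depths are recorded
#' as ground truth in attribute `"layer_z_um"`. Default layer spacing of
#' 170 um corresponds to stacked #1.5 coverslips.
#'
#' @param n_layers number of layers.
#' @param beads_per_layer beads in each layer.
#' @param layer_spacing axial spacing between layers (um).
#' @param bead_diameter bead diameter (um); default 15.4.
#' @param lateral_extent half-width of the lateral placement square (um).
#' @param z_center depth of the middle of the layer set (um).
#' @param intensity per-bead flux.
#' @param seed RNG seed (reproducibility contract).
#' @return a `scene`.
#' @export
bead_layers_phantom <- function(n_layers = 3, beads_per_layer = 12,
                                layer_spacing = 170, bead_diameter = 15.4,
                                lateral_extent = 250, z_center = 3000,
                                intensity = 1, seed = 1) {
  stopifnot(n_layers >= 1, beads_per_layer >= 1, layer_spacing >= 0)
  zs <- z_center + (seq_len(n_layers) - (n_layers + 1) / 2) * layer_spacing
  place_layer <- function(z) {
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(pts) < beads_per_layer) {
      p <- stats::runif(2, -lateral_extent, lateral_extent)
      if (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - p)^2))) > bead_diameter) {
        pts <- rbind(pts, p)
      }
      tries <- tries + 1
      if (tries > 1000 * beads_per_layer) {
        .clf_error("lateral extent too small to place beads without overlap",
                   "clf_placement_error")
      }
    }
    tibble::tibble(x_um = pts[, 1], y_um = pts[, 2], z_um = z,
                   diameter_um = bead_diameter, intensity = intensity)
  }
  em <- withr::with_seed(seed, do.call(rbind, lapply(zs, place_layer)))
  out <- scene(em, extent = list(x = c(-1, 1) * lateral_extent,
                                 y = c(-1, 1) * lateral_extent, z = range(zs)))
  attr(out, "layer_z_um") <- zs
  attr(out, "seed") <- seed
  out
}

#' PSF calibration stack: one on-axis bead per depth
#'
#' One single-emitter scene per depth step, emitter on the central axis —
#' the synthetic counterpart of translating a 2.5 um bead along z.
#'
#' @param zrange a [depth_range()] (default 2-4 mm in 100 um steps).
#' @param bead_diameter bead diameter (um); default 2.5.
#' @param intensity bead flux.
#' @return list of `list(z = depth_um, scene = scene)`.
#' @export
psf_calibration_stack_scene <- function(zrange = depth_range(),
                                        bead_diameter = 2.5, intensity = 1) {
  zs <- depth_samples(zrange)
  lapply(zs, function(z) {
    list(z = z, scene = scene(tibble::tibble(
      x_um = 0, y_um = 0, z_um = z, diameter_um = bead_diameter,
      intensity = intensity)))
  })
}

#' Planar grid target scene
#'
#' A square lattice of point emitters at one depth, the synthetic counterpart
#' of a 100 um grid target, used for field-of-view, magnification and
#' autofocus tests.
#'
#' @param pitch lattice pitch (um); default 100.
#' @param extent full lateral width of the target (um).
#' @param z target depth (um).
#' @param intensity per-node flux.
#' @return a `scene`; emitter count is `(floor(extent/pitch) + 1)^2`.
#' @export
grid_target_scene <- function(pitch = 100, extent = 400, z = 3000,
                              intensity = 1) {
  .check_pos(pitch, "pitch")
  m <- floor(extent / pitch)
  xs <- (seq_len(m + 1) - 1 - m / 2) * pitch
  g <- expand.grid(x_um = xs, y_um = xs)
  scene(tibble::tibble(x_um = g$x_um, y_um = g$y_um, z_um = z,
                       diameter_um = 0, intensity = intensity))
}

#' Poisson + Gaussian sensor-noise model
#'
#' Shot noise at `photon_scale` photons per intensity unit, then additive
#' Gaussian read noise, then a constant offset. `photon_scale = 0` disables
#' shot noise.
#'
#' @param photon_scale photons per intensity unit (Poisson scaling).
#' @param read_sigma read-noise standard deviation (intensity units).
#' @param offset constant offset added last.
#' @param seed RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 0, read_sigma = 0, offset = 0, seed = 1) {
  .check_nonneg(photon_scale, "photon_scale")
  .check_nonneg(read_sigma, "read_sigma")
  .check_nonneg(offset, "offset")
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 offset = offset, seed = seed), class = "noise_model")
}

#' Apply a noise model to a capture frame
#'
#' @param frame a `capture_frame`.
#' @param model a [noise_model()].
#' @return noisy `capture_frame`; per-pixel variance is approximately
#'   mean/photon_scale + read_sigma^2.
#' @export
add_noise <- function(frame, model) {
  img <- frame$image
  out <- withr::with_seed(model$seed, {
    x <- img
    if (model$photon_scale > 0) {
      x <- matrix(stats::rpois(length(img), img * model$photon_scale),
                  nrow(img)) / model$photon_scale
    }
    if (model$read_sigma > 0) {
      x <- x + matrix(stats::rnorm(length(img), 0, model$read_sigma), nrow(img))
    }
    x + model$offset
  })
  frame$image <- out
  frame$metadata$noise <- model[c("photon_scale", "read_sigma", "offset", "seed")]
  frame
}

# ---- forward rendering ------------------------------------------------------

# Default sensor-plane PSF FWHM (um) for the fast Gaussian rendering path.
# Value from psf_kernel_at_depth() for the default log-axicon central lenslet
# at the 3 mm design depth (see the methods vignette).
.default_psf_fwhm_um <- 5.0

#' Construct a capture frame
#'
#' @param image numeric matrix (rows = y) of sensor values.
#' @param pixel_pitch pixel pitch (um).
#' @param metadata free-form list (depth tag, seed, ...).
#' @return object of class `capture_frame`.
#' @export
capture_frame <- function(image, pixel_pitch, metadata = list()) {
  structure(list(image = image, pixel_pitch = pixel_pitch, metadata = metadata),
            class = "capture_frame")
}

#' @export
print.capture_frame <- function(x, ...) {
  cat(sprintf("<capture_frame> %d x %d px @ %g um, sum %.4g\n",
              nrow(x$image), ncol(x$image), x$pixel_pitch, sum(x$image)))
  invisible(x)
}

# um -> pixel coordinate (1-based, centre of sensor at (W+1)/2).
.um_to_px <- function(u_um, n_px, pitch) u_um / pitch + (n_px + 1) / 2

# Separable blur with a 1D kernel g (odd length), zero-padded borders.
.sep_blur <- function(m, g) {
  J <- (length(g) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  mp <- rbind(matrix(0, J, W), m, matrix(0, J, W))
  out <- matrix(0, H, W)
  for (j in -J:J) out <- out + g[j + J + 1] * mp[(1 + J + j):(H + J + j), , drop = FALSE]
  mp <- cbind(matrix(0, H, J), out, matrix(0, H, J))
  out <- matrix(0, H, W)
  for (j in -J:J) out <- out + g[j + J + 1] * mp[, (1 + J + j):(W + J + j), drop = FALSE]
  out
}

# Build (and cache) a fine-grid stamp for a bead: geometric disk image of
# diameter m(z)*bead convolved with a Gaussian PSF of the given sensor-plane
# FWHM, sampled at pitch/fine. Returns a unit-sum matrix with odd dims.
.bead_stamp_fine <- function(d_img_um, fwhm_um, pitch, fine = 8L,
                             cache = NULL, key = NULL) {
  if (!is.null(cache) && !is.null(key) && !is.null(cache[[key]])) return(cache[[key]])
  fp <- pitch / fine
  sigma <- fwhm_um / 2.3548
  Rs <- d_img_um / 2 + 3.5 * sigma + 1.5 * pitch
  K <- as.integer(ceiling(Rs / fp))
  xs <- (-K:K) * fp
  r2 <- outer(xs^2, xs^2, `+`)
  stamp <- if (d_img_um < fp) {
    if (sigma > 0) exp(-r2 / (2 * sigma^2)) else (r2 == 0) * 1
  } else {
    disk <- (r2 <= (d_img_um / 2)^2) * 1
    if (sigma > 0) {
      J <- max(1L, as.integer(ceiling(3 * sigma / fp)))
      g <- stats::dnorm((-J:J) * fp, sd = sigma)
      disk <- .sep_blur(disk, g / sum(g))
    }
    disk
  }
  stamp <- stamp / sum(stamp)
  if (!is.null(cache) && !is.null(key)) cache[[key]] <- stamp
  stamp
}

# Add `intensity * (stamp binned to sensor pixels)` into `img`, centred at the
# fractional pixel position (px, py). Sub-pixel placement is by integer
# fine-cell shift, so the worst-case centroid error is pitch / (2 * fine).
.place_stamp <- function(img, stamp_fine, px, py, intensity, fine = 8L) {
  K <- (nrow(stamp_fine) - 1L) %/% 2L
  c0x <- as.integer(round(px)); c0y <- as.integer(round(py))
  rx <- px - c0x; ry <- py - c0y
  hp <- as.integer(ceiling((K + fine) / fine)) + 1L
  nf <- (2L * hp + 1L) * fine
  # fine coordinate of the canvas-centre pixel's centre
  ctr <- hp * fine + (fine + 1) / 2
  icx <- as.integer(round(ctr + rx * fine))
  icy <- as.integer(round(ctr + ry * fine))
  fa <- matrix(0, nf, nf)
  fa[(icy - K):(icy + K), (icx - K):(icx + K)] <- stamp_fine
  coarse <- .bin_sum(fa, fine)
  H <- nrow(img); W <- ncol(img)
  rows <- (c0y - hp):(c0y + hp)
  cols <- (c0x - hp):(c0x + hp)
  rok <- rows >= 1 & rows <= H; cok <- cols >= 1 & cols <= W
  img[rows[rok], cols[cok]] <- img[rows[rok], cols[cok]] +
    intensity * coarse[rok, cok, drop = FALSE]
  img
}

#' Render a full-sensor capture frame of a scene
#'
#' Each emitter is projected through every non-occluded lenslet
#' ([project_point()]), stamped as a geometric bead image (diameter scaled by
#' the depth magnification) convolved with the PSF, and accumulated into one
#' sensor frame. The fast default PSF is a Gaussian whose sensor-plane FWHM
#' comes from the wave-optics module's kernel for the log-axicon lenslet
#' (`psf_source = "wave_optics"` uses full simulated kernels instead).
#' Stamps are unit-normalized, so the noiseless frame energy equals
#' sum(intensity x number of contributing lenslets). Emitters outside every
#' field-of-view window contribute nothing and are counted in metadata
#' `$clipped`.
#'
#' @param scn a `scene`.
#' @param array an `array_spec`.
#' @param psf_source `"gaussian"` (fast default) or `"wave_optics"`.
#' @param psf_fwhm sensor-plane PSF FWHM (um) for the Gaussian path.
#' @param noise optional [noise_model()].
#' @param psf_n grid size for the wave-optics kernel path.
#' @return a `capture_frame`.
#' @export
render_capture <- function(scn, array, psf_source = c("gaussian", "wave_optics"),
                           psf_fwhm = .default_psf_fwhm_um, noise = NULL,
                           psf_n = 512) {
  psf_source <- match.arg(psf_source)
  sen <- array$sensor
  H <- sen$height_px; W <- sen$width_px; pitch <- sen$pixel_pitch
  img <- matrix(scn$background_level, H, W)
  cache <- new.env(parent = emptyenv())
  em <- scn$emitters
  clipped <- 0L
  kern_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(em))) {
    z <- em$z_um[i]
    m <- magnification_at_depth(array, z)
    d_img <- m * em$diameter_um[i]
    contributing <- 0L
    for (l in array$lenslets) {
      pr <- project_point(array, l$id, c(em$x_um[i], em$y_um[i], z))
      if (pr$occluded) next
      px <- .um_to_px(pr$x_um, W, pitch); py <- .um_to_px(pr$y_um, H, pitch)
      if (px < 1 || px > W || py < 1 || py > H) next
      if (psf_source == "gaussian") {
        key <- sprintf("g|%.2f|%.3f", z, d_img)
        st <- .bead_stamp_fine(d_img, psf_fwhm, pitch, cache = cache, key = key)
      } else {
        key <- sprintf("w|%d|%.2f|%.3f", l$id, z, d_img)
        st <- cache[[key]]
        if (is.null(st)) {
          kk <- sprintf("k|%d|%.2f", l$id, z)
          kn <- kern_cache[[kk]]
          if (is.null(kn)) {
            prof <- log_axicon_phase(l$diameter / 2, l$focal_min, l$focal_max)
            kn <- psf_kernel_at_depth(prof, z, array, n = psf_n)
            kern_cache[[kk]] <- kn
          }
          st <- .bead_stamp_fine(d_img, max(kn$fwhm_um, 1e-3), pitch,
                                 cache = cache, key = key)
        }
      }
      img <- .place_stamp(img, st, px, py, em$intensity[i])
      contributing <- contributing + 1L
    }
    if (contributing == 0L) clipped <- clipped + 1L
  }
  fr <- capture_frame(img, pitch,
                      metadata = list(clipped = clipped,
                                      psf_source = psf_source,
                                      psf_fwhm_um = psf_fwhm,
                                      n_emitters = nrow(em)))
  if (!is.null(noise)) fr <- add_noise(fr, noise)
  fr
}

#' Render the white-light aperture-mask frame
#'
#' Uniform bright disks at each lenslet's stop-limited elemental footprint:
#' the projection of the stop disk through each lenslet vertex onto the
#' sensor (centre `vertex * (1 + d_s/h)`, radius `(a/2) * d_s/h`). Edges are
#' antialiased over one pixel. Overlapping footprints (e.g. with the stop
#' removed) raise a warning, since the stop exists precisely to prevent
#' elemental-image overlap.
#'
#' @param array an `array_spec`.
#' @return a `capture_frame` (values in [0, 1]).
#' @export
render_aperture_frame <- function(array) {
  sen <- array$sensor
  H <- sen$height_px; W <- sen$width_px; pitch <- sen$pixel_pitch
  h <- array$stop$height_above_lenslets
  if (h <= 0) {
    warning("stop at the lenslet plane: footprints unbounded and overlapping")
    return(capture_frame(matrix(1, H, W), pitch, metadata = list(overlap = TRUE)))
  }
  ds <- array$sensor_distance
  rad <- (array$stop$diameter / 2) * ds / h
  ctrs <- t(vapply(array$lenslets, function(l) l$center * (1 + ds / h), numeric(2)))
  # overlap check
  overlap <- FALSE
  for (i in 1:(nrow(ctrs) - 1)) for (j in (i + 1):nrow(ctrs)) {
    if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) < 2 * rad) overlap <- TRUE
  }
  if (overlap) warning("elemental footprints overlap on the sensor")
  xs <- (seq_len(W) - (W + 1) / 2) * pitch
  ys <- (seq_len(H) - (H + 1) / 2) * pitch
  img <- matrix(0, H, W)
  for (i in seq_len(nrow(ctrs))) {
    d <- sqrt(outer((ys - ctrs[i, 2])^2, (xs - ctrs[i, 1])^2, `+`))
    img <- pmax(img, pmin(1, pmax(0, (rad - d) / pitch + 0.5)))
  }
  capture_frame(img, pitch, metadata = list(overlap = overlap,
                                            footprint_radius_um = rad))
}
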