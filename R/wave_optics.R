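# Scalar-diffraction model of logarithmic-axicon and spherical lenslets.
#
# The logarithmic axicon follows the uniform-axial-intensity design: radial
# zones map quadratically to focal length, f(r) = f_min + (f_max - f_min) r^2 / R^2,
# giving the phase phi(r) = -(k / 2 alpha) * log(1 + alpha r^2 / f_min) with
# alpha = (f_max - f_min) / R^2 and k = 2 pi / lambda, normalized so phi(0) = 0.
# Each annulus then focuses at f(r) (d phi/d r = -k r / f(r)), spreading the
# focus into a continuous axial segment of near-uniform intensity.
# Wavelengths are given in nm at the interface and held in um internally.

#' Radial phase profile of a lenslet
#'
#' `log_axicon_phase()` builds the logarithmic-axicon profile for a focal
#' range; with `focal_max == focal_min` it degenerates to the paraxial
#' spherical phase -k r^2 / (2 f). `spherical_phase()` builds the exact
#' spherical converging phase -k (sqrt(r^2 + f^2) - f).
#'
#' @param aperture_radius lenslet semi-aperture (um).
#' @param focal_min,focal_max focal range (um).
#' @param wavelength wavelength (nm).
#' @param n_samples length of the tabulated radial lookup.
#' @return object of class `phase_profile` with fields `kind`,
#'   `aperture_radius`, `focal_min`, `focal_max`, `wavelength_um`, `samples`
#'   (tibble r_um, phase_rad) and evaluator `phase(r)`.
#' @export
log_axicon_phase <- function(aperture_radius, focal_min, focal_max,
                             wavelength = 635, n_samples = 1024) {
  .check_pos(aperture_radius, "aperture_radius")
  .check_pos(focal_min, "focal_min")
  if (focal_max < focal_min) .clf_error("focal_max must be >= focal_min", "clf_invalid_parameter")
  lam <- wavelength / 1000
  k <- 2 * pi / lam
  alpha <- (focal_max - focal_min) / aperture_radius^2
  phase <- if (alpha == 0) {
    function(r) -k * r^2 / (2 * focal_min)
  } else {
    function(r) -(k / (2 * alpha)) * log1p(alpha * r^2 / focal_min)
  }
  .phase_profile("log_axicon", aperture_radius, focal_min, focal_max, lam,
                 phase, n_samples)
}

#' @rdname log_axicon_phase
#' @param focal single focal length of the spherical lens (um).
#' @export
spherical_phase <- function(aperture_radius, focal, wavelength = 635,
                            n_samples = 1024) {
  .check_pos(aperture_radius, "aperture_radius")
  .check_pos(focal, "focal")
  lam <- wavelength / 1000
  k <- 2 * pi / lam
  phase <- function(r) -k * (sqrt(r^2 + focal^2) - focal)
  .phase_profile("spherical", aperture_radius, focal, focal, lam, phase, n_samples)
}

.phase_profile <- function(kind, R, fmin, fmax, lam, phase, n_samples) {
  r <- seq(0, R, length.out = n_samples)
  structure(list(kind = kind, aperture_radius = R, focal_min = fmin,
                 focal_max = fmax, wavelength_um = lam,
                 samples = tibble::tibble(r_um = r, phase_rad = phase(r)),
                 phase = phase),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  cat(sprintf("<phase_profile> %s, R = %g um, f = [%g, %g] um, lambda = %g nm\n",
              x$kind, x$aperture_radius, x$focal_min, x$focal_max,
              x$wavelength_um * 1000))
  invisible(x)
}

#' Surface sag of a phase profile
#'
#' Converts phase delay to resist surface height via
#' sag = (phase - min(phase)) * lambda / (2 pi (n - 1)); a converging
#' profile is thickest on axis, where its phase delay is largest.
#'
#' @param profile a `phase_profile`.
#' @param refractive_index resist index (default 1.51).
#' @return tibble with columns `r_um`, `phase_rad`, `sag_um`.
#' @export
profile_sag <- function(profile, refractive_index = 1.51) {
  s <- profile$samples
  s$sag_um <- (s$phase_rad - min(s$phase_rad)) * profile$wavelength_um /
    (2 * pi * (refractive_index - 1))
  s
}

# ---- field grids and propagation -------------------------------------------

#' Complex field on a regular grid
#'
#' @param field complex (or numeric) square matrix of amplitudes.
#' @param pitch sample pitch (um).
#' @param wavelength wavelength (nm).
#' @return object of class `field_grid`.
#' @export
field_grid <- function(field, pitch, wavelength = 635) {
  .check_pos(pitch, "pitch")
  if (!is.matrix(field)) .clf_error("field must be a matrix", "clf_invalid_parameter")
  structure(list(field = field + 0i, pitch = pitch,
                 wavelength_um = wavelength / 1000),
            class = "field_grid")
}

#' Plane-wave or point-source illumination of a phase profile
#'
#' Builds the field just after the lenslet: unit amplitude inside the
#' aperture, zero outside, carrying the lens phase plus (for a point source at
#' depth `z_src`) the exact incident spherical phase k sqrt(r^2 + z^2). The
#' two phases are combined analytically before sampling so only the slowly
#' varying net phase must be resolved by the grid; construction warns if the
#' net phase advances more than pi radians per sample (Nyquist).
#'
#' @param profile a `phase_profile`.
#' @param n grid size (n x n).
#' @param pitch sample pitch (um); default spans three aperture diameters
#'   (one aperture of guard band on each side).
#' @param z_src point-source depth (um) or `NULL` for plane-wave illumination.
#' @return a `field_grid`.
#' @export
illuminate <- function(profile, n = 2048, pitch = NULL, z_src = NULL) {
  R <- profile$aperture_radius
  if (is.null(pitch)) pitch <- 6 * R / n
  xs <- (seq_len(n) - (n + 1) / 2) * pitch
  r2 <- outer(xs^2, xs^2, `+`)
  r <- sqrt(r2)
  k <- 2 * pi / profile$wavelength_um
  ph <- profile$phase(r)
  if (!is.null(z_src)) {
    .check_pos(z_src, "z_src")
    ph <- ph + k * (sqrt(r2 + z_src^2) - z_src)
  }
  amp <- r <= R
  # Nyquist check on the net radial phase gradient at the aperture edge
  fedge <- if (profile$kind == "log_axicon") profile$focal_max else profile$focal_min
  g <- k * R * abs(1 / fedge - if (is.null(z_src)) 0 else 1 / z_src)
  if (g * pitch > pi) {
    warning(sprintf("phase undersampled: %.2f rad/sample at the aperture edge", g * pitch))
  }
  field_grid(amp * exp(1i * ph), pitch, profile$wavelength_um * 1000)
}

#' Angular-spectrum propagation of a field
#'
#' Exact scalar propagation over `distance`: multiplies the angular spectrum
#' by exp(i kz d) with kz = 2 pi sqrt(1/lambda^2 - fx^2 - fy^2); evanescent
#' components are discarded. Total power is conserved (up to evanescent loss).
#'
#' @param fg a `field_grid`.
#' @param distance propagation distance (um); may be negative.
#' @return a `field_grid` at the new plane.
#' @export
propagate_angular_spectrum <- function(fg, distance) {
  if (distance == 0) return(fg)
  n <- nrow(fg$field)
  lam <- fg$wavelength_um
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * fg$pitch)
  f2 <- outer(fx^2, fx^2, `+`)
  arg <- 1 / lam^2 - f2
  kz <- 2 * pi * sqrt(pmax(arg, 0))
  H <- exp(1i * kz * distance)
  H[arg < 0] <- 0
  Fsp <- stats::fft(fg$field)
  out <- stats::fft(Fsp * H, inverse = TRUE) / length(Fsp)
  field_grid(out, fg$pitch, lam * 1000)
}

#' Total power of a field grid
#' @param fg a `field_grid`.
#' @return sum of |field|^2 * pitch^2.
#' @export
field_power <- function(fg) sum(Mod(fg$field)^2) * fg$pitch^2

# Intensity of the central crop (half-width `hw` samples) of a field.
.center_intensity <- function(fg, hw = NULL) {
  n <- nrow(fg$field)
  c0 <- (n + 1) / 2
  if (is.null(hw)) return(Mod(fg$field)^2)
  i <- max(1, floor(c0 - hw)):min(n, ceiling(c0 + hw))
  Mod(fg$field[i, i])^2
}

# Azimuthally averaged radial intensity profile; returns the centre-referenced
# beam width 2 * min{r : P(r) < P(0)/2} (um), with linear interpolation at the
# crossing. A beam whose centre is dim relative to off-axis rings reports a
# large width, so the measure degrades monotonically under defocus.
.beam_halfwidth <- function(I, pitch) {
  n <- nrow(I)
  c0 <- (n + 1) / 2
  xs <- seq_len(n) - c0
  rbin <- round(sqrt(outer(xs^2, xs^2, `+`)))
  g <- as.vector(rbin)
  prof <- as.numeric(rowsum(as.vector(I), g)) /
    as.numeric(rowsum(rep(1, length(g)), g))
  p0 <- prof[1]
  below <- which(prof < p0 / 2)
  if (!length(below)) return(2 * (length(prof) - 1) * pitch)
  j <- below[1]
  if (j == 1) return(pitch)  # centre already below: degenerate, minimal width
  frac <- (prof[j - 1] - p0 / 2) / (prof[j - 1] - prof[j])
  2 * ((j - 2) + frac) * pitch
}

#' Axial response of a phase profile under plane-wave illumination
#'
#' Propagates the illuminated profile to each z and records, per plane,
#' either the on-axis intensity, the variance-of-Laplacian focus score of
#' the central patch, or the beam sharpness (minimum beam width divided by
#' the beam width at z, where width is the centre-referenced half-maximum
#' diameter of the azimuthally averaged cross-section). Every criterion is
#' normalized to maximum 1.
#'
#' @param profile a `phase_profile`.
#' @param z numeric vector of image-side distances (um).
#' @param criterion `"beam_width"`, `"on_axis_intensity"` or `"focus_score"`.
#' @param n,pitch grid parameters passed to [illuminate()].
#' @param z_src optional point-source depth (um) instead of a plane wave.
#' @param score_halfwidth half-width (samples) of the focus-score patch.
#' @return object of class `axial_response`: tibble (`z_um`, `value`) with
#'   attributes `criterion`, `raw_max` and (for `"beam_width"`) `width_um`.
#' @export
axial_response <- function(profile, z, criterion = c("beam_width",
                                                     "on_axis_intensity",
                                                     "focus_score"),
                           n = 512, pitch = NULL, z_src = NULL,
                           score_halfwidth = 128) {
  criterion <- match.arg(criterion)
  if (length(z) == 0) .clf_error("empty z range", "clf_invalid_parameter")
  f0 <- illuminate(profile, n = n, pitch = pitch, z_src = z_src)
  vals <- vapply(z, function(zz) {
    fz <- propagate_angular_spectrum(f0, zz)
    if (criterion == "on_axis_intensity") {
      max(.center_intensity(fz, 1))
    } else if (criterion == "focus_score") {
      focus_score(.center_intensity(fz, score_halfwidth))
    } else {
      .beam_halfwidth(Mod(fz$field)^2, fz$pitch)
    }
  }, numeric(1))
  if (criterion == "beam_width") {
    out <- tibble::tibble(z_um = z, value = min(vals) / vals)
    attr(out, "width_um") <- vals
    attr(out, "raw_max") <- min(vals)
  } else {
    m <- max(vals)
    out <- tibble::tibble(z_um = z, value = if (m > 0) vals / m else vals)
    attr(out, "raw_max") <- m
  }
  attr(out, "criterion") <- criterion
  class(out) <- c("axial_response", class(out))
  out
}

#' Extended-depth-of-focus range of an axial response
#'
#' Length of the contiguous z-interval containing the global maximum where the
#' normalized response stays at or above `threshold`, with linear
#' interpolation at the crossings.
#'
#' @param resp an `axial_response` (or tibble with `z_um`, `value`).
#' @param threshold fraction of the maximum (default 0.5).
#' @return length (um); 0 with a warning if the response never reaches the
#'   threshold.
#' @export
edof_range <- function(resp, threshold = 0.5) {
  v <- resp$value / max(resp$value)
  iv <- .half_max_interval(resp$z_um, v, threshold)
  if (any(is.na(iv))) {
    warning("response never reaches the threshold; zero-length range")
    return(0)
  }
  iv[2] - iv[1]
}

# Variance-of-Laplacian focus score of a binary grid target imaged through
# the system: the PSF intensity is convolved with a crossed-bar grid (fixed
# in image space) and the score is taken over a central window spanning
# several grid periods. Energy conservation across depths makes the score a
# contrast measure rather than a brightness measure.
.grid_spectrum <- function(n, pitch, grid_pitch_um = 100, bar_um = 20) {
  xs <- (seq_len(n) - 1) * pitch
  barx <- (xs %% grid_pitch_um) < bar_um
  stats::fft(outer(barx, barx, `|`) * 1)
}

.grid_image_score <- function(I, pitch, FG = NULL, crop_px = 512) {
  n <- nrow(I)
  if (is.null(FG)) FG <- .grid_spectrum(n, pitch)
  FI <- stats::fft(I)
  conv <- Re(stats::fft(FI * FG, inverse = TRUE)) / n^2
  c0 <- n %/% 2
  hw <- min(crop_px %/% 2, n %/% 2 - 1)
  win <- conv[(c0 - hw):(c0 + hw), (c0 - hw):(c0 + hw)]
  focus_score(win)
}

# Focus-score curve of the sensor-plane image of an on-axis point emitter
# (convolved with the binary grid target), for object depths z_obj, with the
# sensor fixed at `sensor_distance`.
.point_focus_curve <- function(profile, z_obj, sensor_distance, n = 1024,
                               pitch = NULL) {
  if (is.null(pitch)) pitch <- 6 * profile$aperture_radius / n
  FG <- .grid_spectrum(n, pitch)
  vapply(z_obj, function(z) {
    f0 <- illuminate(profile, n = n, pitch = pitch, z_src = z)
    fz <- propagate_angular_spectrum(f0, sensor_distance)
    I <- Mod(fz$field)^2
    .grid_image_score(I, pitch, FG)
  }, numeric(1))
}

#' Object-space extended-depth-of-focus ratio: log-axicon versus spherical
#'
#' Sweeps an on-axis point emitter through object depths, imaging it once
#' through the central logarithmic-axicon lenslet and once through an
#' equal-aperture spherical lenslet focused at the midpoint focal length,
#' with the sensor fixed at the array's sensor distance. Each depth's image
#' is scored with the variance-of-Laplacian of the simulated image of the
#' binary grid target (the default degree-of-focus measure); the in-focus
#' range of each lens is the contiguous depth interval where the score stays
#' at or above `threshold` times its maximum (crossings refined on a finer
#' grid), and the ratio of the two ranges quantifies the axicon's
#' depth-of-focus extension.
#'
#' Note that this contrast-weighted measurement also penalizes the ideal
#' axicon's depth-varying in-focus energy fraction and its coherent axial
#' oscillations, so it reports a substantially smaller extension factor than
#' the designed focal-segment ratio (the thin-lens conjugate span of the
#' focal range divided by the spherical lens's in-focus range); both views
#' are discussed in the methods vignette.
#'
#' @param array an `array_spec`.
#' @param wavelength wavelength (nm).
#' @param z_span length-2 object-depth sweep bounds (um).
#' @param coarse_step,fine_step sweep steps (um); half-max crossings are
#'   re-sampled at `fine_step`.
#' @param n simulation grid size.
#' @param threshold focus-score threshold as a fraction of the maximum.
#' @return list with `ratio`, `log_range_um`, `spherical_range_um`, the two
#'   score curves, and `conjugate_span_um` (the designed focal segment of
#'   the axicon mapped to object space).
#' @export
edof_ratio <- function(array, wavelength = 635, z_span = c(1800, 4500),
                       coarse_step = 50, fine_step = 10, n = 1024,
                       threshold = 0.5) {
  lens <- array$lenslets[[1]]
  R <- lens$diameter / 2
  prof_log <- log_axicon_phase(R, lens$focal_min, lens$focal_max, wavelength)
  f_mid <- (lens$focal_min + lens$focal_max) / 2
  prof_sph <- spherical_phase(R, f_mid, wavelength)
  ds <- array$sensor_distance

  sweep_one <- function(profile) {
    z <- seq(z_span[1], z_span[2], by = coarse_step)
    s <- .point_focus_curve(profile, z, ds, n = n)
    iv <- .half_max_interval(z, s / max(s), threshold)
    if (any(is.na(iv))) .clf_error("focus-score curve never reaches threshold",
                                   "clf_diagnostic")
    for (edge in iv) {
      zf <- seq(max(z_span[1], edge - coarse_step),
                min(z_span[2], edge + coarse_step), by = fine_step)
      zf <- setdiff(round(zf, 6), round(z, 6))
      if (length(zf)) {
        sf <- .point_focus_curve(profile, zf, ds, n = n)
        o <- order(c(z, zf))
        z <- c(z, zf)[o]; s <- c(s, sf)[o]
      }
    }
    iv <- .half_max_interval(z, s / max(s), threshold)
    list(range = iv[2] - iv[1],
         curve = tibble::tibble(z_um = z, score = s / max(s)))
  }

  lg <- sweep_one(prof_log)
  sp <- sweep_one(prof_sph)
  cr <- conjugate_object_range(lens, ds)
  list(ratio = lg$range / sp$range,
       log_range_um = lg$range, spherical_range_um = sp$range,
       conjugate_span_um = unname(cr[2] - cr[1]),
       log_curve = lg$curve, spherical_curve = sp$curve)
}

#' Sensor-plane PSF kernel for a point emitter at depth
#'
#' Propagates a point-source field through the profile to the sensor plane,
#' resamples the central patch to the sensor pixel pitch, and normalizes the
#' kernel to unit sum. The lateral FWHM is measured from the azimuthally
#' averaged radial profile.
#'
#' @param profile a `phase_profile`.
#' @param z_obj object depth (um).
#' @param array an `array_spec` (supplies sensor distance and pixel pitch).
#' @param n simulation grid size.
#' @param kernel_px kernel half-width in sensor pixels.
#' @return list with `kernel` (unit-sum matrix), `fwhm_um`, `pixel_pitch`.
#' @export
psf_kernel_at_depth <- function(profile, z_obj, array, n = 1024, kernel_px = 16) {
  cr <- conjugate_object_range(array$lenslets[[1]], array$sensor_distance)
  if (z_obj < cr[1] * 0.8 || z_obj > cr[2] * 1.2) {
    warning("z_obj outside the conjugate validity range; kernel extrapolated")
  }
  pitch <- 6 * profile$aperture_radius / n
  f0 <- illuminate(profile, n = n, pitch = pitch, z_src = z_obj)
  fz <- propagate_angular_spectrum(f0, array$sensor_distance)
  I <- Mod(fz$field)^2
  c0 <- (n + 1) / 2
  p_sens <- array$sensor$pixel_pitch
  xs <- (-kernel_px):kernel_px
  qx <- rep(c0 + xs * p_sens / pitch, each = length(xs))
  qy <- rep(c0 + xs * p_sens / pitch, times = length(xs))
  K <- matrix(sample_bilinear(I, qx, qy), length(xs), length(xs))
  K[K < 0] <- 0
  # FWHM from the fine-grid radial profile (not pixel-limited)
  hw <- min(n %/% 2 - 1, round(60 / pitch))
  i <- (c0 - hw):(c0 + hw)
  prof_x <- I[round(c0), i]
  iv <- .half_max_interval((i - c0) * pitch, prof_x / max(prof_x), 0.5)
  list(kernel = K / sum(K), fwhm_um = iv[2] - iv[1], pixel_pitch = p_sens)
}
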