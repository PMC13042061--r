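# Geometric model of the concave seven-lenslet compound array.
#
# Coordinate convention: origin at the central lenslet vertex, +z toward the
# object, sensor plane at z = -sensor_distance. All lengths in micrometres.
# Projection uses the thin-pinhole chief-ray model: each lenslet acts as a
# pinhole at its vertex; diffraction blur is supplied separately by the wave
# optics module.

#' Specify a single lenslet
#'
#' @param id integer lenslet id (1 = central by convention).
#' @param center numeric length-2, lenslet vertex position in the array plane (um).
#' @param diameter aperture diameter (um).
#' @param focal_min,focal_max focal range of the logarithmic-axicon profile (um);
#'   equal values describe an ordinary (single-focus) lenslet.
#' @param tilt_deg tilt of the optical axis from +z (degrees); 0 for the
#'   central lenslet.
#' @param tilt_azimuth_deg azimuth of the tilt direction (degrees, toward the
#'   array centre for a concave array).
#' @return an object of class `lenslet_spec`.
#' @export
lenslet_spec <- function(id, center, diameter, focal_min, focal_max,
                         tilt_deg = 0, tilt_azimuth_deg = 0) {
  .check_pos(diameter, "diameter")
  .check_pos(focal_min, "focal_min")
  if (focal_max < focal_min) .clf_error("focal_max must be >= focal_min", "clf_invalid_parameter")
  structure(list(id = as.integer(id), center = as.numeric(center),
                 diameter = diameter, focal_min = focal_min, focal_max = focal_max,
                 tilt_deg = tilt_deg, tilt_azimuth_deg = tilt_azimuth_deg),
            class = "lenslet_spec")
}

#' Sensor description
#'
#' Defaults follow the OV5647 datasheet (2592 x 1944 pixels, 1.4 um pitch).
#' `binning` trades resolution for speed in simulations: pitch scales by the
#' factor and pixel counts divide by it.
#'
#' @param pixel_pitch pixel pitch (um).
#' @param width_px,height_px sensor size in pixels.
#' @param channels 1 (fluorescence) or 3 (brightfield RGB).
#' @return object of class `sensor_spec`.
#' @export
sensor_spec <- function(pixel_pitch = 1.4, width_px = 2592L, height_px = 1944L,
                        channels = 1L) {
  .check_pos(pixel_pitch, "pixel_pitch")
  .check_pos(width_px, "width_px"); .check_pos(height_px, "height_px")
  if (!channels %in% c(1L, 3L)) .clf_error("channels must be 1 or 3", "clf_invalid_parameter")
  structure(list(pixel_pitch = pixel_pitch, width_px = as.integer(width_px),
                 height_px = as.integer(height_px), channels = as.integer(channels)),
            class = "sensor_spec")
}

#' @rdname sensor_spec
#' @param binning integer binning factor applied to the full-resolution sensor.
#' @export
ov5647_sensor <- function(binning = 1L) {
  sensor_spec(1.4 * binning, 2592L %/% binning, 1944L %/% binning, 1L)
}

#' Field-stop (housing aperture) description
#'
#' The single aperture above the lenslets that limits every lenslet's field of
#' view and keeps the elemental images from overlapping on the sensor.
#' The stop height is not a catalogue value; the default of 2 mm is the
#' smallest round value at which the seven elemental footprints remain
#' disjoint for the default geometry (see the methods vignette).
#'
#' @param diameter stop diameter (um); default 600 um.
#' @param height_above_lenslets stop height above the lenslet plane (um).
#' @return object of class `aperture_spec`.
#' @export
aperture_spec <- function(diameter = 600, height_above_lenslets = 2000) {
  .check_pos(diameter, "diameter")
  .check_nonneg(height_above_lenslets, "height_above_lenslets")
  structure(list(diameter = diameter,
                 height_above_lenslets = height_above_lenslets),
            class = "aperture_spec")
}

#' Depth range specification
#'
#' @param z_min,z_max object distances above the lenslet plane (um).
#' @param step depth step (um).
#' @return object of class `depth_range`.
#' @export
depth_range <- function(z_min = 2000, z_max = 4000, step = 100) {
  .check_pos(z_min, "z_min"); .check_pos(step, "step")
  if (z_max <= z_min) .clf_error("z_max must exceed z_min", "clf_invalid_parameter")
  structure(list(z_min = z_min, z_max = z_max, step = step), class = "depth_range")
}

#' @rdname depth_range
#' @param x a `depth_range`.
#' @export
depth_samples <- function(x) seq(x$z_min, x$z_max, by = x$step)

#' Build the concave seven-lenslet compound array
#'
#' One central lenslet plus six on a hexagonal ring, all sharing a sensor at
#' `sensor_distance` below the array plane. The ring lenslets are tilted so
#' their optical axes converge on the central axis at `intersection_distance`;
#' by default the tilt is computed from the geometry
#' (arctan(ring_radius / intersection_distance), 7.031 degrees for the default
#' 370 um ring and 3 mm intersection). Pass `tilt_deg` explicitly to model a
#' nominal design tilt instead; construction fails if the stated tilt leaves
#' the axes more than 1% of the intersection distance from a common point.
#'
#' @param ring_radius radius of the hexagonal ring (um); default equals the
#'   lenslet diameter (close packing of the 1.1 mm array).
#' @param intersection_distance convergence distance of the tilted axes above
#'   the array (um).
#' @param sensor_distance sensor plane distance below the array (um).
#' @param lens_diameter lenslet aperture diameter (um).
#' @param focal_central,focal_edge length-2 focal ranges (um) of the central
#'   and ring lenslets.
#' @param tilt_deg ring-lenslet tilt (degrees); `NULL` (default) computes it
#'   from the geometry.
#' @param sensor a [sensor_spec()].
#' @param stop a [aperture_spec()].
#' @return object of class `array_spec`.
#' @export
compound_array <- function(ring_radius = 370, intersection_distance = 3000,
                           sensor_distance = 3000, lens_diameter = 370,
                           focal_central = c(1250, 1750),
                           focal_edge = c(1500, 2000),
                           tilt_deg = NULL,
                           sensor = ov5647_sensor(2L),
                           stop = aperture_spec()) {
  .check_pos(ring_radius, "ring_radius")
  .check_pos(intersection_distance, "intersection_distance")
  .check_pos(sensor_distance, "sensor_distance")
  if (is.null(tilt_deg)) {
    tilt_deg <- tilt_for_intersection(ring_radius, intersection_distance)
  }
  ang <- seq(0, 300, by = 60) * pi / 180
  lenslets <- vector("list", 7L)
  lenslets[[1]] <- lenslet_spec(1L, c(0, 0), lens_diameter,
                                focal_central[1], focal_central[2], 0, 0)
  for (k in seq_len(6L)) {
    ctr <- ring_radius * c(cos(ang[k]), sin(ang[k]))
    lenslets[[k + 1L]] <- lenslet_spec(k + 1L, ctr, lens_diameter,
                                       focal_edge[1], focal_edge[2],
                                       tilt_deg, (ang[k] * 180 / pi + 180) %% 360)
  }
  arr <- structure(list(lenslets = lenslets, ring_radius = ring_radius,
                        intersection_distance = intersection_distance,
                        sensor_distance = sensor_distance,
                        sensor = sensor, stop = stop),
                   class = "array_spec")
  conv <- axes_convergence(arr)
  if (conv > 0.01 * intersection_distance) {
    .clf_error(sprintf("optical axes miss the intersection point by %.1f um (> 1%% of %.0f um)",
                       conv, intersection_distance), "clf_invalid_parameter")
  }
  arr
}

#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf("<array_spec> %d lenslets, ring %g um, intersection %g um, sensor %g um below\n",
              length(x$lenslets), x$ring_radius, x$intersection_distance, x$sensor_distance))
  cat(sprintf("  sensor: %d x %d px @ %g um; stop: %g um dia @ %g um height\n",
              x$sensor$width_px, x$sensor$height_px, x$sensor$pixel_pitch,
              x$stop$diameter, x$stop$height_above_lenslets))
  invisible(x)
}

#' Geometric numerical aperture of a lenslet
#'
#' NA = sin(arctan((D/2)/f)) for aperture diameter D and focal length f.
#'
#' @param lens a [lenslet_spec()].
#' @param focal focal length at which to evaluate (um); defaults to
#'   `lens$focal_max` (the marginal focus of the axicon profile).
#' @return dimensionless numerical aperture.
#' @export
lenslet_na <- function(lens, focal = lens$focal_max) {
  .check_pos(focal, "focal")
  .check_pos(lens$diameter, "diameter")
  sin(atan((lens$diameter / 2) / focal))
}

#' Ring tilt required for axis convergence
#'
#' @param ring_radius ring radius (um); 0 gives the untilted central lenslet.
#' @param intersection_distance convergence distance (um).
#' @return tilt angle in degrees.
#' @export
tilt_for_intersection <- function(ring_radius, intersection_distance) {
  .check_nonneg(ring_radius, "ring_radius")
  .check_pos(intersection_distance, "intersection_distance")
  atan(ring_radius / intersection_distance) * 180 / pi
}

#' Pinhole magnification at an object depth
#'
#' m(z) = sensor_distance / z; strictly decreasing in z. The design midpoint
#' (z equal to the sensor distance) gives unit magnification.
#'
#' @param array an `array_spec`.
#' @param z object depth(s) above the array plane (um).
#' @return magnification(s).
#' @export
magnification_at_depth <- function(array, z) {
  .check_pos(z, "z")
  array$sensor_distance / z
}

#' Depth-averaged magnification over a range (closed form)
#'
#' mean of d_s/z over [z_min, z_max] = d_s * log(z_max/z_min) / (z_max - z_min).
#'
#' @param array an `array_spec`.
#' @param z_min,z_max depth range (um).
#' @return mean magnification.
#' @export
mean_magnification <- function(array, z_min = 2000, z_max = 4000) {
  .check_pos(z_min, "z_min"); .check_pos(z_max, "z_max")
  array$sensor_distance * log(z_max / z_min) / (z_max - z_min)
}

#' Object-side conjugate range of a lenslet
#'
#' Thin-lens conjugates u with 1/u = 1/f - 1/v evaluated at the two ends of
#' the focal range, for a sensor fixed at distance v. These bracket the depths
#' that some radial zone of the axicon images sharply onto the sensor.
#'
#' @param lens a [lenslet_spec()].
#' @param sensor_distance image-side distance v (um).
#' @return named numeric `c(z_near, z_far)` (um).
#' @export
conjugate_object_range <- function(lens, sensor_distance) {
  if (sensor_distance <= lens$focal_max) {
    .clf_error("sensor_distance must exceed focal_max for real conjugates",
               "clf_no_real_conjugate")
  }
  u <- function(f) 1 / (1 / f - 1 / sensor_distance)
  c(z_near = u(lens$focal_min), z_far = u(lens$focal_max))
}

.get_lens <- function(array, lens_id) {
  ids <- vapply(array$lenslets, `[[`, integer(1), "id")
  i <- match(lens_id, ids)
  if (is.na(i)) .clf_error(sprintf("unknown lens_id %s", lens_id), "clf_lookup_error")
  array$lenslets[[i]]
}

#' Chief-ray projection of object points through one lenslet
#'
#' Projects 3D object points through the lenslet vertex (pinhole model) onto
#' the sensor plane, and marks points whose chief ray misses the field-stop
#' disk as occluded.
#'
#' @param array an `array_spec`.
#' @param lens_id lenslet id.
#' @param points numeric length-3 vector or n x 3 matrix of (x, y, z) object
#'   positions (um), z > 0.
#' @return tibble with columns `x_um`, `y_um` (sensor-plane position) and
#'   `occluded`.
#' @export
project_point <- function(array, lens_id, points) {
  lens <- .get_lens(array, lens_id)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  z <- points[, 3]
  .check_pos(z, "z")
  ds <- array$sensor_distance
  cx <- lens$center[1]; cy <- lens$center[2]
  # sensor intersection: continue the ray (point -> vertex) to z = -ds
  ts <- (z + ds) / z
  sx <- points[, 1] + ts * (cx - points[, 1])
  sy <- points[, 2] + ts * (cy - points[, 2])
  # stop-plane crossing at z = h
  h <- array$stop$height_above_lenslets
  occl <- rep(FALSE, length(z))
  if (h > 0) {
    tq <- (z - h) / z
    qx <- points[, 1] + tq * (cx - points[, 1])
    qy <- points[, 2] + tq * (cy - points[, 2])
    occl <- (qx^2 + qy^2) > (array$stop$diameter / 2)^2
    occl[z < h] <- FALSE   # rays from below the stop plane never cross it
  }
  tibble::tibble(x_um = sx, y_um = sy, occluded = occl)
}

#' Elemental-image reference centre of a lenslet
#'
#' The sensor-plane point where the lenslet's (converging) optical axis meets
#' the sensor: the projection of the axis-intersection point.
#'
#' @inheritParams project_point
#' @return numeric length-2 (um).
#' @export
elemental_center <- function(array, lens_id) {
  p <- project_point(array, lens_id, c(0, 0, array$intersection_distance))
  c(p$x_um, p$y_um)
}

#' Worst-case distance of the optical axes from the intersection point
#'
#' @param array an `array_spec`.
#' @return maximum distance (um) of any lenslet axis from the point
#'   (0, 0, intersection_distance).
#' @export
axes_convergence <- function(array) {
  Q <- c(0, 0, array$intersection_distance)
  d <- vapply(array$lenslets, function(l) {
    th <- l$tilt_deg * pi / 180; az <- l$tilt_azimuth_deg * pi / 180
    dir <- c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
    P0 <- c(l$center, 0)
    v <- Q - P0
    sqrt(max(0, sum(v^2) - sum(v * dir)^2))
  }, numeric(1))
  max(d)
}

#' Per-lenslet object-plane field-of-view windows at a depth
#'
#' An object point is visible to a lenslet if its chief ray passes the stop
#' disk; by similar triangles through the stop plane the visible window at
#' depth z is a disk of diameter `stop_diameter * z / h` centred at
#' `center * (1 - z/h)`, with h the stop height. A degenerate stop (diameter
#' 0) yields empty windows; a stop at height 0 leaves the view unrestricted
#' (windows of infinite radius).
#'
#' @param array an `array_spec`.
#' @param z object depth (um), scalar.
#' @return tibble with columns `lens_id`, `cx_um`, `cy_um`, `radius_um`.
#' @export
fov_windows_at_depth <- function(array, z) {
  .check_pos(z, "z")
  h <- array$stop$height_above_lenslets
  a <- array$stop$diameter
  out <- lapply(array$lenslets, function(l) {
    if (h == 0) {
      ctr <- c(0, 0); r <- Inf
    } else {
      ctr <- l$center * (1 - z / h)
      r <- (a / 2) * z / h
    }
    tibble::tibble(lens_id = l$id, cx_um = ctr[1], cy_um = ctr[2], radius_um = r)
  })
  do.call(rbind, out)
}

# Rasterized lenslet-coverage counts over the object plane at depth z.
# Returns list(counts = integer matrix, pixel_um).
.coverage_counts <- function(array, z, n = 401) {
  w <- fov_windows_at_depth(array, z)
  if (any(!is.finite(w$radius_um))) {
    .clf_error("coverage counts undefined for an unbounded stop", "clf_invalid_parameter")
  }
  ext <- max(abs(c(w$cx_um + w$radius_um, w$cx_um - w$radius_um,
                   w$cy_um + w$radius_um, w$cy_um - w$radius_um)))
  if (!is.finite(ext) || ext <= 0) {
    return(list(counts = matrix(0L, n, n), pixel_um = 1))
  }
  px <- 2 * ext / (n - 1)
  xs <- seq(-ext, ext, length.out = n)
  counts <- matrix(0L, n, n)
  for (i in seq_len(nrow(w))) {
    d2 <- outer((xs - w$cy_um[i])^2, (xs - w$cx_um[i])^2, `+`)
    counts <- counts + (d2 <= w$radius_um[i]^2)
  }
  list(counts = counts, pixel_um = px)
}

#' Functional-zone diameters versus depth
#'
#' For each depth, the equivalent-circular diameters of the object-plane
#' regions covered by at least `foveated_min` lenslet windows (foveated), at
#' least `blend_min` (blend extent) and at least 1 (peripheral extent).
#' Nesting foveated <= blend <= peripheral holds by construction.
#'
#' @param array an `array_spec`.
#' @param zrange a [depth_range()] or numeric vector of depths (um).
#' @param foveated_min,blend_min coverage-count thresholds.
#' @param n rasterization grid size per depth.
#' @return tibble with columns `z_um`, `foveated_um`, `blend_um`,
#'   `peripheral_um`; depth-averaged diameters are attached as attribute
#'   `"means"`.
#' @export
zone_extents <- function(array, zrange = depth_range(), foveated_min = 6,
                         blend_min = 3, n = 401) {
  zs <- if (inherits(zrange, "depth_range")) depth_samples(zrange) else zrange
  rows <- lapply(zs, function(z) {
    cc <- .coverage_counts(array, z, n = n)
    area <- function(thr) sum(cc$counts >= thr) * cc$pixel_um^2
    tibble::tibble(z_um = z,
                   foveated_um = 2 * sqrt(area(foveated_min) / pi),
                   blend_um = 2 * sqrt(area(blend_min) / pi),
                   peripheral_um = 2 * sqrt(area(1) / pi))
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- c(foveated_um = mean(out$foveated_um),
                          blend_um = mean(out$blend_um),
                          peripheral_um = mean(out$peripheral_um))
  out
}

# ---- geometry serialization -------------------------------------------------

#' Serialize / restore array geometry as a plain list (YAML/JSON block)
#'
#' @param array an `array_spec`.
#' @return a nested list mirroring the config schema.
#' @export
array_to_config <- function(array) {
  list(ring_radius_um = array$ring_radius,
       intersection_mm = um_to_mm(array$intersection_distance),
       sensor_mm = um_to_mm(array$sensor_distance),
       lens_diameter_um = array$lenslets[[1]]$diameter,
       focal_central_um = c(array$lenslets[[1]]$focal_min, array$lenslets[[1]]$focal_max),
       focal_edge_um = c(array$lenslets[[2]]$focal_min, array$lenslets[[2]]$focal_max),
       tilt_deg = array$lenslets[[2]]$tilt_deg,
       stop = list(diameter_um = array$stop$diameter,
                   height_mm = um_to_mm(array$stop$height_above_lenslets)),
       sensor = list(pitch_um = array$sensor$pixel_pitch,
                     w = array$sensor$width_px, h = array$sensor$height_px,
                     channels = array$sensor$channels))
}

#' @rdname array_to_config
#' @param config a list as produced by [array_to_config()]; missing entries
#'   fall back to the package defaults.
#' @export
array_from_config <- function(config) {
  d <- array_to_config(compound_array())   # defaults
  for (k in names(config)) d[[k]] <- config[[k]]
  compound_array(
    ring_radius = d$ring_radius_um,
    intersection_distance = mm_to_um(d$intersection_mm),
    sensor_distance = mm_to_um(d$sensor_mm),
    lens_diameter = d$lens_diameter_um,
    focal_central = as.numeric(d$focal_central_um),
    focal_edge = as.numeric(d$focal_edge_um),
    tilt_deg = d$tilt_deg,
    sensor = sensor_spec(d$sensor$pitch_um, d$sensor$w, d$sensor$h, d$sensor$channels),
    stop = aperture_spec(d$stop$diameter_um, mm_to_um(d$stop$height_mm)))
}
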