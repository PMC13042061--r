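# Stage-0 calibration: aperture segmentation, per-lenslet PSF localization
# across depth, translation-curve fitting, and magnification calibration.
#
# The translation curve of an edge lenslet is the sensor-plane displacement
# (centre-lenslet PSF minus edge-lenslet PSF) as a function of object depth.
# In the pinhole model this displacement is affine in 1/z; the model stores
# the measured knots together with a global linear-in-z fit (slopes,
# intercepts, residual RMS) and a 1/z fit. Evaluation defaults to
# piecewise-linear interpolation of the knots ("translation distances at
# unsampled depths are interpolated"); the global line and the 1/z curve are
# selectable alternatives.

#' Segment the aperture frame into labelled lenslet footprints
#'
#' Thresholds the white-light aperture frame, labels connected components,
#' discards components below `min_area`, and orders labels centre-first
#' (nearest the sensor centre) then counterclockwise from +x.
#'
#' @param frame a `capture_frame` of the physical apertures.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold for `"fixed"` (same units as the frame).
#' @param min_area minimum component area (px).
#' @param expected expected lenslet count; a different count raises a
#'   `clf_segmentation_count` error naming the count found.
#' @return object of class `aperture_mask`: list with `labels` (integer
#'   matrix, 0 background), `centroids` (tibble `lens_id`, `cx_px`, `cy_px`,
#'   `area_px`), `pixel_pitch`.
#' @export
segment_apertures <- function(frame, threshold_method = c("otsu", "fixed"),
                              fixed_value = NULL, min_area = 100, expected = 7L) {
  threshold_method <- match.arg(threshold_method)
  img <- frame$image
  if (length(img) == 0) .clf_error("empty frame", "clf_invalid_parameter")
  mx <- max(img)
  thr <- if (threshold_method == "otsu") {
    if (mx <= 0) Inf else EBImage::otsu(EBImage::Image(img / mx)) * mx
  } else {
    if (is.null(fixed_value)) .clf_error("fixed_value required", "clf_invalid_parameter")
    fixed_value
  }
  bw <- img > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_area)
  } else keep <- integer(0)
  if (length(keep) != expected) {
    .clf_error(sprintf("segmentation found %d components, expected %d",
                       length(keep), expected), "clf_segmentation_count")
  }
  H <- nrow(img); W <- ncol(img)
  cy0 <- (H + 1) / 2; cx0 <- (W + 1) / 2
  cent <- t(vapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(mean(idx[, 2]), mean(idx[, 1]), nrow(idx))
  }, numeric(3)))
  # order: centre-first, then CCW angle from +x (ties: smaller y)
  d <- sqrt((cent[, 1] - cx0)^2 + (cent[, 2] - cy0)^2)
  first <- which.min(d)
  rest <- setdiff(seq_along(keep), first)
  ang <- atan2(cent[rest, 2] - cy0, cent[rest, 1] - cx0) %% (2 * pi)
  rest <- rest[order(round(ang, 6), cent[rest, 2])]
  ord <- c(first, rest)
  relab <- integer(max(lab))
  relab[keep[ord]] <- seq_along(ord)
  labels <- matrix(0L, H, W)
  nz <- lab > 0
  labels[nz] <- relab[lab[nz]]
  structure(list(labels = labels,
                 centroids = tibble::tibble(lens_id = seq_along(ord),
                                            cx_px = cent[ord, 1],
                                            cy_px = cent[ord, 2],
                                            area_px = cent[ord, 3]),
                 pixel_pitch = frame$pixel_pitch),
            class = "aperture_mask")
}

#' @export
print.aperture_mask <- function(x, ...) {
  cat(sprintf("<aperture_mask> %d footprints on %d x %d px\n",
              nrow(x$centroids), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Localize the per-lenslet PSF in each frame of a z-stack
#'
#' Intensity-weighted centroid within each footprint after subtracting a
#' robust background floor (median + 3 MAD of the footprint region). A
#' footprint with no signal above the floor is flagged `missing`.
#'
#' @param stack list of `list(z = depth_um, frame = capture_frame)`.
#' @param mask an [segment_apertures()] mask.
#' @return tibble with columns `lens_id`, `z_um`, `cx_px`, `cy_px`, `mass`,
#'   `missing`.
#' @export
localize_psfs <- function(stack, mask) {
  lab <- mask$labels
  ids <- sort(unique(lab[lab > 0]))
  idx_by_lens <- lapply(ids, function(k) which(lab == k, arr.ind = TRUE))
  rows <- lapply(stack, function(el) {
    img <- el$frame$image
    do.call(rbind, lapply(seq_along(ids), function(j) {
      idx <- idx_by_lens[[j]]
      v <- img[idx]
      floor_v <- stats::median(v) + 3 * stats::mad(v)
      w <- pmax(0, v - floor_v)
      s <- sum(w)
      if (s <= 0 || max(v) <= floor_v) {
        tibble::tibble(lens_id = ids[j], z_um = el$z, cx_px = NA_real_,
                       cy_px = NA_real_, mass = 0, missing = TRUE)
      } else {
        tibble::tibble(lens_id = ids[j], z_um = el$z,
                       cx_px = sum(w * idx[, 2]) / s,
                       cy_px = sum(w * idx[, 1]) / s,
                       mass = s, missing = FALSE)
      }
    }))
  })
  do.call(rbind, rows)
}

#' Fit per-lenslet translation curves from PSF localizations
#'
#' The centre lenslet is the zero point: for each edge lenslet the shift
#' (centre centroid minus edge centroid, in px) is recorded per depth
#' ("knots"), and a least-squares line in z plus a least-squares curve in 1/z
#' are fitted per axis, with residual RMS reported for the linear fit.
#'
#' @param localizations output of [localize_psfs()].
#' @param center_lenslet_id id of the central lenslet (zero translation).
#' @return object of class `translation_model`.
#' @export
fit_translation_model <- function(localizations, center_lenslet_id = 1L) {
  loc <- localizations[!localizations$missing, ]
  ctr <- loc[loc$lens_id == center_lenslet_id, ]
  edges <- setdiff(unique(loc$lens_id), center_lenslet_id)
  knots <- list(); coefs <- list()
  for (id in edges) {
    e <- loc[loc$lens_id == id, ]
    m <- merge(as.data.frame(ctr[, c("z_um", "cx_px", "cy_px")]),
               as.data.frame(e[, c("z_um", "cx_px", "cy_px")]),
               by = "z_um", suffixes = c("_c", "_e"))
    if (nrow(m) < 2) {
      .clf_error(sprintf("lenslet %d has %d valid depths; >= 2 required", id, nrow(m)),
                 "clf_underdetermined_fit")
    }
    m <- m[order(m$z_um), ]
    dx <- m$cx_px_c - m$cx_px_e
    dy <- m$cy_px_c - m$cy_px_e
    fx <- stats::lm(dx ~ z_um, data = data.frame(dx = dx, z_um = m$z_um))
    fy <- stats::lm(dy ~ z_um, data = data.frame(dy = dy, z_um = m$z_um))
    ix <- stats::lm(dx ~ iz, data = data.frame(dx = dx, iz = 1 / m$z_um))
    iy <- stats::lm(dy ~ iz, data = data.frame(dy = dy, iz = 1 / m$z_um))
    knots[[length(knots) + 1]] <- tibble::tibble(lens_id = id, z_um = m$z_um,
                                                 dx_px = dx, dy_px = dy)
    cf <- function(m, i) unname(stats::coef(m)[i])
    coefs[[length(coefs) + 1]] <- tibble::tibble(
      lens_id = id,
      slope_x = cf(fx, 2), intercept_x = cf(fx, 1),
      slope_y = cf(fy, 2), intercept_y = cf(fy, 1),
      rms_x = sqrt(mean(stats::resid(fx)^2)),
      rms_y = sqrt(mean(stats::resid(fy)^2)),
      invz_slope_x = cf(ix, 2), invz_intercept_x = cf(ix, 1),
      invz_slope_y = cf(iy, 2), invz_intercept_y = cf(iy, 1))
  }
  structure(list(coefficients = do.call(rbind, coefs),
                 knots = do.call(rbind, knots),
                 center_lenslet_id = center_lenslet_id,
                 z_range = range(loc$z_um),
                 default_method = "interp"),
            class = "translation_model")
}

#' @export
print.translation_model <- function(x, ...) {
  cat(sprintf("<translation_model> %d edge lenslets, %d depths over [%g, %g] um\n",
              nrow(x$coefficients), length(unique(x$knots$z_um)),
              x$z_range[1], x$z_range[2]))
  cat(sprintf("  linear-fit residual RMS: %.3g px (max over lenslets/axes)\n",
              max(x$coefficients$rms_x, x$coefficients$rms_y)))
  invisible(x)
}

#' Evaluate a translation curve at a depth
#'
#' @param model a [fit_translation_model()] result.
#' @param lens_id lenslet id; the centre lenslet returns (0, 0).
#' @param z depth(s) (um).
#' @param method `"interp"` (piecewise-linear through the measured knots, the
#'   default), `"linear"` (global line in z) or `"invz"` (line in 1/z).
#'   Depths outside the calibrated range are flagged via attribute
#'   `"extrapolated"` (interp extrapolates with the end segments).
#' @return n x 2 matrix of shifts (px), columns dx, dy.
#' @export
shift_at_depth <- function(model, lens_id, z,
                           method = c("interp", "linear", "invz")) {
  method <- match.arg(method, choices = c("interp", "linear", "invz"))
  if (lens_id == model$center_lenslet_id) {
    out <- matrix(0, length(z), 2, dimnames = list(NULL, c("dx", "dy")))
    attr(out, "extrapolated") <- z < model$z_range[1] | z > model$z_range[2]
    return(out)
  }
  co <- model$coefficients[model$coefficients$lens_id == lens_id, ]
  if (nrow(co) == 0) .clf_error(sprintf("unknown lens_id %s", lens_id), "clf_lookup_error")
  if (method == "linear") {
    dx <- co$intercept_x + co$slope_x * z
    dy <- co$intercept_y + co$slope_y * z
  } else if (method == "invz") {
    dx <- co$invz_intercept_x + co$invz_slope_x / z
    dy <- co$invz_intercept_y + co$invz_slope_y / z
  } else {
    kn <- model$knots[model$knots$lens_id == lens_id, ]
    interp1 <- function(v) {
      out <- stats::approx(kn$z_um, v, xout = z, rule = 1)$y
      lo <- z < min(kn$z_um); hi <- z > max(kn$z_um)
      if (any(lo)) {
        s <- (v[2] - v[1]) / (kn$z_um[2] - kn$z_um[1])
        out[lo] <- v[1] + s * (z[lo] - kn$z_um[1])
      }
      n <- nrow(kn)
      if (any(hi)) {
        s <- (v[n] - v[n - 1]) / (kn$z_um[n] - kn$z_um[n - 1])
        out[hi] <- v[n] + s * (z[hi] - kn$z_um[n])
      }
      out
    }
    dx <- interp1(kn$dx_px); dy <- interp1(kn$dy_px)
  }
  out <- cbind(dx = dx, dy = dy)
  attr(out, "extrapolated") <- z < model$z_range[1] | z > model$z_range[2]
  out
}

#' Depth-dependent magnification model
#'
#' Parametric mode uses the pinhole law m(z) = sensor_distance / z; tabulated
#' mode interpolates measured (z, m) pairs linearly. Both are strictly
#' decreasing in z (checked for tabulated input).
#'
#' @param mode `"parametric"` or `"tabulated"`.
#' @param sensor_distance sensor distance (um), required for parametric mode.
#' @param table tibble/data.frame with columns `z_um`, `m` for tabulated mode
#'   (at least two depths).
#' @return object of class `magnification_model`.
#' @export
fit_magnification <- function(mode = c("parametric", "tabulated"),
                              sensor_distance = NULL, table = NULL) {
  mode <- match.arg(mode)
  if (mode == "parametric") {
    if (is.null(sensor_distance)) .clf_error("sensor_distance required", "clf_invalid_parameter")
    .check_pos(sensor_distance, "sensor_distance")
  } else {
    if (is.null(table) || nrow(table) < 2) {
      .clf_error("tabulated mode needs >= 2 calibration depths", "clf_invalid_parameter")
    }
    table <- table[order(table$z_um), ]
    if (any(diff(table$m) >= 0)) {
      .clf_error("tabulated magnification must be strictly decreasing in z",
                 "clf_invalid_parameter")
    }
  }
  structure(list(mode = mode, sensor_distance = sensor_distance,
                 table = if (!is.null(table)) tibble::as_tibble(table)),
            class = "magnification_model")
}

#' @rdname fit_magnification
#' @param model a `magnification_model`.
#' @param z depth(s) (um).
#' @export
magnification <- function(model, z) {
  .check_pos(z, "z")
  if (model$mode == "parametric") {
    model$sensor_distance / z
  } else {
    stats::approx(model$table$z_um, model$table$m, xout = z, rule = 2)$y
  }
}

#' Measure grid magnification in the central elemental image
#'
#' Locates grid-node spots in the central lenslet's footprint (connected
#' components above the Otsu threshold) and estimates magnification as the
#' median nearest-neighbour spacing divided by the known grid pitch.
#'
#' @param frame a `capture_frame` of a grid target.
#' @param mask an `aperture_mask`.
#' @param grid_pitch true grid pitch (um).
#' @param lens_id footprint to analyse (default central = 1).
#' @return scalar magnification estimate.
#' @export
measure_grid_magnification <- function(frame, mask, grid_pitch, lens_id = 1L) {
  img <- frame$image * (mask$labels == lens_id)
  mx <- max(img)
  if (mx <= 0) .clf_error("no signal in footprint", "clf_invalid_parameter")
  thr <- EBImage::otsu(EBImage::Image(img / mx)) * mx
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((img > thr) * 1)))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  ks <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ks) < 2) .clf_error("fewer than 2 grid spots found", "clf_invalid_parameter")
  cent <- t(vapply(ks, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    w <- img[idx]
    c(sum(w * idx[, 2]) / sum(w), sum(w * idx[, 1]) / sum(w))
  }, numeric(2)))
  d <- as.matrix(stats::dist(cent))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  stats::median(nn) * frame$pixel_pitch / grid_pitch
}

# ---- serialization ----------------------------------------------------------

#' Write / read calibration (translation + magnification) as JSON
#'
#' @param model a `translation_model`.
#' @param mag a `magnification_model`.
#' @param path output JSON path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns `list(translation, magnification)`.
#' @export
write_calibration <- function(model, mag, path) {
  payload <- list(
    translation = list(coefficients = model$coefficients, knots = model$knots,
                       center_lenslet_id = model$center_lenslet_id,
                       z_range = model$z_range,
                       default_method = model$default_method),
    magnification = list(mode = mag$mode, sensor_distance = mag$sensor_distance,
                         table = mag$table))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- structure(list(coefficients = tibble::as_tibble(p$translation$coefficients),
                       knots = tibble::as_tibble(p$translation$knots),
                       center_lenslet_id = p$translation$center_lenslet_id,
                       z_range = as.numeric(p$translation$z_range),
                       default_method = p$translation$default_method),
                  class = "translation_model")
  mg <- structure(list(mode = p$magnification$mode,
                       sensor_distance = p$magnification$sensor_distance,
                       table = if (!is.null(p$magnification$table))
                         tibble::as_tibble(p$magnification$table)),
                  class = "magnification_model")
  list(translation = tr, magnification = mg)
}
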