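# Five-stage volumetric reconstruction: rolling-ball background subtraction,
# aperture-mask elemental extraction, depth-dependent shift-and-add
# refocusing, shading-map zone classification with feature-mask artifact
# suppression, and depth-dependent magnification rescaling; plus
# depth-from-focus estimation and flat-field correction.

#' Rolling-ball background subtraction
#'
#' Removes the grayscale opening of the image with a non-flat ball
#' structuring element of the given radius (the classical rolling-ball
#' background estimator): a ball of radius r rolled under the intensity
#' surface traces the background, and structures narrower than the ball
#' survive subtraction. Output is clamped at zero.
#'
#' @param frame a `capture_frame` or numeric matrix.
#' @param radius ball radius (px).
#' @return same type as the input, background-subtracted.
#' @export
subtract_background <- function(frame, radius = 25) {
  img <- if (inherits(frame, "capture_frame")) frame$image else frame
  .check_pos(radius, "radius")
  if (2 * radius >= min(dim(img))) {
    .clf_error("ball radius must be smaller than half the image", "clf_degenerate_radius")
  }
  bg <- .rolling_ball_background(img, radius)
  out <- pmax(img - bg, 0)
  if (inherits(frame, "capture_frame")) {
    frame$image <- out
    frame$metadata$background_radius <- radius
    frame
  } else out
}

# Grayscale opening with a ball structuring element (erosion then dilation),
# border handled by edge replication.
.rolling_ball_background <- function(img, radius) {
  r <- as.integer(ceiling(radius))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- off$dx^2 + off$dy^2
  keep <- d2 <= radius^2
  off <- off[keep, ]
  hgt <- sqrt(radius^2 - d2[keep])
  H <- nrow(img); W <- ncol(img)
  pad <- function(m) {
    m <- rbind(matrix(m[1, ], r, W, byrow = TRUE), m,
               matrix(m[H, ], r, W, byrow = TRUE))
    cbind(matrix(m[, 1], H + 2 * r, r), m, matrix(m[, W], H + 2 * r, r))
  }
  P <- pad(img)
  ero <- matrix(Inf, H, W)
  for (i in seq_len(nrow(off))) {
    sub <- P[(r + 1 + off$dy[i]):(r + H + off$dy[i]),
             (r + 1 + off$dx[i]):(r + W + off$dx[i])]
    ero <- pmin(ero, sub - hgt[i])
  }
  P <- pad(ero)
  dil <- matrix(-Inf, H, W)
  for (i in seq_len(nrow(off))) {
    sub <- P[(r + 1 + off$dy[i]):(r + H + off$dy[i]),
             (r + 1 + off$dx[i]):(r + W + off$dx[i])]
    dil <- pmax(dil, sub + hgt[i])
  }
  dil
}

#' Extract per-lenslet elemental images
#'
#' Masked copies of the frame, one per footprint label; pixels outside a
#' label are zero, so the labelled parts of the elements partition the
#' mask-applied frame.
#'
#' @param frame a `capture_frame`.
#' @param mask an `aperture_mask`.
#' @return object of class `elemental_set`: list with `images` (named list of
#'   matrices), `lens_ids`, `mask`, `pixel_pitch`.
#' @export
extract_elementals <- function(frame, mask) {
  if (!all(dim(frame$image) == dim(mask$labels))) {
    .clf_error("frame and mask dimensions disagree", "clf_invalid_parameter")
  }
  ids <- sort(unique(mask$labels[mask$labels > 0]))
  images <- lapply(ids, function(k) frame$image * (mask$labels == k))
  names(images) <- as.character(ids)
  structure(list(images = images, lens_ids = ids, mask = mask,
                 pixel_pitch = frame$pixel_pitch),
            class = "elemental_set")
}

#' Shift-and-add synthetic refocusing at one depth
#'
#' Each edge elemental image is translated by its calibrated depth-dependent
#' shift (sub-pixel bilinear interpolation) and summed with the central
#' element; features that truly lie at the requested depth converge, features
#' at other depths spread into rings of sub-spots.
#'
#' @param elements an [extract_elementals()] set.
#' @param model a [fit_translation_model()] result.
#' @param z refocus depth (um).
#' @param roi optional list(x = c(x1, x2), y = c(y1, y2)) of pixel bounds:
#'   compute the refocused image only inside this window.
#' @param method shift evaluation method, see [shift_at_depth()].
#' @return numeric matrix (full frame or ROI window); attribute
#'   `"extrapolated"` flags depths outside the calibrated range.
#' @export
refocus <- function(elements, model, z, roi = NULL, method = "interp") {
  extra <- FALSE
  acc <- NULL
  for (id in elements$lens_ids) {
    img <- elements$images[[as.character(id)]]
    if (id == model$center_lenslet_id) {
      part <- if (is.null(roi)) img else img[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]]
    } else {
      s <- shift_at_depth(model, id, z, method = method)
      extra <- extra || any(attr(s, "extrapolated"))
      part <- .shift_image(img, s[1, "dx"], s[1, "dy"], roi = roi)
    }
    acc <- if (is.null(acc)) part else acc + part
  }
  attr(acc, "extrapolated") <- extra
  acc
}

#' Shading map: lenslet-coverage counts after refocus translation
#'
#' The binary footprint of each lenslet undergoes the same translation as its
#' elemental image; the integer sum counts how many lenslet fields of view
#' cover each refocused pixel (0..7), defining the functional zones.
#'
#' @inheritParams refocus
#' @param mask an `aperture_mask`.
#' @return integer matrix of class `shading_map`.
#' @export
build_shading_map <- function(mask, model, z, roi = NULL, method = "interp") {
  ids <- sort(unique(mask$labels[mask$labels > 0]))
  acc <- NULL
  for (id in ids) {
    bin <- (mask$labels == id) * 1
    if (id == model$center_lenslet_id) {
      part <- if (is.null(roi)) bin else bin[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]]
    } else {
      s <- shift_at_depth(model, id, z, method = method)
      part <- .shift_image(bin, s[1, "dx"], s[1, "dy"], roi = roi) >= 0.5
    }
    acc <- if (is.null(acc)) part * 1L else acc + part
  }
  structure(matrix(as.integer(acc), nrow(acc), ncol(acc)), class = "shading_map")
}

#' Classify shading-map counts into functional zones
#'
#' Foveated: count >= `foveated_min`; blend: `blend_min` .. `foveated_min`-1;
#' peripheral: 1 .. `blend_min`-1; outside: 0. The three zones plus outside
#' partition every pixel.
#'
#' @param map a [build_shading_map()] result (integer matrix).
#' @param foveated_min,blend_min count thresholds (defaults 6 and 3).
#' @return integer matrix with codes 0 = outside, 1 = peripheral, 2 = blend,
#'   3 = foveated; attribute `"levels"` names the codes.
#' @export
classify_zones <- function(map, foveated_min = 6, blend_min = 3) {
  z <- matrix(0L, nrow(map), ncol(map))
  z[map >= 1] <- 1L
  z[map >= blend_min] <- 2L
  z[map >= foveated_min] <- 3L
  attr(z, "levels") <- c("outside", "peripheral", "blend", "foveated")
  z
}

#' Feature mask from the central elemental image
#'
#' Local-mean adaptive threshold followed by binary morphological opening:
#' the binary map of structures seen by the central lenslet, used to suppress
#' shift-and-add ghosts (features absent from the central view).
#'
#' @param central_element matrix (central lenslet's masked image).
#' @param window adaptive-threshold window (odd, >= 3).
#' @param opening_radius disc radius (px) for the opening; must stay below
#'   the radius of the smallest genuine feature or the mask will erase it.
#' @param offset threshold offset as a fraction of the image maximum.
#' @return binary matrix (`feature_mask` class).
#' @export
build_feature_mask <- function(central_element, window = 15, opening_radius = 1,
                               offset = 0.02) {
  if (window < 3 || window %% 2 == 0) .clf_error("window must be odd and >= 3", "clf_invalid_parameter")
  mx <- max(central_element)
  if (mx <= 0) {
    return(structure(matrix(0L, nrow(central_element), ncol(central_element)),
                     class = "feature_mask"))
  }
  img <- central_element / mx
  w <- window %/% 2
  bw <- EBImage::thresh(EBImage::Image(img), w = w, h = w, offset = offset)
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    bw <- EBImage::opening(bw, brush)
  }
  structure(matrix(as.integer(EBImage::imageData(bw) > 0),
                   nrow(central_element), ncol(central_element)),
            class = "feature_mask")
}

#' Apply feature and shading masks to a focal stack
#'
#' Inside the foveated and blend zones (coverage >= `blend_min`), voxels not
#' covered by the feature mask are zeroed; the peripheral zone is never
#' feature-masked. With `normalize = TRUE` each voxel is divided by its
#' coverage count (shading normalization of the intensity gradient).
#'
#' @param stack 3D array (y, x, z) of refocused layers.
#' @param feature a [build_feature_mask()] mask.
#' @param shading 3D integer array of per-layer shading maps.
#' @param blend_min blend-zone threshold.
#' @param normalize divide by coverage count where positive.
#' @return masked 3D array.
#' @export
apply_masks <- function(stack, feature, shading, blend_min = 3,
                        normalize = FALSE) {
  if (!all(dim(stack) == dim(shading))) .clf_error("stack/shading shape mismatch", "clf_invalid_parameter")
  if (!all(dim(stack)[1:2] == dim(feature))) .clf_error("feature mask shape mismatch", "clf_invalid_parameter")
  out <- stack
  nz <- dim(stack)[3]
  for (k in seq_len(nz)) {
    lay <- out[, , k]
    cnt <- shading[, , k]
    kill <- (cnt >= blend_min) & (feature == 0)
    lay[kill] <- 0
    if (normalize) {
      pos <- cnt > 0
      lay[pos] <- lay[pos] / cnt[pos]
    }
    out[, , k] <- lay
  }
  out
}

#' Rescale a focal stack to common object-space sampling
#'
#' Each layer is resampled about the central optical axis by the ratio of its
#' depth magnification to the reference depth's, so that all layers share the
#' object-space pixel size pitch / m(ref_z).
#'
#' @param stack 3D array (y, x, z).
#' @param mag a [fit_magnification()] model.
#' @param z depths (um) of the layers.
#' @param pixel_pitch sensor pixel pitch (um).
#' @param ref_z reference depth (um) whose sampling is kept (default: the
#'   depth of unit pinhole magnification, i.e. the intersection distance for
#'   the default design).
#' @param center_px optional (x, y) pixel position of the optical axis;
#'   default the image centre.
#' @return list with `stack` (rescaled array), `object_pixel_um`, `ref_z`.
#' @export
rescale_stack <- function(stack, mag, z, pixel_pitch, ref_z = NULL,
                          center_px = NULL) {
  if (is.null(ref_z)) {
    ref_z <- if (mag$mode == "parametric") mag$sensor_distance else stats::median(z)
  }
  m_ref <- magnification(mag, ref_z)
  H <- dim(stack)[1]; W <- dim(stack)[2]
  if (is.null(center_px)) center_px <- c((W + 1) / 2, (H + 1) / 2)
  out <- array(0, dim(stack))
  for (k in seq_along(z)) {
    mk <- magnification(mag, z[k])
    if (mk <= 0) .clf_error("non-positive magnification", "clf_invalid_parameter")
    s <- mk / m_ref   # source px per output px
    xq <- center_px[1] + (seq_len(W) - center_px[1]) * s
    yq <- center_px[2] + (seq_len(H) - center_px[2]) * s
    out[, , k] <- matrix(sample_bilinear(stack[, , k],
                                         rep(xq, each = H), rep(yq, times = W)),
                         H, W)
  }
  list(stack = out, object_pixel_um = pixel_pitch / m_ref, ref_z = ref_z)
}

#' Full five-stage volumetric reconstruction
#'
#' Composes background subtraction, elemental extraction, per-depth
#' shift-and-add refocusing, shading/zone maps, feature masking and
#' magnification rescaling into one deterministic pipeline.
#'
#' @param frame raw `capture_frame`.
#' @param mask an `aperture_mask`.
#' @param model a `translation_model`.
#' @param mag a `magnification_model`.
#' @param zrange a [depth_range()] or numeric vector of refocus depths (um).
#' @param background_radius rolling-ball radius (px), or `NULL` to skip.
#' @param feature_mask apply central-element feature masking.
#' @param normalize_shading divide by coverage counts.
#' @param rescale resample layers to common object-space sampling.
#' @param roi optional pixel window (list(x=, y=)) for the refocused layers.
#' @param shift_method see [shift_at_depth()].
#' @param feature_window,feature_opening feature-mask parameters.
#' @return object of class `recon_volume`: list with `stack` (y, x, z array),
#'   `z_um`, `shading` (array), `zones` (array), `object_pixel_um`,
#'   `provenance`.
#' @export
reconstruct <- function(frame, mask, model, mag, zrange = depth_range(),
                        background_radius = NULL, feature_mask = TRUE,
                        normalize_shading = FALSE, rescale = TRUE, roi = NULL,
                        shift_method = "interp", feature_window = 15,
                        feature_opening = 1) {
  zs <- if (inherits(zrange, "depth_range")) depth_samples(zrange) else zrange
  if (!is.null(background_radius)) frame <- subtract_background(frame, background_radius)
  elements <- extract_elementals(frame, mask)
  dims <- if (is.null(roi)) dim(frame$image) else
    c(roi$y[2] - roi$y[1] + 1, roi$x[2] - roi$x[1] + 1)
  stack <- array(0, c(dims[1], dims[2], length(zs)))
  shading <- array(0L, c(dims[1], dims[2], length(zs)))
  for (k in seq_along(zs)) {
    stack[, , k] <- refocus(elements, model, zs[k], roi = roi, method = shift_method)
    shading[, , k] <- build_shading_map(mask, model, zs[k], roi = roi,
                                        method = shift_method)
  }
  zones <- array(0L, dim(shading))
  for (k in seq_along(zs)) zones[, , k] <- classify_zones(shading[, , k])
  feat <- NULL
  if (feature_mask) {
    ctr <- elements$images[[as.character(model$center_lenslet_id)]]
    if (!is.null(roi)) ctr <- ctr[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]]
    feat <- build_feature_mask(ctr, window = feature_window,
                               opening_radius = feature_opening)
    stack <- apply_masks(stack, feat, shading, normalize = normalize_shading)
  } else if (normalize_shading) {
    ones <- matrix(1L, dims[1], dims[2])
    stack <- apply_masks(stack, ones, shading, normalize = TRUE)
  }
  obj_px <- frame$pixel_pitch
  if (rescale) {
    ctr_px <- NULL
    if (!is.null(roi)) {
      H <- nrow(frame$image); W <- ncol(frame$image)
      ctr_px <- c((W + 1) / 2 - roi$x[1] + 1, (H + 1) / 2 - roi$y[1] + 1)
    }
    rs <- rescale_stack(stack, mag, zs, frame$pixel_pitch, center_px = ctr_px)
    stack <- rs$stack
    obj_px <- rs$object_pixel_um
  }
  structure(list(stack = stack, z_um = zs, shading = shading, zones = zones,
                 feature = feat, object_pixel_um = obj_px,
                 provenance = list(
                   background_radius = background_radius,
                   feature_mask = feature_mask,
                   normalize_shading = normalize_shading,
                   rescale = rescale, shift_method = shift_method,
                   pixel_pitch = frame$pixel_pitch,
                   package_version = as.character(utils::packageVersion("compoundlf")))),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<recon_volume> %d x %d x %d voxels, z in [%g, %g] um, %g um/px (object)\n",
              d[1], d[2], d[3], min(x$z_um), max(x$z_um), x$object_pixel_um))
  invisible(x)
}

#' Depth-from-focus estimation on a focal stack
#'
#' Computes a focus score (variance of Laplacian by default) per layer inside
#' the region of interest, then localizes the peak with parabolic
#' interpolation (ties broken toward smaller z).
#'
#' @param stack a `recon_volume` or 3D array (y, x, z).
#' @param z layer depths (um); taken from the volume if omitted.
#' @param roi optional list(x=, y=) pixel window for the score.
#' @return object of class `depth_estimate`: list with `z_est_um` and `curve`
#'   (tibble `z_um`, `score`).
#' @export
estimate_depth <- function(stack, z = NULL, roi = NULL) {
  if (inherits(stack, "recon_volume")) {
    if (is.null(z)) z <- stack$z_um
    stack <- stack$stack
  }
  if (dim(stack)[3] < 3) .clf_error("need >= 3 layers", "clf_invalid_parameter")
  scores <- vapply(seq_len(dim(stack)[3]), function(k)
    focus_score(stack[, , k], roi = roi), numeric(1))
  if (max(scores) - min(scores) <= 1e-12 * max(abs(scores), 1)) {
    warning("flat focus-score curve; no focus found")
    return(structure(list(z_est_um = NA_real_,
                          curve = tibble::tibble(z_um = z, score = scores)),
                     class = "depth_estimate"))
  }
  structure(list(z_est_um = .parabolic_peak(z, scores),
                 curve = tibble::tibble(z_um = z, score = scores)),
            class = "depth_estimate")
}

#' @export
print.depth_estimate <- function(x, ...) {
  cat(sprintf("<depth_estimate> z = %.1f um (%d layers)\n", x$z_est_um,
              nrow(x$curve)))
  invisible(x)
}

#' Flat-field correction
#'
#' Divides by the mean-normalized reference, guarding small or non-positive
#' denominators with an epsilon (with a warning).
#'
#' @param img numeric matrix (or `capture_frame`).
#' @param reference reference image, same shape.
#' @param eps_frac guard floor as a fraction of the reference mean.
#' @return corrected image, same type as input.
#' @export
flat_field <- function(img, reference, eps_frac = 1e-3) {
  x <- if (inherits(img, "capture_frame")) img$image else img
  if (!all(dim(x) == dim(reference))) .clf_error("shape mismatch", "clf_invalid_parameter")
  mu <- mean(reference)
  if (mu <= 0) .clf_error("reference has non-positive mean", "clf_invalid_parameter")
  ref <- reference / mu
  eps <- eps_frac
  if (any(ref <= eps)) warning("reference contains small/non-positive regions; guarded with epsilon")
  out <- x / pmax(ref, eps)
  if (inherits(img, "capture_frame")) {
    img$image <- out
    img
  } else out
}
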