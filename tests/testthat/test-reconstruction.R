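test_that("rolling-ball background: constants, impulses, reference oracle", {
  # constant image -> all zeros
  expect_equal(subtract_background(matrix(3.2, 50, 60), 10),
               matrix(0, 50, 60))
  # impulse on a flat background survives, the background is removed; the
  # ball pokes up under a 1 px spike by its closed-form sag r - sqrt(r^2 - 1)
  img <- matrix(0.5, 41, 41); img[21, 21] <- 5.5
  out <- subtract_background(img, 6)
  sag <- 6 - sqrt(6^2 - 1)
  expect_equal(out[21, 21], 5 - sag, tolerance = 1e-9)
  expect_lt(max(out[-21, ]), 1e-9)
  # frozen reference: grayscale opening with a ball structuring element
  # (expected values computed once with scipy.ndimage.grey_opening)
  inp <- as.matrix(read.csv(test_path("fixtures", "rb_input.csv"), header = FALSE))
  ref <- as.matrix(read.csv(test_path("fixtures", "rb_bg_scipy.csv"), header = FALSE))
  dimnames(inp) <- dimnames(ref) <- NULL
  bg <- compoundlf:::.rolling_ball_background(inp, 8)
  expect_lt(max(abs(bg - ref)), 1 / 255)   # within one 8-bit gray level
  expect_error(subtract_background(matrix(0, 10, 10), 6),
               class = "clf_degenerate_radius")
})

test_that("elemental extraction partitions the masked frame", {
  s <- get_setup3()
  scn <- bead_layers_phantom(beads_per_layer = 5, seed = 3)
  fr <- render_capture(scn, s$array)
  el <- extract_elementals(fr, s$mask)
  expect_length(el$images, 7)
  total <- Reduce(`+`, el$images)
  expect_equal(total, fr$image * (s$mask$labels > 0))
  # a spot inside label k appears only in element k
  one <- render_capture(scene(tibble::tibble(
    x_um = 0, y_um = 0, z_um = 3000, diameter_um = 2.5, intensity = 1)), s$array)
  els <- extract_elementals(one, s$mask)
  for (id in 1:7) expect_equal(count_spots(els$images[[as.character(id)]]), 1)
  bad <- capture_frame(matrix(0, 10, 10), 4.2)
  expect_error(extract_elementals(bad, s$mask), class = "clf_invalid_parameter")
})

test_that("refocusing converges at the true depth and conserves energy", {
  s <- get_setup3()
  zt <- 3150
  fr <- render_capture(scene(tibble::tibble(
    x_um = 25, y_um = -10, z_um = zt, diameter_um = 2.5, intensity = 1)), s$array)
  el <- extract_elementals(fr, s$mask)
  pr <- project_point(s$array, 1L, c(25, -10, zt))
  ctr <- sensor_px(s$array, c(pr$x_um, pr$y_um))
  roi <- list(x = round(ctr[1]) + c(-8, 8), y = round(ctr[2]) + c(-8, 8))
  zg <- seq(2000, 4000, by = 100)
  prof <- vapply(zg, function(z) max(refocus(el, s$model, z, roi = roi)),
                 numeric(1))
  expect_lt(abs(zg[which.max(prof)] - zt), 100 + 1e-9)
  # at the true depth: one compact spot; far off: a ring of dimmer sub-spots
  at_true <- refocus(el, s$model, zt, roi = roi)
  off <- refocus(el, s$model, zt + 500, roi = roi)
  expect_gt(max(at_true), 2 * max(off))
  # energy: the refocused sum equals the sum of the translated elements
  full_true <- refocus(el, s$model, zt)
  expect_lt(abs(sum(full_true) / sum(Reduce(`+`, el$images)) - 1), 1e-6)
  # all-zero elements refocus to zero
  zero <- extract_elementals(capture_frame(matrix(0, 648, 864), 4.2), s$mask)
  expect_equal(max(abs(refocus(zero, s$model, 3000, roi = roi))), 0)
})

test_that("shading maps count coverage; zones nest and partition", {
  s <- get_setup3()
  for (z in c(2400, 3000, 3600)) {
    sm <- build_shading_map(s$mask, s$model, z)
    expect_true(all(sm >= 0 & sm <= 7))
    zl <- classify_zones(sm)
    # partition: every pixel gets exactly one of the four labels
    expect_true(all(zl %in% 0:3))
    a_fov <- sum(sm >= 6); a_blend <- sum(sm >= 3); a_per <- sum(sm >= 1)
    expect_lte(a_fov, a_blend); expect_lte(a_blend, a_per)
    expect_equal(sum(zl == 3), a_fov)
    expect_equal(sum(zl == 2), a_blend - a_fov)
    expect_equal(sum(zl == 1), a_per - a_blend)
  }
  # at the convergence depth the centre attains the maximal count
  sm3 <- build_shading_map(s$mask, s$model, 3000)
  expect_equal(sm3[324, 432], 7L)
  expect_equal(max(sm3), 7L)
  # degenerate maps
  expect_true(all(classify_zones(matrix(7L, 5, 5)) == 3L))
  expect_true(all(classify_zones(matrix(1L, 5, 5)) == 1L))
})

test_that("feature mask: blank, survival under opening, component count", {
  blank <- build_feature_mask(matrix(0, 64, 64))
  expect_equal(sum(blank), 0)
  s <- get_setup3()
  scn <- bead_layers_phantom(n_layers = 1, beads_per_layer = 3,
                             layer_spacing = 0, z_center = 3000,
                             lateral_extent = 120, seed = 21)
  fr <- render_capture(scn, s$array)
  el <- extract_elementals(fr, s$mask)
  fm <- build_feature_mask(el$images[["1"]], window = 15, opening_radius = 1)
  expect_equal(count_spots(fm, frac = 0.5), 3)
  expect_error(build_feature_mask(matrix(0, 10, 10), window = 4),
               class = "clf_invalid_parameter")
})

test_that("feature masking removes off-centre-only features, spares periphery", {
  s <- get_setup3()
  arr <- s$array
  # an emitter outside the central lenslet's window but inside edge windows:
  # reconstructed in the blend zone, absent from the central element
  ghost <- scene(tibble::tibble(x_um = 500, y_um = 0, z_um = 3000,
                                diameter_um = 2.5, intensity = 1))
  # a peripheral emitter seen by at most two lenslets
  per <- scene(tibble::tibble(x_um = 600, y_um = 0, z_um = 3000,
                              diameter_um = 2.5, intensity = 1))
  run_one <- function(scn, feature_mask = TRUE) {
    fr <- render_capture(scn, arr)
    x <- scn$emitters$x_um
    px <- sensor_px(arr, c(-x, 0))
    roi <- list(x = round(px[1]) + c(-6, 6), y = round(px[2]) + c(-6, 6))
    reconstruct(fr, s$mask, s$model, s$mag, c(3000),
                roi = roi, rescale = FALSE, feature_mask = feature_mask)
  }
  vg <- run_one(ghost)
  vg_raw <- run_one(ghost, feature_mask = FALSE)
  expect_gte(max(vg$shading), 3)         # lands in blend or foveated coverage
  expect_gt(max(vg_raw$stack), 0.1)      # present before feature masking
  expect_lt(max(vg$stack), 1e-3 * max(vg_raw$stack))  # suppressed after
  vp <- run_one(per)
  expect_lte(max(vp$shading[, , 1][vp$stack[, , 1] > 0]), 2)
  expect_gt(max(vp$stack), 0)            # peripheral features are never masked
})

test_that("feature mask all ones leaves the stack unchanged", {
  s <- get_setup3()
  fr <- render_capture(scene(tibble::tibble(
    x_um = 0, y_um = 0, z_um = 3000, diameter_um = 15.4, intensity = 1)), s$array)
  el <- extract_elementals(fr, s$mask)
  roi <- center_roi(s$array, 20)
  lay <- refocus(el, s$model, 3000, roi = roi)
  stack <- array(lay, c(dim(lay), 1))
  shading <- array(build_shading_map(s$mask, s$model, 3000, roi = roi),
                   dim(stack))
  ones <- matrix(1L, nrow(lay), ncol(lay))
  expect_equal(apply_masks(stack, ones, shading), stack)
  norm <- apply_masks(stack, ones, shading, normalize = TRUE)
  expect_equal(norm[, , 1][shading[, , 1] == 7] * 7,
               stack[, , 1][shading[, , 1] == 7])
})

test_that("magnification rescaling equalizes object-space geometry", {
  s <- get_setup3()
  arr <- s$array
  # identity at the reference depth
  lay <- matrix(runif(101 * 101), 101)
  rs <- rescale_stack(array(lay, c(101, 101, 1)), s$mag, 3000, 4.2)
  expect_equal(rs$stack[, , 1], lay, tolerance = 1e-12)
  expect_equal(rs$object_pixel_um, 4.2)
  # equal true separations at different depths match after rescaling
  sep_at <- function(z) {
    fr <- render_capture(scene(tibble::tibble(
      x_um = c(-60, 60), y_um = 0, z_um = z, diameter_um = 2.5, intensity = 1)),
      arr)
    el <- extract_elementals(fr, s$mask)
    roi <- center_roi(arr, 40)
    lay <- refocus(el, s$model, z, roi = roi)
    rs <- rescale_stack(array(lay, c(dim(lay), 1)), s$mag, z, 4.2,
                        center_px = c(41, 41))
    m <- rs$stack[, , 1]
    idx <- which(m > 0.25 * max(m), arr.ind = TRUE)
    cl <- stats::kmeans(idx[, 2], 2)
    abs(diff(sort(cl$centers))) * rs$object_pixel_um
  }
  s1 <- sep_at(2600); s2 <- sep_at(3400)
  expect_lt(abs(s1 - 120), 4.2)
  expect_lt(abs(s1 - s2), 4.2)   # within one object pixel
  # a 100 um grid measures 100 um pitch after rescaling, within 2%
  fr <- render_capture(grid_target_scene(100, 400, 2600), arr)
  vol <- reconstruct(fr, s$mask, s$model, s$mag, c(2600),
                     roi = center_roi(arr, 90), feature_mask = FALSE)
  m <- vol$stack[, , 1]
  frame <- capture_frame(m, vol$object_pixel_um)
  mask1 <- list(labels = matrix(1L, nrow(m), ncol(m)))
  pitch_ratio <- measure_grid_magnification(frame, mask1, 100)
  expect_lt(abs(pitch_ratio - 1), 0.02)
})

test_that("depth-from-focus: peak localization and tie handling", {
  s <- get_setup3()
  fr <- render_capture(grid_target_scene(100, 400, 3000), s$array)
  el <- extract_elementals(fr, s$mask)
  roi <- center_roi(s$array, 85)
  zg <- seq(2500, 3500, by = 50)
  stk <- array(0, c(diff(roi$y) + 1, diff(roi$x) + 1, length(zg)))
  for (k in seq_along(zg)) stk[, , k] <- refocus(el, s$model, zg[k], roi = roi)
  de <- estimate_depth(stk, zg)
  expect_lt(abs(de$z_est_um - 3000), 50)
  # the in-focus peak dominates every defocused layer by a wide margin
  # (periodic targets re-register partially at defocus, so the tail of the
  # curve is not monotone, but it stays far below the converged peak)
  pk <- which.max(de$curve$score)
  expect_equal(de$curve$z_um[pk], 3000)
  expect_gt(de$curve$score[pk], 3 * max(de$curve$score[-pk]))
  # flat stacks warn and return NA
  expect_warning(df <- estimate_depth(array(1, c(10, 10, 5)), 1:5), "flat")
  expect_true(is.na(df$z_est_um))
  expect_error(estimate_depth(array(0, c(5, 5, 2)), 1:2),
               class = "clf_invalid_parameter")
  # accessor methods
  expect_s3_class(tidy(de), "tbl_df")
  expect_equal(glance(de)$z_est_um, de$z_est_um)
})

test_that("flat-field correction: identity, exact inverse, guarded zeros", {
  img <- matrix(runif(400), 20)
  expect_equal(flat_field(img, matrix(1, 20, 20)), img)
  vig <- outer(seq(0.5, 1, length.out = 20), seq(0.5, 1, length.out = 20))
  vimg <- img * vig
  corrected <- flat_field(vimg, vig)
  expect_lt(max(abs(corrected / mean(vig) - img)), 1e-6 * max(img))
  ref0 <- vig; ref0[1, 1] <- 0
  expect_warning(flat_field(vimg, ref0), "guarded")
  expect_error(flat_field(img, matrix(1, 5, 5)), class = "clf_invalid_parameter")
})

test_that("empty frames reconstruct to empty volumes with valid metadata", {
  s <- get_setup3()
  fr <- capture_frame(matrix(0, 648, 864), 4.2)
  vol <- reconstruct(fr, s$mask, s$model, s$mag, c(2900, 3000),
                     roi = center_roi(s$array, 30))
  expect_equal(max(abs(vol$stack)), 0)
  expect_equal(vol$z_um, c(2900, 3000))
  expect_type(vol$provenance$package_version, "character")
})
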