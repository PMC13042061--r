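test_that("aperture segmentation: seven ordered labels, count errors", {
  s <- get_setup3()
  mask <- s$mask
  expect_equal(sort(unique(mask$labels[mask$labels > 0])), 1:7)
  expect_equal(nrow(mask$centroids), 7)
  # label 1 is the footprint nearest the sensor centre
  d <- sqrt((mask$centroids$cx_px - (864 + 1) / 2)^2 +
              (mask$centroids$cy_px - (648 + 1) / 2)^2)
  expect_equal(which.min(d), 1L)
  # labels 2..7 wind counterclockwise from +x
  ang <- atan2(mask$centroids$cy_px[-1] - (648 + 1) / 2,
               mask$centroids$cx_px[-1] - (864 + 1) / 2) %% (2 * pi)
  expect_false(is.unsorted(ang))
  expect_lt(ang[1], 0.05)
  # an empty frame reports the count found
  blank <- capture_frame(matrix(0, 100, 100), 4.2)
  err <- tryCatch(segment_apertures(blank), error = identity)
  expect_s3_class(err, "clf_segmentation_count")
  expect_match(conditionMessage(err), "0 components")
})

test_that("PSF localization matches the forward model to sub-pixel", {
  s <- get_setup3()
  loc <- s$loc
  expect_false(any(loc$missing))
  arr <- s$array
  err <- vapply(seq_len(nrow(loc)), function(i) {
    pr <- project_point(arr, loc$lens_id[i], c(0, 0, loc$z_um[i]))
    exp_px <- sensor_px(arr, c(pr$x_um, pr$y_um))
    max(abs(c(loc$cx_px[i], loc$cy_px[i]) - exp_px))
  }, numeric(1))
  expect_lt(max(err), 0.1)
  # at the intersection depth all centroids sit on the elemental centres
  at3 <- loc[loc$z_um == 3000, ]
  for (i in seq_len(nrow(at3))) {
    ec <- sensor_px(arr, elemental_center(arr, at3$lens_id[i]))
    expect_lt(max(abs(c(at3$cx_px[i], at3$cy_px[i]) - ec)), 0.1)
  }
  # a signal-free footprint is flagged missing, not an error
  blank_stack <- list(list(z = 3000, frame = capture_frame(
    matrix(0, 648, 864), 4.2)))
  lb <- localize_psfs(blank_stack, s$mask)
  expect_true(all(lb$missing))
})

test_that("translation model: knots, fits, residuals and symmetry", {
  s <- get_setup3()
  tm <- s$model
  arr <- s$array
  pitch <- arr$sensor$pixel_pitch
  expect_equal(nrow(tm$coefficients), 6)
  # central lenslet is identically the zero point
  expect_equal(unname(shift_at_depth(tm, 1L, c(2000, 3000, 4000))),
               matrix(0, 3, 2), ignore_attr = TRUE)
  # the pinhole shift is affine in 1/z: the 1/z fit is near-exact, and the
  # linear-in-z fit leaves the residual the independent oracle predicts
  analytic_dx <- function(z) {
    (project_point(arr, 1L, c(0, 0, z))$x_um -
       project_point(arr, 2L, c(0, 0, z))$x_um) / pitch
  }
  zk <- tm$knots$z_um[tm$knots$lens_id == 2]
  oracle <- vapply(zk, analytic_dx, numeric(1))
  fit <- stats::lm(oracle ~ zk)
  rms_oracle <- sqrt(mean(stats::resid(fit)^2))
  co <- tm$coefficients[tm$coefficients$lens_id == 2, ]
  expect_lt(abs(co$rms_x - rms_oracle), 0.1)
  expect_gt(co$rms_x, 1)  # the global line genuinely misfits at this pitch
  iv <- shift_at_depth(tm, 2L, zk, method = "invz")[, "dx"]
  expect_lt(max(abs(iv - oracle)), 0.15)
  # interpolation through the knots reproduces the analytic curve closely
  zq <- c(2150, 2550, 3350, 3850)
  ip <- shift_at_depth(tm, 2L, zq)[, "dx"]
  expect_lt(max(abs(ip - vapply(zq, analytic_dx, numeric(1)))), 0.2)
  # radial symmetry: equal slope magnitudes, azimuths at 60 degree steps
  mags <- sqrt(tm$coefficients$slope_x^2 + tm$coefficients$slope_y^2)
  expect_lt((max(mags) - min(mags)) / mean(mags), 0.01)
  az <- sort(atan2(tm$coefficients$slope_y, tm$coefficients$slope_x) %% (2 * pi))
  expect_equal(diff(az), rep(pi / 3, 5), tolerance = 0.01)
  # shift magnitude is monotone in depth and larger close-up
  m2 <- abs(shift_at_depth(tm, 2L, seq(2000, 4000, 100))[, "dx"])
  expect_true(all(diff(m2) < 0))
  # two depths give the exact interpolating line
  loc2 <- s$loc[s$loc$z_um %in% c(2500, 3500), ]
  tm2 <- fit_translation_model(loc2)
  expect_lt(max(tm2$coefficients$rms_x, tm2$coefficients$rms_y), 1e-9)
  # fewer than two depths is underdetermined
  expect_error(fit_translation_model(s$loc[s$loc$z_um == 3000, ]),
               class = "clf_underdetermined_fit")
  expect_error(shift_at_depth(tm, 42L, 3000), class = "clf_lookup_error")
})

test_that("extrapolation outside the calibrated range is flagged", {
  tm <- get_setup3()$model
  sh <- shift_at_depth(tm, 2L, c(1500, 3000, 4500))
  expect_equal(attr(sh, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("noisy calibration recovers the noiseless slopes within 2%", {
  s <- get_setup3()
  arr <- s$array
  scenes <- psf_calibration_stack_scene(depth_range(2000, 4000, 100))
  stack <- lapply(seq_along(scenes), function(i) {
    nm <- noise_model(photon_scale = 3000, read_sigma = 0.001, seed = 100 + i)
    list(z = scenes[[i]]$z,
         frame = render_capture(scenes[[i]]$scene, arr, noise = nm))
  })
  tmn <- fit_translation_model(localize_psfs(stack, s$mask))
  for (id in 2:7) {
    a <- tmn$coefficients[tmn$coefficients$lens_id == id, ]
    b <- s$model$coefficients[s$model$coefficients$lens_id == id, ]
    expect_lt(abs(sqrt(a$slope_x^2 + a$slope_y^2) /
                    sqrt(b$slope_x^2 + b$slope_y^2) - 1), 0.02)
  }
})

test_that("magnification model: parametric law and grid-calibrated table", {
  s <- get_setup3()
  expect_equal(magnification(s$mag, 3000), 1)
  expect_true(all(diff(magnification(s$mag, seq(2000, 4000, 100))) < 0))
  expect_lt(abs(stats::integrate(function(z) magnification(s$mag, z),
                                 2000, 4000)$value / 2000 - 1.04), 5e-3)
  # tabulated calibration from synthetic 100 um grids recovers d_s/z within 1%
  arr <- s$array
  tab <- do.call(rbind, lapply(c(2500, 3500), function(z) {
    fr <- render_capture(grid_target_scene(100, 400, z), arr)
    tibble::tibble(z_um = z, m = measure_grid_magnification(fr, s$mask, 100))
  }))
  expect_lt(max(abs(tab$m / (3000 / tab$z_um) - 1)), 0.01)
  mg <- fit_magnification("tabulated", table = tab)
  # exact at the calibrated depths, linear midpoint in between
  expect_lt(abs(magnification(mg, 2500) - 1.2), 0.015)
  expect_equal(magnification(mg, 3000), mean(tab$m), tolerance = 1e-9)
  expect_error(fit_magnification("tabulated", table = tab[1, ]),
               class = "clf_invalid_parameter")
  expect_error(fit_magnification("parametric"), class = "clf_invalid_parameter")
})

test_that("calibration JSON round-trips models exactly", {
  s <- get_setup3()
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(s$model, s$mag, p)
  cal <- read_calibration(p)
  expect_equal(cal$translation$coefficients, s$model$coefficients,
               tolerance = 1e-12)
  expect_equal(cal$translation$knots, s$model$knots, tolerance = 1e-12)
  expect_equal(shift_at_depth(cal$translation, 3L, 2750),
               shift_at_depth(s$model, 3L, 2750))
  expect_equal(magnification(cal$magnification, 2600),
               magnification(s$mag, 2600))
})
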