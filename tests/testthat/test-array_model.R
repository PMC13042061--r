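test_that("numerical aperture follows sin(arctan((D/2)/f))", {
  lens <- lenslet_spec(1L, c(0, 0), 370, 1250, 1750)
  expect_lt(abs(lenslet_na(lens, 1750) - 0.105), 0.001)
  expect_equal(lenslet_na(lens, 1500), sin(atan(185 / 1500)), tolerance = 1e-12)
  expect_lt(abs(lenslet_na(lens, 1500) - 0.1224), 5e-5)
  # degenerate aperture rejected; D -> 0 limit sends NA -> 0
  expect_error(lenslet_spec(1L, c(0, 0), 0, 1250, 1750),
               class = "clf_invalid_parameter")
  tiny <- lenslet_spec(1L, c(0, 0), 1e-9, 1250, 1750)
  expect_lt(lenslet_na(tiny, 1750), 1e-11)
  expect_error(lenslet_na(lens, -5), class = "clf_invalid_parameter")
})

test_that("ring tilt reproduces the convergence geometry", {
  expect_equal(tilt_for_intersection(0, 3000), 0)
  expect_lt(abs(tilt_for_intersection(370, 3000) - 7.031), 1e-3)
  # the ring radius implied by the printed design tilt
  expect_lt(abs(tilt_for_intersection(371.4, 3000) - 7.057), 0.01)
  expect_error(tilt_for_intersection(370, -1), class = "clf_invalid_parameter")
})

test_that("axis convergence: geometric tilt exact, printed tilt within 1%", {
  arr <- test_array()
  expect_lt(axes_convergence(arr), 1e-6)
  arr_printed <- compound_array(tilt_deg = 7.057, sensor = ov5647_sensor(3L))
  conv <- axes_convergence(arr_printed)
  expect_gt(conv, 1)           # the printed tilt does not converge exactly
  expect_lt(conv, 0.01 * 3000) # but stays within the stated 1% tolerance
})

test_that("pinhole magnification and its depth average", {
  arr <- test_array()
  expect_equal(magnification_at_depth(arr, 3000), 1)
  expect_equal(magnification_at_depth(arr, 2000), 1.5)
  expect_lt(abs(mean_magnification(arr, 2000, 4000) - 1.0397), 1e-4)
  # closed form against a numerical-quadrature oracle
  num <- stats::integrate(function(z) magnification_at_depth(arr, z),
                          2000, 4000, rel.tol = 1e-12)$value / 2000
  expect_equal(mean_magnification(arr, 2000, 4000), num, tolerance = 1e-10)
  expect_error(magnification_at_depth(arr, 0), class = "clf_invalid_parameter")
})

test_that("thin-lens conjugates give the ~2 mm detection range", {
  arr <- test_array()
  cr <- conjugate_object_range(arr$lenslets[[1]], 3000)
  expect_equal(unname(cr), c(1250 * 3000 / 1750, 1750 * 3000 / 1250),
               tolerance = 1e-12)
  expect_lt(abs(cr[1] - 2142.9), 0.1)
  expect_lt(abs(cr[2] - 4200), 0.1)
  span <- cr[2] - cr[1]
  expect_lt(abs(span - 2000) / 2000, 0.1)   # "nearly 2-mm axial detection range"
  # midpoint focal images the 3 mm design depth exactly
  mid <- lenslet_spec(9L, c(0, 0), 370, 1500, 1500)
  expect_equal(unname(conjugate_object_range(mid, 3000)), c(3000, 3000))
  expect_error(conjugate_object_range(arr$lenslets[[1]], 1700),
               class = "clf_no_real_conjugate")
})

test_that("chief-ray projection: convergence point, linearity, occlusion", {
  arr <- test_array()
  # the intersection point lands on every lenslet's elemental reference centre
  for (l in arr$lenslets) {
    p <- project_point(arr, l$id, c(0, 0, arr$intersection_distance))
    expect_false(p$occluded)
    expect_equal(c(p$x_um, p$y_um), 2 * l$center, tolerance = 1e-9)
  }
  # sensor displacement exactly proportional to lateral displacement, slope m(z)
  for (z in c(2200, 3000, 3800)) {
    d <- seq(-50, 50, by = 10)
    p <- project_point(arr, 1L, cbind(d, 0, z))
    slopes <- diff(p$x_um) / diff(d)
    expect_equal(slopes, rep(-magnification_at_depth(arr, z), length(slopes)),
                 tolerance = 1e-12)
  }
  # occlusion: brute-force ray/stop-disk oracle on a chosen geometry
  pt <- c(430, 0, 3000)
  for (id in c(1L, 2L, 5L)) {
    lens <- arr$lenslets[[id]]
    tq <- (pt[3] - arr$stop$height_above_lenslets) / pt[3]
    q <- pt[1:2] + tq * (lens$center - pt[1:2])
    expect_equal(project_point(arr, id, pt)$occluded,
                 sum(q^2) > (arr$stop$diameter / 2)^2)
  }
  expect_true(project_point(arr, 2L, pt)$occluded)    # beyond lens 2's window
  expect_false(project_point(arr, 1L, pt)$occluded)   # visible to the centre
  expect_error(project_point(arr, 99L, c(0, 0, 3000)), class = "clf_lookup_error")
})

test_that("field-of-view windows follow the similar-triangles model", {
  arr <- test_array()
  h <- arr$stop$height_above_lenslets
  a <- arr$stop$diameter
  for (z in c(2100, 3000, 3900)) {
    w <- fov_windows_at_depth(arr, z)
    expect_equal(w$radius_um, rep((a / 2) * z / h, 7), tolerance = 1e-12)
    for (i in seq_len(7)) {
      l <- arr$lenslets[[i]]
      expect_equal(c(w$cx_um[i], w$cy_um[i]), l$center * (1 - z / h),
                   tolerance = 1e-9)
    }
  }
  # window diameter affine in z: perfect linear fit
  zs <- seq(2000, 4000, by = 100)
  diam <- vapply(zs, function(z) 2 * fov_windows_at_depth(arr, z)$radius_um[1],
                 numeric(1))
  fit <- stats::lm(diam ~ zs)
  expect_lt(max(abs(stats::resid(fit))) / mean(diam), 1e-9)
  # degenerate stop -> empty windows
  arr0 <- compound_array(stop = aperture_spec(1e-9, 2000),
                         sensor = ov5647_sensor(3L))
  expect_lt(max(fov_windows_at_depth(arr0, 3000)$radius_um), 1e-3)
})

test_that("zone extents nest and bracket the design diameters", {
  arr <- test_array()
  ze <- zone_extents(arr, depth_range(2000, 4000, 250), n = 301)
  expect_true(all(ze$foveated_um <= ze$blend_um + 1e-9))
  expect_true(all(ze$blend_um <= ze$peripheral_um + 1e-9))
  m <- attr(ze, "means")
  # foveated-diameter bracket over plausible stop heights (sweep oracle)
  for (h in c(1000, 1500, 2000)) {
    arrh <- compound_array(stop = aperture_spec(600, h), sensor = ov5647_sensor(3L))
    zh <- zone_extents(arrh, depth_range(2100, 4000, 475), n = 241)
    mh <- attr(zh, "means")["foveated_um"]
    expect_gt(mh, 400); expect_lt(mh, 800)
  }
  # with the default stop the peripheral zone reaches ~2 mm at the far depth
  expect_gt(max(ze$peripheral_um), 1800)
  # equal thresholds make the zones coincide
  z1 <- zone_extents(arr, c(3000), foveated_min = 1, blend_min = 1, n = 241)
  expect_equal(z1$foveated_um, z1$blend_um)
  expect_equal(z1$blend_um, z1$peripheral_um)
})

test_that("geometry serializes to a config block and back", {
  arr <- compound_array(tilt_deg = 7.057, sensor = ov5647_sensor(2L),
                        stop = aperture_spec(550, 1800))
  cfg <- array_to_config(arr)
  arr2 <- array_from_config(cfg)
  expect_equal(arr2$lenslets[[2]]$tilt_deg, 7.057)
  expect_equal(arr2$stop$diameter, 550)
  expect_equal(arr2$sensor$pixel_pitch, 2.8)
  expect_equal(array_to_config(arr2), cfg)
})
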