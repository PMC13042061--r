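# Shared fixtures. Heavy objects (calibrated models) are built lazily once
# per test session and reused across files.

.fx <- new.env(parent = emptyenv())

# Default array on a 3x-binned sensor (4.2 um pitch, 864 x 648 px): the
# standard desk-scale configuration for pipeline tests.
test_array <- function(binning = 3L) compound_array(sensor = ov5647_sensor(binning))

# Pixel coordinate of a sensor-plane position (um) for an array.
sensor_px <- function(array, xy_um) {
  c(xy_um[1] / array$sensor$pixel_pitch + (array$sensor$width_px + 1) / 2,
    xy_um[2] / array$sensor$pixel_pitch + (array$sensor$height_px + 1) / 2)
}

# Calibrated setup at binning 3: aperture mask, PSF localizations,
# translation + magnification models.
get_setup3 <- function() {
  if (is.null(.fx$setup3)) {
    arr <- test_array(3L)
    mask <- segment_apertures(render_aperture_frame(arr))
    scenes <- psf_calibration_stack_scene(depth_range(2000, 4000, 100))
    stack <- lapply(scenes, function(el)
      list(z = el$z, frame = render_capture(el$scene, arr)))
    loc <- localize_psfs(stack, mask)
    .fx$setup3 <- list(array = arr, mask = mask, stack = stack, loc = loc,
                       model = fit_translation_model(loc),
                       mag = fit_magnification("parametric",
                                               sensor_distance = arr$sensor_distance))
  }
  .fx$setup3
}

# ROI (pixel window) centred on the sensor centre.
center_roi <- function(array, half_px) {
  W <- array$sensor$width_px; H <- array$sensor$height_px
  list(x = round(c((W + 1) / 2 - half_px, (W + 1) / 2 + half_px)),
       y = round(c((H + 1) / 2 - half_px, (H + 1) / 2 + half_px)))
}

# Count connected components above a threshold fraction of the maximum.
count_spots <- function(img, frac = 0.05) {
  bw <- img > frac * max(img)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  max(lab)
}
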