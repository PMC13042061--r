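---
title: "Optical model and reconstruction methods"
author: "compoundlf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical model and reconstruction methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compoundlf)
```

# The imaging system being modeled

`compoundlf` simulates and reconstructs data from a compact foveated
compound-eye light-field imager: seven 370 µm lenslets — one on the optical
axis, six on a hexagonal ring of radius 370 µm — sharing a single planar
sensor 3 mm below the array. The ring lenslets are tilted so that all seven
optical axes converge 3 mm above the array, at the midpoint of the usable
object-depth range; a single 600 µm field stop above the lenslets limits
every lenslet's field of view so that the seven *elemental images* remain
disjoint on the sensor. Each lenslet carries a logarithmic-axicon phase
profile whose radial zones focus over a continuous focal segment
(1,250–1,750 µm for the central lenslet, 1,500–2,000 µm for the ring),
giving every lenslet an extended depth of focus on the fixed sensor plane.

Because the six ring lenslets view the scene from laterally displaced
positions, an object's elemental images shift with its depth (parallax).
Shift-and-add refocusing exploits this: translate each edge elemental image
by its depth-dependent *translation curve* and sum; features at the chosen
depth converge, features elsewhere disperse. Counting how many lenslet
fields of view cover each reconstructed pixel yields the *shading map*,
whose thresholds define three functional zones: *foveated* (coverage ≥ 6,
all-lenslet overlap, full volumetric reconstruction), *blend* (3–5,
moderate parallax), and *peripheral* (1–2, wide-field 2D context).

# Geometry module

All lengths are micrometres; the origin sits at the central lenslet vertex
with +z toward the object and the sensor plane at z = −3,000 µm.
Projection is a thin-pinhole chief-ray model: each lenslet maps an object
point through its vertex onto the sensor; diffraction blur is supplied
separately. Within this model,

* magnification at depth z is m(z) = d<sub>s</sub>/z with d<sub>s</sub> the
  sensor distance, averaging
  d<sub>s</sub>·ln(z<sub>max</sub>/z<sub>min</sub>)/(z<sub>max</sub>−z<sub>min</sub>)
  ≈ 1.04 over 2–4 mm — the design's "≈1× magnification";
* the object-side detection range follows from thin-lens conjugates of the
  focal-segment endpoints at the fixed sensor distance:
  u(f) = (1/f − 1/d<sub>s</sub>)⁻¹, giving 2.14–4.20 mm (span ≈ 2.06 mm) for
  the central lenslet;
* the field-of-view window of a lenslet at depth z is the disk of object
  points whose chief ray clears the stop: diameter a·z/h and centre
  c·(1 − z/h) for stop diameter a, stop height h and lenslet centre c —
  affine in z, which is why the field of view scales linearly with imaging
  distance.

Two geometric constants deserve comment. First, the ring-lenslet tilt: with
ring radius 370 µm and a 3 mm intersection the exact convergence tilt is
arctan(370/3000) = 7.031°; the nominal design figure of 7.057° corresponds
to a 371.4 µm ring. The constructor computes the tilt from the geometry by
default (so the axis-convergence invariant holds to machine precision) and
accepts the nominal figure explicitly, which still converges within the 1%
tolerance. Second, the stop height above the lenslets, which no catalogue
value fixes: it controls both the zone diameters and the elemental-image
footprints (radius (a/2)·d<sub>s</sub>/h at centre c·(1 + d<sub>s</sub>/h)).
Heights below ≈1.87 mm make neighbouring footprints overlap, defeating the
stop's purpose; the default is 2.0 mm, the smallest round value with
disjoint footprints, which yields a depth-averaged foveated diameter of
≈0.59 mm, a blend extent of ≈0.93 mm and a peripheral extent growing to
≈1.9 mm at the far depth — matching the design's ~600 µm / ~1 mm / up-to-2 mm
zone figures.

```{r zones}
arr <- compound_array()
ze <- zone_extents(arr, depth_range(2000, 4000, 500))
ze
attr(ze, "means")
```

# Wave-optics module

The logarithmic axicon follows the uniform-axial-intensity design: radial
zones map quadratically to focus, f(r) = f<sub>min</sub> + (f<sub>max</sub> −
f<sub>min</sub>)·r²/R², equivalent to the phase
φ(r) = −(k/2α)·ln(1 + α r²/f<sub>min</sub>) with α = Δf/R², which satisfies
the ray condition dφ/dr = −k·r/f(r) and degenerates to the paraxial
spherical phase as Δf → 0. Fields are propagated with the exact scalar
angular-spectrum method on square grids (default 2048², pitch spanning three
aperture diameters, which samples the steepest lens phase at ≥ 4 samples per
fringe); power is conserved to 10⁻⁶ apart from evanescent loss. Sensor-plane
point-spread functions are resampled to the pixel pitch and unit-normalized.
The default wavelength is 635 nm, the red characterization wavelength.

Simulated at 635 nm, the ideal axicon's central-lenslet PSF keeps a compact
core across the detection range — lateral FWHM ≈ 5 µm at the 3 mm design
depth, varying less than 3× over 2.4–4 mm, consistent with the 4–11 µm
resolving-power bracket — while an equal-aperture spherical lenslet's PSF
degrades within ≈ ±0.15 mm of its single conjugate.

## What the ideal coherent model does and does not reproduce

The ideal scalar simulation reproduces the designed *focal segment*: under
plane-wave illumination the axicon maintains a focused core from
f<sub>min</sub> to f<sub>max</sub>, and mapping that segment to object space
through the thin-lens conjugates gives the ≈2 mm detection range. It also
reproduces the spherical reference's in-focus range with the sensor fixed at
3 mm: ≈0.2–0.3 mm by a variance-of-Laplacian half-maximum criterion. The
ratio of designed segment to spherical range is therefore ≈7–9, the
six-fold-plus depth-of-focus extension the architecture is built around.

What the ideal coherent model does *not* reproduce is that same factor under
a single uniform contrast criterion. Two genuine wave effects intervene:
the exact axicon's on-axis response oscillates by tens of percent
(interference between the stationary zone and aperture-edge waves — the
oscillation is geometric, so wavelength averaging over a laser linewidth
does not smooth it), and the in-focus *energy fraction* varies several-fold
across the segment because near depths are served by the broad central zone
(Airy-like PSF) while far depths are served by a narrow outer annulus
(Bessel-like PSF with a faint core atop a halo). A variance-of-Laplacian
score, being quadratic in intensity, compounds both effects: the measured
contiguous half-maximum range of the ideal axicon comes out at ≈0.5–0.6 mm
rather than the designed ≈2 mm, and `edof_ratio()` reports ≈2–3 rather than
≥6. Fabricated lenslets with smoothed profiles, broadband incoherent
emission and camera-referred scoring do not show these ideal-coherent
penalties. `edof_ratio()` therefore reports the honest contrast-based
measurement together with `conjugate_span_um`, the designed-segment
equivalent, and both views are printed by the characterization report.

# Synthetic phantoms and the forward renderer

The phantom generator mirrors the physical test objects: 2.5 µm calibration
beads stepped along the axis at 100 µm (the PSF stack), 15.4 µm beads in
three layers spaced 170 µm (stacked #1.5 coverslips), and a 100 µm-pitch
planar grid target. Rendering projects every emitter through each
non-occluded lenslet, stamps a geometric bead image (diameter scaled by
m(z)) convolved with the PSF, and accumulates one sensor frame. The fast
default PSF is a Gaussian of 5 µm sensor-plane FWHM — the wave-optics kernel
width of the log-axicon lenslet at the 3 mm design depth — held constant
across the detection range, as an extended-depth-of-focus optic is designed
to achieve; full wave-optics kernels are available behind
`psf_source = "wave_optics"`. Stamps are unit-normalized and placed with
1/16-pixel quantization, so frame energy equals intensity × contributing
lenslets and sub-pixel centroids are preserved to < 0.1 px. Noise is
Poisson shot noise at a configurable photon scale followed by Gaussian read
noise and a constant offset, all seeded.

What the generator deliberately omits: optical aberrations and fabrication
deviations of the printed profiles, scattering and refraction in thick
samples, chromatic effects, Bayer mosaicing and sensor nonlinearity, and
structured backgrounds. Passing tests therefore validate the geometry,
calibration and reconstruction logic — not robustness to those real-data
effects.

The simulations in this package run on binned variants of the 2592×1944 @
1.4 µm sensor (2× binning for point-source resolution studies, 3× for
pipeline and autofocus studies); binning preserves the physical sensor
extent while keeping desk-scale runtimes, and every quantity is computed in
physical units so the binning choice only sets the sampling density.

# Calibration

The white-light aperture frame is thresholded (Otsu by default), labelled,
and ordered centre-first then counterclockwise from +x. PSFs are localized
per footprint by intensity-weighted centroid above a robust floor (median +
3×MAD). For each edge lenslet the translation curve is the displacement of
the central PSF minus the edge PSF versus depth. The model stores the
measured knots and three evaluators:

* `"interp"` (default): piecewise-linear interpolation between the
  calibrated depths — translation distances at unsampled depths are
  interpolated, and with 100 µm calibration steps the interpolation error of
  the underlying curve is far below a hundredth of a pixel;
* `"linear"`: a single least-squares line in z, whose slope/intercept and
  residual RMS are always reported. In the pinhole model the shift is affine
  in 1/z, not z, so over 2–4 mm the global line leaves systematic residuals
  of ≈3 px at 4.2 µm pitch (≈10–40 µm on the sensor); evaluating with it
  visibly mis-registers refocusing near the range ends, which is why it is
  reported but not the evaluation default;
* `"invz"`: a least-squares line in 1/z, near-exact for this geometry.

Magnification is calibrated either parametrically (m(z) = d_s/z) or from
measured grid-pitch ratios at two or more depths (tabulated, linearly
interpolated).

# Reconstruction pipeline

`reconstruct()` composes five stages: (1) rolling-ball background
subtraction — grayscale opening with a non-flat ball structuring element
(default radius 25 px; skipped when the radius is `NULL`); (2) elemental
extraction by the aperture mask; (3) shift-and-add refocusing per depth with
sub-pixel bilinear translation (Fourier-free, energy-conserving before
masking); (4) shading-map construction by translating the binary footprints
identically, zone classification (foveated ≥ 6, blend 3–5, peripheral 1–2 —
the nominal peripheral definition "≤ 3" overlaps the blend band, so the
disjoint 1–2 convention is the documented default, configurable), and
feature masking: an adaptive-threshold + binary-opening mask from the
central elemental image zeroes voxels in the foveated and blend zones that
the central lenslet does not corroborate, suppressing cross-lenslet
collision ghosts while never touching the peripheral zone; (5) per-layer
magnification rescaling about the optical axis to the common object-space
pixel size at the reference depth (the axis-intersection depth by default).

Depth from focus uses the variance of the 3×3 Laplacian per layer (the
standard degree-of-focus score; it is also the default score in the
wave-optics module) with three-point parabolic peak interpolation, ties
broken toward smaller z.

Numerical choices worth noting: bilinear shifts sample as zero outside the
frame; shading counts are thresholded at 0.5 after interpolation so the map
stays integer; the adaptive-threshold window (15 px) and opening radius
(1 px) must bracket the genuine feature scale — the opening radius in
particular must stay below the smallest real feature's radius; the
rolling-ball cost grows with radius², so large-radius backgrounds on full
sensors are better computed at binned resolution.

# Problem sizes and expected figures

The bundled tests and the acceptance script run, at the sizes above, in a
few minutes end to end and compute among others:

* edge-lenslet numerical aperture sin(arctan(185/1750)) ≈ 0.105;
* central-lenslet detection range ≈ 2.06 mm (2.14–4.20 mm);
* depth-averaged magnification ≈ 1.04;
* autofocus recovery of a 1.7 mm stage translation (grid target at 2.15 and
  3.85 mm, chosen symmetric about the 3 mm design midpoint) to well within
  5% — with the piecewise translation model the residual error is dominated
  by noise, not by model bias;
* reconstructed axial FWHM of a foveated point source ≈ 65 µm at 3 mm
  (within the 60–180 µm axial-resolution band: the refocused peak decays
  once the six edge spots, moving radially at |d(shift)/dz| ≈ 0.12 µm/µm,
  separate by about one spot width);
* three-layer bead phantom layer separations recovered within 5%.

# Known limitations

* The pinhole projection ignores aberrations and pupil effects; tilt enters
  only through the axis geometry.
* The contrast-based EDOF measurement of the ideal coherent axicon
  understates the designed six-fold extension, as analysed above.
* Brightfield (absorbing) specimens are outside the forward model; only
  emissive scenes are rendered.
* Rotation or affine per-lenslet registration is not modelled — translation
  only, as in the reconstruction it implements.
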