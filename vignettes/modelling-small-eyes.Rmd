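---
title: "Modelling vision in small eyes without an image plane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vision in small eyes without an image plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Many invertebrates carry eyes of a tenth of a millimetre that provide only
low-resolution vision. Such eyes rarely have a defined image plane: the lens
abuts the photoreceptor volume directly, most of the retina is under-focused,
and classical visual-optics quantities (focal length, F-number, receptor
acceptance angle from geometry) are not well defined. The only way to state
what such an eye can see is to compute, for every photoreceptor, its *angular
sensitivity function* (ASF) - the relative amount of light it absorbs as a
function of the direction a parallel beam arrives from - and to derive
resolution, field of view and sensitivity maps from the full set of ASFs.

`ocellus` implements this programme by geometric-optics ray tracing through
triangular-mesh eye geometry:

1. **Geometry.** The eye is a set of closed (watertight) triangle meshes -
   cornea, lens, retinal volume, screening pigment - each with a refractive
   index. Meshes are read from STL or generated parametrically. An octree
   accelerates ray-mesh queries; it is an accelerator only and never changes
   a result (this is tested against a brute-force scan).
2. **Tracing.** For each of ~4000 directions on a hemisphere covering the
   visual field, a parallel bundle of ~10000 evenly spaced rays in a 50 um
   radius disc is traced through the meshes. At every surface crossing the
   ray refracts by Snell's law; Fresnel losses are ignored (they amount to a
   few percent at these index steps and the published method omits them).
   Totally internally reflected rays reflect specularly and continue, with a
   hard cap of 50 surface events; a strict terminate-on-TIR mode exists to
   probe sensitivity to that choice.
3. **Absorption.** Photoreceptors are absorbing truncated cones with a
   non-absorbing central core, bases packed hexagonally (~2.5 um apart) on
   the back retinal wall, apices at the lens-facing surface. Ray segments
   inside the retinal volume are marched in 0.25 um steps; at each step
   inside at least one receptor's absorbing shell the remaining power decays
   by Beer-Lambert absorption (coefficient 0.0067 per um) and the absorbed
   amount is credited, split equally among the receptors sharing the step.
   Power is conserved to floating-point accuracy: absorbed + exited +
   terminated = input.
4. **Analysis.** Per-receptor absorbed power over the sampled directions is
   interpolated onto a regular 1-degree azimuth x elevation grid to form the
   ASF. Viewing directions are 30%-of-peak weighted centroids; cut-off
   spatial frequencies are the full width at half maximum of the ASF's
   Fourier modulus along the horizontal and vertical frequency axes; the
   field of view is the set of directions where some receptor still collects
   at least 5% of its own peak absorption.
5. **Image filtering.** The ASFs, resampled through an equisolid-angle
   fisheye calibration (r = 2 f sin(theta/2)), become per-receptor
   pixel-weight maps. Applying them to a calibrated photograph gives receptor
   responses; a Voronoi map seeded at the projected viewing directions,
   white-normalized so uniform white maps to uniform white and edge-filtered
   at 5% of the maximum total sensitivity, renders what the eye encodes.

# Worked example

```{r}
library(ocellus)

eye <- make_velvetworm_eye()              # deterministic synthetic eye
receptors <- place_receptors(eye, spacing = 2.5)
cfg <- optical_config(n_directions = 1000, rays_per_beam = 2000)

tab <- trace_absorb(eye, receptors, cfg)  # receptor x direction matrix
map <- resolution_map(tab)                # ASF widths, cut-offs, FOV, pupil
print(map)
plot(map, "cutoff_h")

# image filtering
calib <- fisheye_calibration(360, axis = eye$aperture_axis)
asfs <- lapply(map$receptors$id, function(id) angular_sensitivity(tab, id))
stack <- build_transfer_stack(asfs, calib)
scene <- make_test_pattern("bessel-dot-array", calib, frequency = 0.095)
view <- render_receptor_image(apply_filter(scene, stack), stack)
plot(view)
```

# The synthetic velvet-worm eye

The study species' reconstructed eye mesh is not publicly deposited, so the
package ships a parametric generator (`make_velvetworm_eye()`) that encodes
the published qualitative and quantitative constraints of the real eye:

* a ~100 um eye with a smooth, protruding cornea whose own radius of
  curvature is smaller than the eyeball's, covering a homogeneous biconvex
  lens (air 1.0, cornea 1.4, lens 1.44, retina 1.36; a measured lens index
  of 1.485 is selectable via `optical_config(n_lens = 1.485)`);
* no vitreous gap: the retinal volume's front face is inset 0.25 um *into*
  the lens, so the two watertight volumes deliberately overlap instead of
  sharing numerically fragile coincident surfaces (the tracer resolves
  overlaps by volume priority);
* a distinctly asymmetric retina with a deep posterior pouch lying opposite
  the forward viewing direction (~45 degrees off the aperture axis in the
  horizontal plane), so the forward field enjoys both a longer absorbing
  path and better focus;
* receptors in a near-hexagonal array at 2.5 um spacing, shaped as absorbing
  cones with a non-absorbing core, whose overlap emulates interdigitating
  microvilli;
* a surrounding screening-pigment cup, open only over the optical aperture,
  that terminates every ray reaching it;
* mesh resolutions in the 7000-17000 triangle range per optical surface.

Dimensions the anatomy does not pin down - corneal curvature radius, lens
rear curvature, central retinal depth, pouch depth/width/position, the
angular extent of the receptor-bearing retina, receptor radii - are free
parameters of `eye_params()`. Their defaults were calibrated once toward
the published functional figures (forward acute zone of ~0.11 cycles/deg,
~140 x 130 degree field of view, smallest ASF width ~10 degrees,
forward-to-lateral resolution ratio ~2, higher summed absorption in the
forward field); the acceptance script and the acceptance test suite
recompute all of these from scratch, and the Known limitations section
names the two figures that resist the emulation. The calibration
is a property of the generator's defaults, not of the analysis code, and
none of the optics constants (indices, absorption coefficient, beam
geometry) were touched by it.

What the generator does *not* emulate: histological irregularities and
inter-individual variation (the published comparison suggests these hardly
affect the computed performance), the exact free-form lens shape (ours is a
surface of revolution), microvillar ultrastructure, and any spectral or
temporal properties. Tests passing on this synthetic eye therefore validate
the *method* and the calibrated emulation - not anatomical measurements of
a particular animal.

# Reference eyes as oracles

Two analytically tractable eyes validate the tracer end to end:

* `make_ball_lens_eye(R, n)` - a homogeneous glass-bead lens in air with an
  absorbing detector shell. The paraxial back focal distance
  `BFD = R (2 - n) / (2 (n - 1))` (25 um for R = 50 um, n = 1.5) is
  recovered by tracing to within 2%.
* `make_concentric_eye()` - concentric spherical shells, rotationally
  symmetric about every axis through the centre, which catches
  orientation-dependent bugs anywhere in the chain. This oracle is so
  under-focused that its angular sensitivities are broad gradients that
  never fall below half their peak within the hemisphere, so symmetry is
  asserted on the quantities it defines: mirror symmetry of directional
  profiles, monotone off-axis decline, and uniformity of summed absorption
  and per-receptor total sensitivity (all within Monte-Carlo noise).

# Numerical choices

* **Units.** STL files carry no units; the package declares micrometres
  throughout. `read_stl(scale =)` rescales on import.
* **Self-intersection guard.** After every surface event the ray advances
  1e-6 um before the next intersection query, the standard offset against
  re-hitting the departing facet.
* **Shared edges.** Moller-Trumbore intersection uses an inclusive
  barycentric test (>= 0 within 1e-9), so rays cannot escape through
  triangle seams; hits duplicated on shared edges are resolved by the
  minimum-t rule.
* **Octree defaults.** Leaf capacity 32, maximum depth 10 - balanced for
  meshes of ~10^4 triangles; correctness never depends on them.
* **Normals.** Per-face geometric normals by default, matching the published
  method's faceted surfaces. `optical_config(smooth_normals = TRUE)`
  interpolates vertex normals, which is markedly more accurate on the
  analytic sphere-based reference eyes and is used in the focal-distance
  validation.
* **Medium bookkeeping.** Volume membership along a ray is tracked by
  crossing parity over the watertight meshes, initialised outside the eye.
  Where volumes overlap by design, the highest-priority volume (retina >
  lens > cornea) defines the medium. Crossing a boundary between identical
  media is recorded as an index-match no-op.
* **Screening pigment.** The retina mesh is a perfect absorber for rays
  arriving from any medium but its window medium (the lens), and for rays
  leaving the retinal volume from inside. The pigment cup absorbs
  unconditionally.
* **Absorption step.** 0.25 um (~1/10 receptor spacing); halving it changes
  totals by far less than 0.1%. The equal-split overlap rule keeps total
  absorption independent of how many receptors share a step; a closed-form
  product of exponentials is recovered on straight paths.
* **ASF interpolation.** Scattered direction samples are interpolated by
  moving least squares (weighted local-linear fit over the 7 nearest
  samples, with the azimuth axis locally metric-corrected by cos(elevation)).
  This is first-order accurate like barycentric interpolation on a
  triangulation; cells farther than twice the direction-lattice spacing from
  any sample are set to zero, values are clipped at zero. The effective
  angular resolution of an ASF is therefore bounded by the direction-lattice
  spacing (about 4 degrees at 1000 directions), which slightly widens very
  narrow sensitivity functions.
* **Cut-off convention.** "Width of the signal in Fourier space" is read as
  the full width at half maximum of the Fourier modulus; the axis slices are
  computed by the projection-slice identity (1-D transforms of the axis
  projections), which is exactly the 2-D transform on the axes and is tested
  against it. A half-width (`"hwhm"`) mode is provided since the factor-two
  convention is ambiguous in the literature; the FWHM reading is the default
  because it reproduces the published forward acute-zone value on the
  calibrated eye.
* **Field-of-view extents.** The 5% criterion is applied receptor-wise
  (absorption relative to that receptor's own peak), which reduces to the
  published most-peripheral-receptor rule at the field edge without needing
  a definition of "peripheral". Extents are measured as the angular range of
  in-field directions within a 6-degree band about the horizontal (or
  vertical) plane through the peak-absorption direction, plus one
  direction-lattice spacing for the finite sampling cell.
* **Problem sizes.** The published conditions (4000 directions x 10000 rays)
  are the package defaults. The validation suite and the acceptance script
  run a reduced trace of 1000 directions x 2000 rays (and 500 x 1000 for the
  symmetry oracle), which keeps per-receptor Monte-Carlo noise a few percent
  while completing in minutes; doubling either count changes per-receptor
  cut-offs by only a few percent.

# Design decisions on genuinely open points

* **Overlap attribution.** The published method states that receptor shells
  overlap but not how shared absorption is attributed; the package splits it
  equally among the containing receptors, the simplest symmetric rule. Total
  absorption is provably independent of the rule.
* **Receptor shape.** Radii are not quantified anatomically. The synthetic
  eye's defaults (base 3.0 um, apex 2.2 um, core 0.5 um) give the strongly
  interdigitating overlap seen in the ultrastructure at 2.5 um spacing and
  keep the deep pouch interior covered by absorbing material; for bare
  meshes `place_receptors()` defaults to a slimmer 2.0/0.5/0.5 um cone. All
  are exposed.
* **Receptor axes.** Along the local line from the back wall toward the
  lens, found by casting from each base toward the lens centroid and taking
  the retinal exit point as the apex.
* **Beam placement.** Parallel rays make the source distance irrelevant;
  beams start on a disc tangent to a sphere of twice the eye's bounding
  radius, aimed at the eye centroid.
* **Hemisphere sampling.** A deterministic Fibonacci lattice ("evenly
  distributed" is all that is published); no random numbers anywhere in the
  pipeline, so identical configurations reproduce bit-identical artifacts.
* **Colour.** Images are converted to luminance before filtering; the
  modelled receptors are of a single spectral type.
* **Behavioural test patterns.** The piecewise-sine target is one full sine
  period across the target width (continuous with the 0.5 background), the
  difference-of-gaussians spot is balanced to leave mean luminance
  unchanged, and the dot array places Bessel-profile dots on a hexagonal
  grid over the sphere with spacing 1/frequency. These are parameterized
  approximations of the published stimulus descriptions, not digitized
  copies of the original stimuli.

# Known limitations

* Geometric optics only: no diffraction (the Rayleigh angle `1.22 lambda/d`
  for a 100 um aperture at 500 nm is ~0.35 degrees, negligible against
  ~10 degree sensitivities - `diffraction_limit()` computes this), no
  polarization, no Fresnel losses, no wavelength dispersion.
* No photon-noise simulation: responses are noiseless expected absorptions.
* The synthetic eye is a calibrated emulation; absolute agreement with the
  published maps is expected only at the reduced-precision level the
  acceptance criteria state (orderings strict, values within ~25%). Two
  figures resist the emulation: the forward-to-lateral resolution ratio
  comes out nearer 3x than the published ~2x (the compact synthetic retina
  holds its lateral receptors close to the nodal region, broadening their
  sensitivities), and the modulation of the 10-degree behavioural pattern is
  several-fold lower than published (the emulated sensitivities carry
  heavier flanks, and few receptor viewing directions fall inside so small a
  target). The acceptance suite reports both as computed.
* Very narrow ASFs (a few degrees) are widened by the direction-lattice
  resolution; increase `n_directions` if that regime matters.
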