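---
title: "Quantifying nauplius swimming: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nauplius swimming: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naupflow)
```

naupflow quantifies how barnacle nauplius larvae swim and how they disturb
the water around them. The raw material is high-speed video: per-frame
landmark digitizations of the larva (the two frontal-horn tips, the
dorsal-thoracic-spine tip, and the right-side tips of the antennule `ant1`,
antenna `ant2`, and mandible `mand`), and time-resolved 2-D velocity fields
from micro-particle image velocimetry (PIV). This vignette documents the
models and conventions the package implements, the parameters that matter,
what the synthetic-data generators do and do not emulate, and the numerical
decisions that were genuinely open.

## Body frame and kinematic definitions

All kinematics derive from two constructions:

* the **body centroid**, the mean of the three body landmarks, and
* the **tail vector CT**, from the centroid to the dorsal-thoracic-spine
  tip.

The angle of appendage *i* is the angle between CA (centroid to appendage
tip) and CT,

$$\theta_i = \cos^{-1}\left(\frac{\vec{CA}\cdot\vec{CT}}
  {\lVert \vec{CA}\rVert\,\lVert\vec{CT}\rVert}\right) \in [0^\circ, 180^\circ],$$

so 0° points at the tail and 180° points directly forward. Because the
angle is a ratio of dot products it is invariant under rigid rotation and
translation of the image — a property the test suite checks explicitly.

A displacement step between frames is classified by the sign of its dot
product with CT: negative = **forward** (away from the tail), positive =
**backward**, zero = neutral. From these come the Table-style metrics
produced by `measure_kinematics()`:

* **U**, average swimming speed: path length over elapsed time by default.
  Net-displacement-over-time is available via `run_config(speed_mode =
  "net")`; the path-length reading was chosen because beat-cycle
  back-and-forth is real locomotor output, not tracking noise, at these
  frame rates.
* **Re = U·L/ν** with L the carapace length and ν = 9.5×10⁻⁷ m² s⁻¹ by
  default (seawater, 25 °C, 33 psu). L comes from
  `run_config(body_length=)`; if absent, the mean distance from the
  frontal-horn midpoint to the spine tip is used as a stand-in, which
  overestimates carapace length (it spans horns plus spine) and is
  therefore only a fallback.
* **forward:backward displacement ratio**: per cycle, summed forward step
  magnitudes over summed backward magnitudes, averaged across cycles. A
  cycle with no backward displacement makes the ratio infinite; the result
  carries an `Inf` sentinel plus a flag, and `kinematics_metrics()` maps it
  to `NA` so group means are not contaminated.
* **beat frequency**: detected cycles divided by the elapsed time between
  the first and last cycle boundary.
* **amplitude**: per-cycle angular range (max θ − min θ), averaged across
  cycles. Whether published amplitudes are per-cycle means or grand maxima
  is not decidable from the source material; the per-cycle mean is the
  default and `amplitude_mode = "grand_max"` is the alternative.
* **percent in phase**: percentage of frames in which two appendages'
  angular velocities carry the same sign. Frames where either central
  difference is exactly zero (stroke reversals sampled on the extremum) are
  excluded from the denominator; this makes identical series score exactly
  100 and perfect anti-phase exactly 0 instead of drifting by a frame's
  worth per reversal.
* **angular speeds and separations at mid-stroke**: the mid-power and
  mid-recovery frames are the frames of peak antenna angular speed within
  each half-stroke. Angular separations are absolute differences (signed
  separations are not well defined without a stated convention).

### Cycle segmentation

`segment_cycles()` places cycle boundaries at successive minima of the
3-point-smoothed antenna angle. Within a cycle, the **power stroke** is
the frames where the smoothed angular velocity is negative — the appendage
sweeping toward the tail — and the recovery stroke is the complement. The
sign convention is exposed (`power_stroke_decreasing`) because propulsion
direction is a biological statement, not a mathematical one. Smoothing is
used *only* for segmentation; reported angular speeds use raw central
differences so magnitudes are not biased low. Ties in extremum detection
go to the earlier frame.

## Hydrodynamic operators

All fields are uniform grids of square cells (the working export geometry
is 80 × 64 cells of 16 px, about 25 µm at the study's magnification), with
a body mask whose cells are excluded from every fluid statistic.

* `vorticity()`: ω = ∂v₂/∂x − ∂v₁/∂y by central differences, one-sided at
  edges and against the mask. Central differencing is exact for linear
  fields, which the tests exploit (shear → −k exactly; solid rotation →
  2ω₀ exactly).
* `find_vortices()`: a vortex region is a connected component of cells
  with |ω| above a fraction (default 0.1) of the field's peak |ω|, split
  by sign. The delimitation of "the area bounded by a vortex" is not
  standardized; fixed-fraction-of-peak thresholding is the simplest rule
  that is scale-free in ω, and the fraction is configurable so its
  sensitivity can be reported. Circulation is the discrete area integral
  Γ = Σω·dx·dy. Left/right assignment uses the sign of CT × r against the
  body axis.
* `area_of_influence()`: area of unmasked cells with speed ≥ 0.0005 m s⁻¹
  (the conventional detectability threshold for rheotactic predators at
  nauplius scale); ≥ rather than > at the cutoff, a distinction far below
  measurement resolution.
* `attenuation_fit()`: assumes ‖V‖ ∝ rⁿ. Speed thresholds U* are
  log-spaced between a noise floor (default 10⁻⁵ m s⁻¹; PIV noise) and the
  field maximum; S(U*) is the area at or above U*, r = √(S/π) its
  equivalent-circle radius, and n the OLS slope of ln U* on ln r.
  Three numerical guards matter on a finite grid:
  * the body mask plus a one-cell ring is excluded from the *speed data*
    (edge vectors are unreliable) but its area is added back to every
    S(U*) — the occluded hole sits at the flow source where speed
    certainly exceeds any threshold, so every enclosing iso-speed disc
    must count it;
  * bins whose equivalent radius does not clear the hole radius by at
    least 2 cells are dropped (cell-counted areas of contours hugging the
    hole carry O(h/r) perimeter error);
  * bins whose equivalent radius exceeds the largest circle fully
    contained in the grid around the source are dropped — a clipped
    contour understates r and would bias the slope.
  With these guards the fit recovers generator powers across n ∈ [−3, −1]
  within ±0.05 on the working grid, with and without a body-sized mask.
  The conventional summary value is the fit at the frame of peak flow
  speed (the peak of the power stroke); `attenuation_series()` also emits
  the full time evolution.
* `flux_through_line()`: the 2-D flux Φ = Σ(v·n̂)dl through a reference
  segment, by bilinear sampling and trapezoidal quadrature (exact for
  fields linear along the line). `body_flux_line()` builds the
  conventional lines: dorsal view, a segment of length W (carapace width)
  perpendicular to CT at the posterior margin; lateral view, 1.5×H
  parallel to the axis on the ventral side. The published sketch of these
  lines is schematic, so the offsets are configurable with those defaults.
  The normal points toward the food-capture side: positive flux = flow
  toward the body.
* `relative_flux()`: absolute flux is computed in the laboratory frame;
  relative flux subtracts the body centroid velocity from every cell
  first, which by linearity equals Φ_abs − (v_body·n̂)·L — an identity the
  tests verify to 10⁻¹². Relative flux is the ecologically meaningful
  quantity: fluid comoving with the larva delivers no food.
* `trace_particles()`: classical RK4 through bilinear-in-space,
  linear-in-time velocity, terminating (with a flag) when a particle
  enters the mask or leaves the grid — the bookkeeping used for real lost
  tracers.

## The PIV engine

`piv_multipass()` re-implements the standard multi-pass cross-correlation
scheme: windows shrink from `initial_window` to `final_window` (64→32 px
default; 96→64 for larger larvae), 50% overlap, each pass offsetting the
second frame's windows by the previous pass's integer prediction. The
correlation peak is refined with a 3-point Gaussian sub-pixel fit —
standard PIV practice, with a parabolic fallback where log-weights are
undefined. Vectors with window mask fraction > 0.5, negligible signal, or
first-to-second peak ratio below 1.1 are invalidated. After the final pass
the normalized median test (threshold 2.0, ε = 0.1 px — the universal
defaults, since the commercial implementation used for the original fields
is unpublished) rejects outliers, and rejected/invalid vectors are filled
by iterated local-mean interpolation. Windows are unweighted (no
apodization), documented as a deviation knob. On synthetic particle images
at study seeding density (> 15 particles per final window) the engine
recovers uniform shifts of 0.5–8 px with RMS error below 0.05 px, inside
the 0.1 px design target.

`mask_larva()` chains background-removal filters (Gaussian smoothing and
sliding-extremum subtraction; kernel sizes and threshold are configuration
since no published values exist), thresholds relative to the filtered
maximum, and keeps the largest connected component.

The engine is optional: ready-made fields can enter through
`read_field_sequence()`, whose plain text-plus-JSON dialect replaces
proprietary export formats by contract (columns `x_index, y_index, v1,
v2, mask_flag`, SI units, sidecar geometry).

## Statistics

`perm_t_test()` permutes group labels with the difference of group means
as statistic (a studentized variant is offered; the two are
permutationally equivalent for balanced equal-variance designs) and the
add-one two-sided p-value, p = (1 + #{|T| ≥ |T_obs|})/(1 + n_perm), which
cannot reach zero. `method = "exhaustive"` enumerates all label
assignments and serves as the independent oracle in the tests. The default
9999 permutations match the study's convention; calibration at the study's
group sizes (n = 5 vs 5) is verified by simulation: empirical type-I error
at α = 0.05 falls within [0.035, 0.065] over 2000 null replicates. No
multiple-testing correction is applied by default (none was applied in the
source analyses); Benjamini–Hochberg can be layered on the summary table
by the user. `build_summary()` produces mean ± SE per group per metric
with a significance flag at p < 0.05, skipping tests where a group has a
single usable value.

## Synthetic data: what it does and does not emulate

`make_landmarks()` realizes a `kinematics_spec()`: appendage angles follow
phase-lagged oscillations `θ_i(t) = mean_i + (A_i/2)·cos(ψ(u_i))`, where
the phase warp ψ lets an asymmetric `power_fraction` of the cycle occupy
the decreasing (power) half — real strokes are asymmetric, and the
mid-stroke metrics distinguish power from recovery, so pure sinusoids
would under-exercise them. The body advances by `forward_step` during the
power fraction and retreats by `backward_step` during recovery, and the
ground truth (frequency, amplitudes, lags, expected percent-in-phase,
step ratio, mean path speed) rides along as an attribute.
`species_kinematics_spec()` encodes the two study morphotypes: beat
frequencies 35.7 and 11.4 Hz, amplitudes 50.8/94.8/79.0° and
48.9/90.5/56.5°, speeds 7.7 and 4.5 mm s⁻¹, ratios 6.2 and 9.3, with
pairwise phase lags derived from the published percent-in-phase values
via lag = (1 − p/100)·180°. Three phases cannot reproduce three pairwise
lags exactly; the antennule–mandible pair is whatever the other two
imply, which lands within a few points of the published value.
Digitizing noise defaults to 0.5 px, a realistic click error.

`make_field()` produces analytic fields with closed-form ground truth:
radial power-law decay (the law is imposed on speed directly rather than
solving Stokes flow, because the attenuation fit measures exactly that
quantity), a Lamb–Oseen vortex pair, uniform and comoving flows, and a
solid-rotation patch. The patch's exterior is the irrotational 1/r tail
of a Rankine vortex by default: a hard-zero exterior would put a velocity
jump at the patch edge whose discrete shear-sheet vorticity cancels the
patch circulation on any finite grid, destroying the closed-form oracle
Γ = 2ω₀πR²; `exterior = "still"` keeps the hard-edged variant for
stress-testing.

`make_particle_images()` renders Gaussian-spot tracers advected exactly by
a supplied field. None of the generators model appendage–fluid coupling,
three-dimensional motion, out-of-plane loss of particles, or optical
artifacts, so passing tests demonstrate that the *estimators* are correct
and convergent — not that real videos are free of digitizing bias,
out-of-plane error, or PIV peak-locking.

## Problem sizes and determinism

Every generator is deterministic given its `rng_seed`. The validation
suite runs at the study's own scales — 80 × 64 export grids, 40–50 frames
per beat cycle with 3–4 cycles, 256² px particle images at 0.02
particles px⁻², 2000 replicates for test calibration — sizes at which the
whole suite completes in well under a minute on one core. Convergence
properties (kinematic recovery error versus frames per cycle, circulation
error versus grid pitch) are checked at 2–4× refinements of those sizes.

## Known limitations

* All hydrodynamics are 2-D cross-sections; no 3-D flux reconstruction,
  pressure, or force estimation is attempted.
* Left-side appendages are not modelled (digitizations cover the right
  side only).
* The attenuation fit assumes a single dominant flow source collocated
  with the body; multi-source fields would need per-source fitting.
* The PIV engine omits window deformation and advanced weighting, which
  limits accuracy in strongly sheared flow relative to commercial codes;
  it is validated for the displacement range 0.5–8 px per frame.
* Side assignment of vortices and flux-line sign conventions report signed
  values plus orientation metadata rather than forcing any particular
  published sign convention.
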