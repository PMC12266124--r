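---
title: "Models and methods behind mtukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtukit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtukit)
```

`mtukit` is a computational companion to engineered muscle-tendon-unit (MTU)
bioactuators: 3D-bioprinted constructs in which a central engineered skeletal
muscle tissue (the bioactuator) is flanked by two tendon-mimicking,
fibroblast-seeded anchors, joined by an interdigitated myotendinous-junction
(MTJ)-like interface. The package covers the four quantitative workflows such
a study needs — geometric design and contraction simulation, video-based
contractility quantification, tissue mechanics fitting, and myotube
morphometry — together with a synthetic-data generator that provides every
input with known ground truth. This vignette explains the models, the
parameters that matter, and the numerical choices, in that order.

## 1. Construct geometry and meshing

An MTU design (`mtu_design()`) is a rectangular block, by default
6 mm x 3 mm x 15 mm, with a central muscle section and two anchors carrying
2 mm x 1 mm rectangular holes (the mounting holes are simplified to
rectangles because anchor contact is not simulated). The muscle section is
either *compact* (one slab) or *sparse*: `n_bridges` parallel bridges of
width `bridge_width` separated by `bridge_gap`. Because viable tissue only
forms within roughly 150-200 um of a surface, the sparse layout exists to
maximize the exterior surface area of the muscle section;
`surface_area()` gives the closed-form box-face sum, which is strictly
increasing in the number of bridges at fixed total bridge width.

The interface interpenetration is summarized by
`interdigitation_fraction(r_i, L)` = 100 r_i / L: with the measured
invagination radius of 0.8 mm and a 15 mm construct it is 5.33%, i.e. the
two tissues interlock over about 5% of the construct length.

`hex_mesh()` voxelizes a design into identical hexahedra. The geometry is
rectilinear, so voxelization is exact up to grid snapping; bridge and gap
boundaries are rounded to the nearest element boundary, which preserves the
overall layout width exactly and each bridge width to within one element.
A bridge resolved by fewer than two elements, or a gap thinner than one
element, is an error rather than a silent geometry change. Elements are
labelled muscle or tendon by axial position, and muscle elements within
`surface_layer_depth` element layers of the exterior form the *contractile
set* — the default of one layer represents the thin living shell at the
default resolution (`h = 0.1` mm, which reproduces a sparse-construct mesh
with on the order of 3 x 10^5 vertices). Coarse meshes (`h = 0.5` mm,
a few thousand vertices) are used for sweeps and tests; the bar benchmark
below changes by under 2% when the element size is halved, which is why we
consider the coarse resolution adequate for trend comparisons.

## 2. Corotational contraction model

`simulate_contraction()` integrates corotational hexahedral elasticity:
each element extracts its rotation R by polar decomposition of the
shape-matching matrix between current and rest corner offsets, and linear
isotropic elasticity (2x2x2 Gauss-integrated trilinear stiffness) is applied
in the rotated frame. This is the standard model for soft-tissue simulation
at large rotations and moderate strains.

Actuation is a *prescribed contractile strain*: every contractile element
targets a rest shape shortened by a factor (1 - eps) along the actuation
direction (the long axis, parallel to the bridges). Muscle then contracts
"the same relative amount" everywhere, and design comparisons are made at a
fixed eps. The strain magnitude of matured tissue is not identifiable from
geometry alone, so eps = 0.10 is a package default, chosen as a
physiologically plausible tetanic shortening for engineered muscle; all
sweep conclusions are trends at fixed eps and are insensitive to its exact
value.

Material defaults come from microindentation of matured constructs:
E = 49.7 kPa (muscle), 158.9 kPa (tendon), Poisson ratio 0.4 for both,
density 1000 kg/m^3. Units are mm / kPa / s, under which stress times area
is in mN.

Time integration is implicit backward Euler (default 0.4 s in 10 ms steps,
linear ramp) with lumped mass and Rayleigh damping (alpha = 1 /s,
beta = 0.002 s; at these scales inertia is negligible and the dynamics are
effectively a damped quasistatic continuation). One linearized solve per
step uses the corotational tangent with frozen rotations — exact for fixed
R, refreshed every step. Only the first and final frames are analyzed, so
after the ramp the state is *settled*: iterations continue until the
internal-force infinity norm falls below `1e-8 * E_muscle * min(h)^2` (mN),
with a 200-iteration cap and an error, never a silent pass, on
non-convergence. Two safeguards matter in the settle phase. First, update
lengths are capped at half an element, because the frozen-rotation
linearization is only locally valid and overshooting it can cycle. Second,
the solve adds a stiffness-scaled diagonal `1e-4 * E_muscle * min(h)`:
the construct is free-floating, so the stiffness matrix has six near-null
rigid modes through which force roundoff would otherwise be amplified into
large rigid drifts that starve the elastic correction.

The deformation metric (`max_deformation()`) is the largest per-vertex
displacement magnitude between the first and last frames *after removing
the best-fit rigid transform* (Kabsch alignment): a free body may drift or
rotate as a whole, and the metric should measure shape change only.

Validation relies on a closed form: a free homogeneous bar with every
element contractile has its stress-free equilibrium at the rest shape
scaled by (1 - eps) along the axis, so a 10 mm bar at eps = 0.1 ends
9 mm long and its end vertices move exactly 0.5 mm. The solver reproduces
this to well under 1%, matches linear elasticity at eps = 1e-3, and is
objective (rotating the rest mesh leaves the metric unchanged).

`design_sweep()` crosses bridge counts and widths, records infeasible
combinations (bridges that overflow the width, or that the mesh cannot
resolve) instead of failing, and returns a tidy table. More and thinner
bridges raise the contractile (surface) fraction of the muscle section and
therefore the deformation; `optimal_design()` picks the maximum, breaking
ties toward fewer bridges on manufacturability grounds.

## 3. Optical-flow contractility quantification

`estimate_flow()` computes dense per-pixel displacement between two frames
by coarse-to-fine iterative Lucas-Kanade: per pyramid level, the second
frame is warped by the current flow, gradients and the temporal difference
are integrated under a Gaussian window (sigma 4 px), and the per-pixel 2x2
normal equations give an increment (capped at 2 px per iteration). After
each iteration the flow is smoothed with a Gaussian of sigma 2 px, which
propagates flow from well-textured into aperture-limited areas. Correctness
is defined by an accuracy contract on synthetic videos, not by matching a
specific library: mean endpoint error below 0.2 px for 2 px translations at
the default noise level. The contract is evaluated on the interior region
where the integration window is fully supported; frame borders necessarily
contain content with no correspondence in the other frame, so their error is
unbounded for any estimator.

Angle convention: flow components (u, v) have u rightward and v downward
(image rows grow downward); quoted angles are measured counterclockwise
from +x in display orientation, i.e. `theta = atan2(-v, u)`. Under this
convention the customary contraction angle of 135 degrees points up-left.
`directional_alignment()` counts vectors within a half-open sector
`[angle - tol, angle + tol)` (default tol 22.5 degrees, an 8-sector hue
wheel), after discarding magnitudes below 0.1 px/frame as noise; the
half-open convention makes disjoint sectors tile the circle so fractions
sum to one, and an isotropic field yields 45/360 = 0.125.

The volumetric contractile kinetic energy is
`E_k = (rho / 2) * mean(v_i^2)` over the tissue mask, in J/m^3: each pixel
contributes (rho/2) v^2 times its volume, and normalizing by the total
tissue volume cancels the uniform section depth, which is kept only as
metadata. Density defaults to 1000 kg/m^3 (tissue is approximately water).
Speeds convert to m/s via the pixel size and frame interval. A uniform
1 mm/s field gives exactly 5 x 10^-4 J/m^3, and E_k scales quadratically
with ground-truth speed on synthetic translations.

`segment_voids()` removes the dark void areas from the tissue mask before
volume normalization: SLIC-style superpixels (k-means in joint space and
intensity over local neighbourhoods) are thresholded on mean brightness
(default 0.15 on a [0, 1] scale), with a per-pixel refinement so that
superpixels straddling a void edge do not leak. The threshold is an
explicit, tuned parameter by design — it depends on the imaging setup.

`subtraction_displacement()` supports the image-subtraction analysis: it
returns the absolute-difference image plus a single lateral displacement
along a chosen axis, obtained by cross-correlating the mean *signed*
derivative profiles of the two frames (the signed derivative keeps edge
phase; its magnitude blurs the peak) with parabolic sub-pixel refinement.
Featureless frames yield `NA`, not zero. `visualize_flow()` renders the
customary overlay: arrows at a uniform 0.02% pixel sample, scaled 25x,
hued by direction.

## 4. Tissue mechanics

`fit_hertz()` fits spherical indentation curves to the Hertz model
`F = (4/3) E* sqrt(R) delta^(3/2)` with `E* = E / (1 - nu^2)` — the rigid
indenter reduction, justified because cubic zirconia is many orders of
magnitude stiffer than kPa-scale tissue. After the `delta^(3/2)` transform
the model is linear in E, so the fit is closed-form least squares:
deterministic, fast, and exactly invertible on noiseless synthetic curves.
Depths beyond 10% of the indenter radius (R = 100 um, hence 10 um) are
rejected — the acquisition bound for Hertz validity, not a soft warning.
An optional two-parameter variant also searches a contact-point offset by
bounded one-dimensional optimization; it is off by default because the
curves are assumed zeroed at contact. Monte-Carlo recovery at the default
noise level is centred: the median fitted modulus over 100 noisy curves is
within 2% of truth.

`tensile_summary()` converts force-displacement to stress-strain with the
cross-section and gauge length (mN/mm^2 = kPa), fits the elastic modulus in
a configurable linear window (default 2-10% strain), and detects fracture
as the first drop below 50% of the running force maximum, reporting the
last pre-drop sample as the fracture point (force in mN, strain as percent
elongation). Monotone curves return `NA` fracture fields with the modulus
still fitted. `fold_change()`, `tissue_specific_force()` (force normalized
by active tissue area, uN/mm^2) and `fracture_area_fraction()` (damaged
area as a percent of muscle area, by exact pixel counting after
intersection with the tissue mask) are the thin arithmetic utilities the
derived statistics need.

## 5. Morphometry

Scenes arrive as labelled data (instance mask, per-tube MyHC positivity,
nuclei coordinates); segmentation from raw fluorescence is upstream and out
of scope. `fusion_index()` is the fraction of nuclei whose centroid falls
inside a marker-positive tube — centroids, because nuclei are counted, not
measured, and boundary pixels count as inside. `shift_angles()` takes each
tube's principal axis from second central moments of its mask and reports
the acute angle to the reference (tension) axis; near-circular masks, whose
long axis is undefined, are excluded with a message. `myotube_widths()`
reports twice the median distance-transform value along the medial axis
(approximated by per-bin maxima of the distance transform along the
principal axis); the choice of a medial-axis median over a single caliper
measurement is ours and is documented here because the field protocol
leaves the sampling unspecified. Widths under about 2 px cannot be resolved
by a distance transform and are flagged unreliable. `texture_variance()`
is the population variance of intensities in an ROI (mask or polygon),
used to discriminate muscle from tendon matrix texture.

## 6. Synthetic data: what it does and does not emulate

All generators take explicit seeds and are bit-reproducible.

* **Videos** (`gen_video()`): band-limited texture (Gaussian noise low-pass
  filtered at `texture_scale`, default 8 px) advected by an exact affine
  motion model (translation, uniaxial contraction, rotation) with bilinear
  warping and additive Gaussian sensor noise (default SD 0.01 on a [0, 1]
  scale, a typical video SNR). The texture floor is kept well above the
  void intensity so that brightness separates tissue from voids, as in
  backlit video of a printed construct. Ground truth is the exact applied
  displacement field. Displacements beyond half the texture correlation
  length trigger a warning because flow estimation becomes ill-posed.
  Real stimulation videos are recorded at 25 or 50 fps; the pixel size
  (default 10 um/px) and bit depth are configurable defaults, not claims
  about any particular microscope.
* **Indentation curves**: the Hertz forward model plus Gaussian force
  noise — by construction exactly invertible by the fitter at zero noise.
* **Tensile curves**: linear-elastic loading to a fracture strain, then a
  drop to near zero; noise only before fracture.
* **Morphometry scenes**: rotated-rectangle tubes with wrapped-normal
  orientation scatter of SD `1/sqrt(angle_concentration)` radians about the
  tension axis, rejection-sampled against overlap; exactly
  `round(fusion_fraction * n_nuclei)` nuclei inside marker-positive tubes,
  the rest on background.

Passing tests on these inputs demonstrates that the estimators are correct
under their stated models (affine motion, Hertzian contact, linear
elasticity, elliptical tubes). They do not demonstrate robustness to
non-affine tissue deformation, fluorescence photophysics, out-of-plane
motion, or segmentation error in real lab data — those remain the user's
responsibility to assess.

## 7. Orchestration and problem sizes

`run_demo()` wires all stages behind one validated configuration (unknown
keys are rejected before anything runs) and one global seed fanned out to
per-stage child seeds; outputs are deterministic CSV/JSON plus figures in a
self-contained report directory. The default demo and the test suite use
deliberately small problem sizes — 128 px videos, coarse (0.5-1 mm) meshes
with a few thousand vertices, 100-curve Monte-Carlo batches — which are
sufficient for every closed-form oracle and trend check the package makes;
the full-resolution mesh (h = 0.1 mm, ~3 x 10^5 vertices) is exercised for
construction only. The package's R functions are its interface; the
`scripts/acceptance.R` script reruns the headline desk-checkable numbers
from the installed package.

## 8. Known limitations

* No contact mechanics: the anchors are free, as in the simulated study
  system; pillar interaction forces are out of scope.
* The corotational model assumes small strains within each element;
  eps well above ~0.2 would need a hyperelastic law.
* Muscle dynamics are not calibrated: time courses are not comparable to
  electrically stimulated tissue; only first-vs-last-frame deformation is.
* The flow estimator is a polynomial-expansion-free Lucas-Kanade variant;
  it meets the stated accuracy contract but is not bit-compatible with any
  specific external implementation.
* Laboratory values that depend on living tissue (absolute force output,
  measured E_k of real constructs, IL-6, histology) are context for
  interpretation, not quantities this package can reproduce.
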