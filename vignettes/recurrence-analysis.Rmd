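---
title: "Methods: pattern-of-failure analysis of radiotherapy recurrences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern-of-failure analysis of radiotherapy recurrences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After radiotherapy of an abdominal tumor, a local recurrence seen on a
follow-up CT raises two questions that drive target-volume policy: how much
dose did the recurrent volume actually receive under each treatment plan,
and where does it lie relative to the high-dose (boost) volume — infield,
marginal, or outfield? Answering them requires bringing the follow-up scan
into the planning frame, turning the delineated recurrence contours into a
volume, correlating that volume with the plans' dose grids, and measuring
its geometry against the boost and margin-expanded shells around it.
`rtrecur` implements this workflow for DICOM-RT inputs (CT series,
RT Structure Set, RT Dose) with every quantitative step testable against
closed-form phantom answers.

## Coordinates and the rigid transform

All geometry lives in DICOM patient coordinates (LPS, mm); voxel indices
are 0-based with the origin at the *center* of voxel (0,0,0), which removes
half-voxel ambiguity in every index/physical conversion.

A registration result is the nine-component vector
$(t_x, t_y, t_z,\; rp_x, rp_y, rp_z,\; r_x, r_y, r_z)$: translation (mm),
rotation point (mm) and rotation angles (degrees). The induced motion is

$$T(x) = R\,(x - rp) + rp + t, \qquad R = R_z(r_z)\,R_y(r_y)\,R_x(r_x),$$

with intrinsic z–y–x Euler angles. Degrees (not radians) are used in I/O
and reports, and the serialization header states the convention explicitly
so a stored transform is interpretable without the package. In the
pipeline, $T$ maps *planning-frame* points to sampling locations in the
*follow-up* frame (the usual resampling convention); a structure delineated
on the follow-up scan is carried into the planning frame through $T^{-1}$.
Transforms with different rotation points can induce the same motion, so
comparisons use the canonical form (`rt_effective_translation()`,
`rt_angles()`).

## Registration

Follow-up scans acquired in oblique (right-anterior-oblique) positioning
can differ from the planning CT by 20–60° axial rotations — far outside
the capture range of any intensity metric started at identity. Registration
therefore has two stages:

1. **Pre-initialization** (`preinitialize()`): deterministic alignment of
   the intensity centroids (weights are intensities shifted to be
   non-negative), plus an optional user-supplied axial-angle hint applied
   about the fixed volume's centroid. This mirrors clinical practice, where
   the approximate acquisition angle is known.
2. **Mutual-information maximization** (`register_rigid()`): a 3-level
   coarse-to-fine pyramid (block-mean downsampling by 4×, 2×, 1×) over the
   six rigid degrees of freedom, holding the rotation point fixed at the
   initialization's rotation point — the PTV centroid when a PTV structure
   is available (registration "about the prescription target"), else the
   image centroid. The metric is histogram mutual information (default 50
   bins at full resolution, reduced on coarse levels so the joint histogram
   stays populated) over a seeded random sample of foreground voxels
   (default 25% at full resolution; coarse levels, which carry few voxels,
   are sampled fully). Nelder–Mead optimizes each level with a simplex
   scaled to the level (coarse levels explore, the final level refines) and
   is restarted up to twice per level to re-inflate a collapsed simplex.

Because voxel sampling is seeded and Nelder–Mead is deterministic,
identical seeds give bit-identical transforms. An optional metric mask
(e.g. a dilated union of target and spinal-cord structures) can restrict
the sampled voxels; it is off by default because the phantom studies do not
need it. The manual-revision step of a semi-automated workflow is
represented by an override transform in the case configuration, which
bypasses registration entirely and is recorded as such in the report.

On the standard phantom (64×64×40 voxels at 2.5×2.5×3 mm), ground-truth
motions with translations up to 20 mm and hinted axial rotations of 20–60°
are recovered to well under half the in-plane spacing and half a degree.
Two properties of the fixtures matter for interpreting this: phantom
rendering is partial-volume supersampled (edge voxels carry fractional
intensities, as real CT does) — with hard-edged rendering the MI optimum
itself is biased by interpolation aliasing, and no optimizer fixes that —
and mild Gaussian HU noise (default σ = 10 HU) keeps the metric surface
non-degenerate.

## Voxelization with subvoxel accuracy

Structures are planar closed polygons (mm) per axial slice and stay in
physical coordinates until voxelization. `voxelize()` rasterizes each
slice's polygons by the even-odd rule on an in-plane subgrid of factor
$2^\ell$ and records fractional occupancy (covered subcells / subcells).
The refinement level increases (factors 1, 2, 4, 8) until the total volume
changes by less than 0.5% (relative) between consecutive levels; the
achieved level is stored on the mask. A contour is attributed to its
nearest grid slice; if the nearest slice is farther than half a slice
thickness away, the assignment is made anyway but warned about.
Self-intersecting polygons are processed by the even-odd rule with a
warning (the intersection test snaps cross products below numerical noise
to zero, so polygons whose arcs merely share vertices are not flagged).

Two numerical facts about this scheme are worth stating plainly:

* **Error plateau.** The in-plane rasterization error vanishes with the
  refinement factor, but the representation of a contour as a slab of one
  slice thickness contributes a constant bias (about 0.05% for a 25 mm
  sphere on 3 mm slices). Errors against closed-form volumes therefore
  decrease strictly over the levels the refinement actually traverses and
  then plateau at the slab floor; further refinement cannot and should not
  push below it, which is exactly why the convergence rule stops.
* **2D, not 3D, supersampling.** Subdivision is in-plane only, matching the
  slice-wise nature of the contour data. A 3D scheme could reduce the slab
  bias but would have to invent inter-slice geometry the contours do not
  contain.

A converged 25 mm sphere on a 1×1×3 mm grid comes out at 65.44 ml against
the closed form 65.45 ml (−0.02%).

## Dose sampling, DVH and statistics

`sample_dose()` evaluates the dose grid by trilinear interpolation at every
occupied mask voxel center (mapped through a transform if the mask lives in
another frame). Voxels mapping outside the dose grid are **never silently
zeroed**: they are returned as "dose-undefined" with their volume, excluded
from min/max/median (a silent zero would corrupt the reported minimum dose)
and reported as a separate volume; more than 50% undefined volume is
treated as a grid mismatch and raises an error.

The cumulative DVH is the volume-weighted reverse cumulative histogram on
uniform bins (default 0.1 Gy; report precision is a separate choice). Its
value at 0 Gy equals the total defined volume and it is non-increasing by
construction. The median is the volume-weighted 50th percentile with linear
interpolation across the spanning sample; the same definition applied to a
uniform field returns the field value exactly, and applied to a linear
0→50 Gy gradient over a spanning box returns 25 Gy.

The volume-in-isodose statistic thresholds at a percentage of a reference
dose. The reference is the analyzed plan's **prescribed dose** (switchable
to the grid maximum): base and boost plans are analyzed separately because
they were delivered sequentially, and the cut-off is tied to prescription
coverage in the same spirit as ICRU-style plan evaluation.

Oracle equivalence is tested against a brute-force enumeration of
analytic-geometry subvoxels at 10× supersampling on ≤32³ grids:
volume, median and volume-in-isodose agree within 1%. Two caveats are
geometric, not implementational: the min/max of a linear field lie on the
discretized surface, where any voxel-center implementation can differ from
the continuum by up to the dose change across a voxel half-diagonal (the
tests assert exactly that bound); and affine fields with near-equal
gradient components collapse the lattice dose values into widely spaced
atoms, below whose spacing no lattice median is defined — oracle fixtures
therefore use incommensurate components.

## Margin expansion, overlap and classification

`expand_margin()` implements the margin criterion of a Euclidean distance
transform thresholded at the margin: a voxel enters the expansion iff its
center lies within the margin (mm, anisotropic spacing respected) of a
voxel center of the binarized (occupancy ≥ 0.5) input. It is computed
exactly at grid resolution as an FFT convolution with the anisotropic ball
structuring element; sub-voxel accuracy therefore comes from the analysis
grid, not the operator (a 20 mm ball expanded by 10 mm on a 1 mm grid gives
112.7 ml against the closed-form 113.10 ml). The operator is extensive,
monotone in the margin, and approximately a semigroup (10 mm twice vs
20 mm once agree within 2%; exact semigroup behavior would require the
continuum transform).

`overlap()` intersects fractional occupancies
($\sum \min(o_{rec}, o_{region})\cdot v$) and reports ml and the percentage
of the recurrence volume — the quantity plotted per plan against the 80%
isodose volume. `classify_location()` evaluates the recurrence against the
boost and its +1 cm / +1.5 cm / +2 cm shells. Because the shells are
nested, coverage fractions are non-decreasing — the canonical row pattern
of a pattern-of-failure table is a theorem here and is asserted as a
property test over randomized fixtures. A recurrence is flagged "within" a
shell when its coverage reaches a containment threshold, default 0.95. The
threshold is a convention, not physics: a clinician's by-eye "within" and
a voxel count can legitimately disagree (a recurrence can be 84% inside one
region yet read as contained on the representative slice), which is why the
full coverage fractions are always reported alongside the flags.

`max_extension()` measures how far the recurrence protrudes beyond the
boost surface, center-to-surface on the binarized masks at grid resolution
(the boost voxel centers represent its surface; voxels inside the boost
contribute 0). Two modes: `"3d"` (maximum over all recurrence voxels) and
`"axial"`, which mirrors the clinical ruler-on-one-slice measurement —
per-slice in-plane distance to the boost portion of the same slice, worst
slice reported. For an obliquely elongated recurrence the measurable axial
extension can fall short of the 3D one (slices beyond the boost's axial
extent cannot be measured in-plane), so both are reported, along with a
direction-resolved extension over the six cardinal directions to support
anisotropic-margin conclusions. A fixture built with a 62.6 mm protrusion
reads back 6.30 cm on a 1.5×1.5×3 mm grid — the 0.4 mm excess is the
center-to-center discretization of the surface.

## The phantom generator

`phantom_spec()` / `make_phantom()` generate the study conditions every
test runs under, not ad-hoc fixtures: an abdomen-sized body ellipsoid
(HU 0) in air (−1000 HU) with four embedded contrast spheres standing in
for vessel/organ landmarks; a spherical target with a sequential pair of
plans (44.5 Gy prescribed to the PTV by the base plan, 9 Gy by the boost,
as plateau-with-linear-falloff fields); a follow-up scan that is the
planning scene observed under a known rigid motion (axial rotations up to
60°, the oblique-positioning regime), optionally with a shrunken body
ellipsoid emulating the weight loss typical between planning and follow-up;
Gaussian HU noise (σ = 10 HU, seeded); and partial-volume rendering
(2× supersampled). Everything is written as genuine DICOM through the
package's own writers, so the format code is exercised rather than
bypassed, and identical spec + seed gives bit-identical files (UIDs come
from the seeded RNG; no timestamps are written). Every fixture carries
closed-form expected values (sphere/union volumes via the two-sphere lens
formula, shell coverages via spherical caps, the ground-truth transform) as
machine-readable metadata.

What the phantoms deliberately do **not** emulate: deformable anatomy (a
severely deformed follow-up violates the rigid model and is out of scope),
scanner artifacts, heterogeneous tissue texture, and realistic dose
calculation. Passing tests therefore demonstrate the correctness of the
geometry, dose bookkeeping and registration machinery under rigid motion
and noise — not registration robustness on deformed clinical anatomy, which
the workflow addresses by manual revision (the override transform).

The recurrence fixture (`make_recurrence_fixture()`) is the boost sphere
united with a protruding lobe sphere whose tip extends a stated distance
beyond the boost surface; per-slice union outlines are built from circle
arcs so even-odd rasterization sees a single polygon rather than two
overlapping ones (which would XOR).

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| Isodose level | 80% of the plan's prescribed dose | the cut-off separating infield from marginal failure when 95% coverage is the planning aim |
| Margins | 10, 15, 20 mm | the shells of the classification table |
| Containment threshold | 0.95 coverage | operationalizes "within"; fractions always reported |
| Voxelization | factors 1–8, stop at 0.5% volume change | subvoxel accuracy with a principled stopping rule |
| DVH bin width | 0.1 Gy | an order below reporting precision (0.01 Gy) |
| MI bins / sampling / levels / iterations | 50 / 0.25 / 3 / 200 | conventional MI settings; all configurable |
| Phantom grid | 64×64×40 at 2.5×2.5×3 mm | abdomen-scale scene with clinical slice thickness, sized so the full suite runs in minutes |
| HU noise | σ = 10 HU | keeps MI non-trivial without drowning structure |
| Report precision | 2 decimals (ml, Gy) | matches clinical reporting |

## Degenerate inputs and tie-breaks

Mixed frames of reference in a CT series are an error; a frame mismatch
between structure set and image is a warning plus a flag, never a silent
pass. An all-constant image has no intensity centroid (error). A composite
sum-plan dose grid (IMRT base+boost in one file) is flagged and its
per-plan columns stay null — per-plan statistics from a sum are
unanswerable, and the report says so rather than guessing. Subcell centers
exactly on a polygon edge follow the even-odd crossing convention with a
half-subcell offset, so lattice-aligned boxes rasterize exactly. Non-axial
rotation components tilt contours out of their planes; transformed contours
are flattened to their mean plane, silently below 1 mm of tilt (the
residual of an essentially axial motion) and with a warning above.

## Problem sizes in the test suite

The suite validates on: 64×64×40 phantoms for registration and the
end-to-end pipeline; 90³ unit-spacing grids for the dilation law; ≤32³
grids against the 10× brute-force oracle; 50 randomized fixtures for the
shell-nesting property. These sizes were chosen so the complete suite runs
in a few minutes on one core while every tolerance above still binds.

## Known limitations

* Rigid motion only; deformation is handled by flagging and manual
  override, not modelled.
* Axial-plane contour model: the toolkit assumes structures are delineated
  on axial slices and that inter-scan rotations are dominantly axial;
  large oblique rotations degrade contour planarity (warned).
* The DICOM layer covers the subset of the standard the workflow needs
  (explicit VR little endian, defined-length sequences, 16-bit pixel
  data); it is validated against an independent reader but is not a
  general-purpose DICOM implementation.
* `max_extension` is surface-resolution limited (half a voxel) and the
  margin operator is exact only at grid resolution; both sharpen on finer
  analysis grids.
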