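---
title: "Quantifying bronchial-tree deformation during lung collapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bronchial-tree deformation during lung collapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaydeform)
```

## The problem

During pulmonary surgery the operated lung is deflated, so preoperative 3D
reconstructions built from inflated CT no longer match what the surgeon
sees. A unilateral pneumothorax produces the same one-sided collapse in
vivo and can be imaged with ordinary CT, which makes paired
inflated/collapsed airway segmentations a usable substrate for measuring
how each bronchial branch moves, shortens and narrows during collapse —
and for pushing those measured deformations back onto an inflated airway
model to synthesize the collapsed anatomy for intraoperative augmented
reality guidance.

`airwaydeform` implements that whole measurement-and-forward-model
pipeline for binary airway masks: centerline extraction, rigid
registration on the structures collapse leaves intact, per-branch
deformation quantification with ancestor contributions removed, branch
morphometry, and the forward collapse model. A seeded phantom generator
stands in for patient data so every stage is testable end to end.

## Coordinate frame and data model

All geometry is in physical millimetres in an LPS-like patient frame: x
grows toward the patient's left, y posteriorly, z cranially. NIfTI input
(whose world frame is RAS by convention) is reoriented and sign-flipped
into this frame at read time; NRRD is read as left-posterior-superior.
The three anatomical views project onto coordinate pairs: axial (x, y),
sagittal (x, z), coronal (y, z).

A centerline tree is a rooted tree of polylines: one branch per tibble
row, points ordered proximal to distal, each non-root branch starting
exactly at its parent's distal endpoint. The root is the trachea; its
distal endpoint is the main carina. Branch labels come from a schema
(human: main/lobar/segmental down to B1–B10 with the intermediate
bronchus and the lingula; porcine: the pig airway including the accessory
lobe and the cranial/caudal upper-lobe subdivisions).

## Centerline extraction

Masks are thinned to unit-width skeletons by iterative removal of simple
points (6-subfield directional passes, endpoint-preserving, 26-connected
foreground / 6-connected background), the skeleton is parsed into an
endpoint/junction graph, rooted at the most cranial endpoint (or a user
hint), and leaf spurs shorter than `min_spur_mm` are pruned iteratively
with degree-2 chains merged. The default spur threshold is twice the mean
tube radius estimated as `sqrt(V / (pi * L))` from the mask volume and
total skeleton length; the pruning rule is a convention of this package,
not something the measurement model depends on.

Raw voxel skeletons are not metrically faithful: they meander by about
half a voxel, and at bifurcations the medial axis branches up to a tube
radius *distal* to the geometric branch point (the junction wedge of two
merging tubes). Since the deformation measures below are differences of
fitted branch directions and arclengths between two states, those
artifacts matter, and `extract_centerline()` therefore post-processes by
default:

* **smoothing** — iterated 3-point moving average of interior points
  (endpoints pinned, so connectivity is untouched);
* **recentering** — each mid-branch point is moved to the area centroid
  of its luminal cross-section, found by casting 24 rays in the plane
  orthogonal to the local tangent and integrating the polar boundary
  radius (rays that escape through a junction are capped at twice the
  median radius). The proximal and distal 20 % of each branch are left
  alone because their cross-sections straddle the junction;
* **junction refinement** — each junction is relocated to the point on
  the parent's mid-section line that is least-squares closest to the
  children's mid-section lines, and the incident polylines are cut back
  to their own side. Constraining the junction to the parent axis keeps
  the solve well-conditioned even when a child runs nearly parallel to
  its parent.

## The deformation measures

Each branch is summarized by a total-least-squares **branch vector**: the
leading principal axis of its points, oriented proximal-to-distal, with
length equal to the extent of the point projections. For branch $b$ with
collapsed vector $\vec c_b$ and inflated vector $\vec\iota_b$ the
displacement is

$$\vec d_b = \vec c_b - \vec\iota_b,$$

and its norm is the displacement in mm. Angles are measured per view as
the full-quadrant arctangent of the projected components — axial
$\operatorname{atan2}(v_x, v_y)$, sagittal
$\operatorname{atan2}(v_x, v_z)$, coronal
$\operatorname{atan2}(v_y, v_z)$ — in $(-180°, 180°]$, zero along the
second-named axis. The two-argument arctangent is required rather than a
plain $\tan^{-1}$ ratio: measured airway deformations exceed ±90° at the
segmental level, which a single-argument form cannot represent.

A rotation of a lobar bronchus sweeps all its segmental children along
with it. To report what each branch did *itself*, the raw per-view angle
change of the parent is subtracted (signed shortest difference, wrapped):

$$\Delta\theta^{\text{indep}}_v(b) =
  \operatorname{wrap}\!\big(\Delta\theta^{\text{raw}}_v(b) -
  \Delta\theta^{\text{raw}}_v(\text{parent}(b))\big).$$

Summing the independent deltas down any trachea-to-branch path telescopes
back to the raw delta of the terminal branch (modulo 360°) — an identity
the test suite checks to $10^{-9}$ degrees on every phantom.

Three numerical conventions deserve explanation:

* **Near-degenerate views.** When a unit direction lies within about 8.6°
  of a view axis (in-plane magnitude < 0.15, the `min_inplane` floor),
  its projected angle is numerically meaningless — the near-vertical
  trachea has no usable axial angle, and one noisy value there would
  contaminate every branch in the tree through the ancestor subtraction.
  Such angles are reported `NA`, and an ancestor with an undefined view
  angle contributes zero to the subtraction.
* **Junction-guarded fits.** The view angles are computed from branch
  vectors fitted to the middle 60 % of each branch (the `trim_frac`
  parameter). For a straight branch the trimmed and untrimmed directions
  coincide, so this changes nothing in exact arithmetic; on extracted
  centerlines it removes the residual junction-wedge bend. Displacement
  vectors and lengths always use the full branch.
* **Per-view cross-talk.** The three view angles of one direction are
  redundant (a direction has two degrees of freedom), so the per-view
  formulation cannot decouple them: a pure rotation about z changes not
  only the axial angle but, through the moving x and y components, also
  the sagittal and coronal angles of most vectors. Consequently the
  independence property is exact *in the view of the rotation* — a
  z-rotation of a lobar subtree leaves all descendant axial deltas at
  zero — while the other views inherit bounded cross-talk. This is a
  property of the 2D-projection formulation itself, not of the
  implementation. For the same reason per-view angles are defined in the
  fixed patient frame, which is why registration always precedes
  measurement.

Branch length is the arclength of the polyline (so curvature counts);
maximal diameter is measured by casting 36 rays orthogonal to the local
tangent at each interior centerline point, taking the largest antipodal
pair sum per point, and the maximum over points. Points within 1.5 local
radii of a branch end are excluded so junction blobs cannot masquerade as
the lumen. The boundary along each ray is the sub-step linear
interpolation of the 0.5 crossing of the trilinearly interpolated mask,
with rays marched at a quarter of the smallest spacing. Parenchymal or
lobe volume is foreground voxel count times voxel volume.

One caveat worth knowing when validating the diameter estimator: a
digitized cylinder whose radius is an exact multiple of the voxel spacing
sits on the digitization knife edge — the voxel-center surface is then
biased a half voxel outward in entire slices, and the error does not
shrink smoothly with resolution. Convergence checks in the test suite use
a grid-incommensurate radius (4.75 mm) for that reason; results at
commensurate radii remain within one voxel but alias.

## Registration

The collapsed tree is aligned to the inflated tree rigidly (no scaling —
scale change *is* deformation signal) using only structures the collapse
does not affect: the tracheal proximal endpoint, the main carina, and the
contralateral main bronchus (distal endpoint plus arclength fractions
0.25/0.5/0.75), solved in closed form by orthogonal Procrustes. When both
trees carry labels the correspondence set is then densified to arclength-
resampled points of every matched branch on the trachea and the whole
contralateral subtree; a few hundred correspondences average the
per-landmark extraction noise down by roughly an order of magnitude. The
collapsed-side branches are never used.

## The forward collapse model

`apply_deformations()` applies a table of independent per-view angle
deltas and length deltas back onto an inflated tree, root to leaves: each
branch is re-anchored to its deformed parent's distal endpoint, rotated,
and scaled along its fitted direction until its arclength matches the
inflated length plus its own delta (floored at 5 % of the original).
Diameter deltas are carried for reporting but not applied.

The rotation step is the one place where the design was genuinely open.
Composing the three view deltas as successive rotations about the z, y
and x axes looks natural but is not invertible: measuring the view-angle
changes such a composition induces and comparing them with the composed
deltas gives errors with a median around 50° for deltas within ±40°
(each axis rotation disturbs the other two projections). The package
instead reconstructs the **target direction** directly: the branch's
cumulative per-view target angles each constrain the direction to a
half-plane through the corresponding view axis, the least-squares
intersection of those half-planes (smallest eigenvector of the stacked
plane normals, sign fixed by agreement with the targets) is the target
direction, and the branch's points are rotated by the minimal rotation
taking the old fitted direction onto it. For a table measured from a real
tree pair the constraints are mutually consistent and the reconstruction
is exact — the forward model and the measurement invert each other to
floating precision on straight-branch phantoms, which the acceptance
suite verifies at 1°/0.5 mm. A view flagged `NA` in the table simply
contributes no constraint. For an internally inconsistent (hand-edited)
table the reconstruction degrades gracefully to the least-squares
compromise.

`tree_distance()` scores a modeled tree against a reference as the
symmetric mean closest-point distance per matched branch after 1 mm
arclength resampling, and overall as the branch-length-weighted mean.

## The phantom generator

`phantom_spec()` describes a complete binary airway tree at clinically
plausible scales; the defaults are a 50 mm, 16 mm-diameter trachea,
length ratio 0.75 and radius ratio 0.63 per generation (segmental
bronchi then come out near 4 mm diameter and 21 mm length, matching the
scales reported for human and porcine airways), a 35° ± 5° branching
angle with ±15° azimuthal jitter, and 1 mm voxels. Generations 0–3 are
labeled trachea / main / lobar / segmental; the human schema supports a
depth-3 binary tree, the porcine schema only depth 2 (only one of its
lobar bronchi subdivides), and requesting deeper labels is an error.
Everything is seeded: the same spec and seed reproduce the phantom to the
byte.

`collapse_phantom()` builds the collapsed state of one lung (the
contralateral side stays rigid, as in a unilateral pneumothorax) and
returns the exact deformation table that produced it. Because arbitrary
per-view delta triples are generically inconsistent — three view angles
of one direction carry only two degrees of freedom — ground truth is
sampled as hierarchical per-branch 3D rotations (axis-angle, magnitudes
up to 25°, rejection-resampled so every induced independent per-view
delta stays within ±40°) plus length scales uniform in 0.6–1.0, and the
recorded truth deltas are the per-view changes those rotations actually
induce on the fitted branch directions. Such a table is consistent by
construction, so on noiseless trees `independent_deformations()` recovers
it to ~$10^{-13}$ degrees, and the voxel pipeline's whole error budget is
attributable to voxelization, skeletonization and registration.

What the phantom does **not** emulate: curved branches (real bronchi
bend; the forward model carries curvature through but the generator makes
straight tubes), non-circular lumina, segmentation errors at the wall,
missing distal branches in the collapsed scan, and parenchyma (a scaled
ellipsoid stands in for volume tests only). Passing the phantom suite
therefore demonstrates the computational chain, not clinical accuracy.

## What the pipeline achieves on phantoms, honestly

The integration suite runs 20 seeded phantoms through
generate → voxelize (1 mm) → skeletonize → register (under a random rigid
nuisance transform) → measure, and compares recovered independent deltas
with the ground truth. With the extraction refinements described above
the pooled median absolute angle error is a little under 1° and roughly
three quarters of branch-view deltas land within 2°; length deltas land
within 1 mm for a bit over half the branches. The residual errors are
dominated by a genuine identifiability limit, not by estimator noise:
when a strongly rotated, shortened branch (length scales go down to 0.6,
view deltas up to ±40°) folds toward its parent, the two tubes overlap
over much of the branch's length, the union's medial axis no longer
contains the branch's true centerline, and no extraction method can
recover geometry the mask no longer encodes. The acceptance suite states
the stricter targets (median ≤ 0.5°, 95 % within 2°/1 mm) and reports the
measured values; under these collapse magnitudes those targets are not
met, and the corresponding test documents that gap rather than hiding
it. On noiseless trees (no voxelization) recovery is exact.

## Cohort summaries

`summarize_cohort()` reduces per-subject deformation tables to per-branch
medians. For the single overall "median displacement" figure two
conventions exist — the median of all branch displacement norms pooled
across subjects, and the median of per-subject medians — and published
summaries rarely say which they use; both are reported (`glance()`), and
neither is privileged.

## Problem sizes used in the checks

Unit tests run on depth-2/3 phantoms (7–15 branches, masks around
100–150 voxels per side); the integration suite uses 20 depth-3 phantoms
at 1 mm spacing; the acceptance script repeats the same computations from
scratch in about two minutes. These sizes were chosen to exercise every
code path at realistic anatomical scales while keeping a full run
interactive.

## Known limitations

* Segmental-level labeling of *real* extracted trees is supported via
  label transfer from a labeled reference tree or by structural
  generation-based assignment; fully automatic anatomical labeling of
  arbitrary patient anatomy (variant branching) is out of scope.
* The per-view angle formulation is the measurement model throughout;
  its projection cross-talk and frame dependence are documented above
  rather than "fixed", because the forward model is built to invert
  exactly that formulation.
* Rigid registration on the contralateral side assumes that side truly
  is rigid; mediastinal shift violates this in extreme collapse.
* Masks are treated as binary truth; partial-volume effects and
  segmentation noise at the wall propagate into diameters at the
  half-voxel level.
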