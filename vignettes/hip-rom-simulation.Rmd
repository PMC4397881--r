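---
title: "Dynamic simulation of hip range of motion and cam impingement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic simulation of hip range of motion and cam impingement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipsim)
```

## The problem

Femoroacetabular impingement (FAI) is premature bony contact between the
proximal femur and the acetabular rim that limits hip motion.  In the cam
variant an aspherical prominence at the femoral head-neck junction jams
against the rim during flexion and internal rotation.  Static radiographic
measures describe the deformity but not whether it actually blocks motion;
a dynamic answer needs the two bone surfaces and a collision model.

`hipsim` simulates clinically defined hip motions on triangulated femur and
pelvis surfaces.  A motion is swept until the bones collide; a capped
corrective translation of the femoral head is allowed before a pose is
declared impinged; the angle at which impingement occurs is the
range-of-motion (ROM) endpoint.  The package also localizes the impinging
area on the head-neck clock face, estimates the resection that dissolves
the impingement, compares native and cam-deformed conditions at a
limitation threshold, and ships a parametric hip phantom with an analytic
ROM oracle so every stage can be validated without patient data.

## Pose model and coordinate conventions

Anatomical frames follow the International Society of Biomechanics
conventions.  The pelvis frame takes Z from the left to the right anterior
superior iliac spine, X anteriorly in the plane of the two ASIS points and
the posterior midpoint, and Y superiorly; the femur frame has its origin at
the hip rotation center with Y running from the epicondyle midpoint to that
center.  The hip rotation center is fitted to the femoral head by a
least-squares sphere (optionally refined so the head-to-cup clearance is as
uniform as possible — the equidistant idea).  Fiducial K-wire points are
registered with a rigid SVD solution; its root-mean-square residual is the
fiducial registration error.

A joint pose is flexion, abduction and internal rotation, composed in that
fixed order: flexion about the pelvis Z axis, abduction about the pelvis X
axis, then internal rotation about the femoral long axis (intrinsic).  All
rotations pivot at the hip center; the corrective head translation is added
afterward.  Signs follow the side of the hip: on a right hip positive
flexion carries the thigh anteriorly, positive abduction laterally, and
positive internal rotation turns the anterior femur medially; a left hip
mirrors the latter two.  The composition order is a configuration field
(`sim_config()$rotation_order`) so order sensitivity can be examined, but
the three standard clinical sweeps each rotate about a single axis, where
the order is immaterial.

## Collision handling and the corrective translation

Contact queries run on axis-aligned bounding-box trees over both meshes.
`query_contact()` reports the minimal surface-to-surface distance when the
meshes are separated and a penetration estimate (the deepest penetrating
vertex's distance to the other surface) when they collide; `colliding` is
equivalent to `min_distance <= 0`.  The 0.1 mm `contact_tolerance` is used
both as the witness-pair reporting band and as the minimum clearance a
corrected pose must reach; the two roles share one parameter on purpose,
since no finer resolution is meaningful at CT surface accuracy.

When a reoriented femur collides, up to `max_translation` (default 3 mm) of
femoral head translation may be spent to reach a collision-free state.
`resolve_translation()` selects, among feasible translations inside the
cap, the one maximizing the minimal clearance — a capped operationalization
of keeping the articular surfaces equidistant.  The search is a
deterministic multi-start Nelder-Mead (a penetration-gradient heuristic
seed plus the six axis directions); there is no randomness, so repeated
runs are bitwise identical.  A pose needing more than the cap is impinged,
and the sweep halts.  The corrective translation is re-derived
independently at every candidate pose, never accumulated along the sweep,
so endpoints are path-independent.

Endpoint search sweeps in 2 degree coarse steps and bisects to 0.1 degree
on an integer grid, guaranteeing the bracket property: the reported angle
is free or resolved and one resolution step beyond is impinged.

## The phantom and its analytic oracle

`phantom_spec()` describes a ball-in-cup hip: a spherical head (radius
25 mm by default) inside a cup shell of inner radius head + clearance
(2 mm), covered to a rim polar angle of 70 degrees; a cylindrical
neck/shaft (radius 12 mm) leaves the head along an oblique axis.  The cup
pole points superior-medially and the neck inferior-laterally, each tilted
40 degrees, giving a neutral neck-to-pole offset of 170 degrees.  These
dimensions are adult-sized and produce endpoint angles in the clinically
familiar range (flexion ~140 degrees, abduction ~74, internal rotation at
90 degrees flexion ~32 with no cam).  The cam is a spherical-cap bump at
the head-neck junction: cap radius 5 mm and height 3.5 mm by default,
matching an artificial deformity made from a nylon screw head 1 cm across
and 3.5 mm proud, placed in the anterosuperior 11-2 o'clock band.  The
default clock position is 2 o'clock, the anterior end of that band, where
the bump maximally limits internal rotation in flexion — the classic cam
pattern.  The mesh is a single lathed surface (watertight by construction
at any resolution), locally refined around the cam cap so the bump profile
is resolved well below the joint clearance.

For this geometry the zero-translation endpoints have closed forms.  The
neck meets the rim when the angle between the neck axis and the cup pole
falls to `coverage + asin(r_neck / R_cup)`; for a sweep in the plane of the
pole this is `alpha0 - coverage - asin(r_neck / R_cup)`.  A cam taller than
the clearance adds a second contact when its super-clearance region
(angular half-width `gamma_c`) reaches the rim circle.  Both are solved for
arbitrary single-axis sweeps by resolving the probe and pole into
cylindrical components about the rotation axis.  `analytic_rom()` is
validated in the test suite against an independent brute force that
samples the rim edge circle at 0.05 degree azimuth and evaluates exact
pointwise penetration margins; the two agree to about 0.001 degree, and
the mesh engine then matches the oracle to about 0.1 degree.

One geometric consequence of a sub-hemispheric cup deserves emphasis: a
translation straight out of the cup increases every clearance, so with the
3 mm cap enabled the engine legitimately postpones impingement several
degrees past the concentric closed form.  The oracle models the concentric
zero-translation case only.  All engine-versus-oracle comparisons
(including the cohort study replica) therefore run with
`max_translation = 0`, and the cap semantics are tested separately:
endpoints are monotone non-decreasing in the cap, and a constructed
contact needing ~5 mm of separation is impinged at a 3 mm cap but resolved
at 6 mm.

## Synthetic CT and segmentation

`voxelize_ct()` rasterizes the closed meshes on a grid with 0.265 mm
in-plane pixels and 1.0 mm slices (slice axis superior), emulating the
acquisition protocol of the validation experiment the phantom stands in
for.  Intensities are relative densities — air 0, soft tissue 1.0, nylon
1.15, bone 1.9 — not calibrated Hounsfield units; nylon sits between soft
tissue and bone so a threshold of 1.5 excludes the cam while 1.05 includes
it, reproducing paired with/without-deformity femur models from a single
acquisition.  An optional 2x supersampling mode yields partial-volume
fractions at boundaries; the default rasterizes at the target grid, which
conserves convex-body volumes to well under 2 percent at this spacing.

`segment_volume()` thresholds at native resolution, optionally
block-averages the binary mask to a coarser occupancy field (surfaced at
0.5 occupancy, which avoids biasing the boundary toward either material),
keeps the largest connected components, and extracts surfaces by marching
tetrahedra — chosen over table-driven marching cubes because the six-tetrahedron
cube split is watertight by construction with no case table.  Iso-surface
meshes are dense, so `decimate_mesh()` (vertex clustering) reduces them
before collision sweeps.  The CT round-trip used in the tests reconstructs
at 0.53 mm in-plane / 1.0 mm slices and decimates at 1.0 mm; endpoints
re-simulated on the segmented meshes stay within 1 degree of the
mesh-direct endpoints, which quantifies the image pipeline's contribution
to error.  Reconstructing much coarser than half the joint clearance is
not meaningful: both articular surfaces can then land in a shared cell and
fuse.

## Impingement localization and virtual resection

At a blocked pose, `contact_zone()` collects the face pairs within the
contact tolerance and reports the femoral zone's area and area-weighted
centroid, mapped to the radiological head-neck clock face (12 superior,
3 anterior on a right hip, mirrored on the left) about the neck axis.
`aggregate_map()` unions zones over a motion set and tracks per-vertex
maximum penetration.

`resection_estimate()` plans the bone removal that dissolves impingement
at given target angles.  Each round poses the femur at each target (with
the allowed correction), finds the femoral vertices within the contact
tolerance of the pelvis, carves, and re-checks, up to 20 rounds.  The
default `"spherical"` mode cuts contacting head vertices radially back to
the best-fit spherical head contour — the osteochondroplasty goal of
restoring sphericity — rather than shaving only the interfering sliver;
partial-sliver cuts leave near-contact surfaces that re-impinge at
adjacent poses, and surgeons burr to the spherical contour for the same
reason.  The sphericity carve applies only where the surface is radial
(vertex normal aligned with the radius); neck and shaft contacts get the
minimal clearance carve along their normals (`"minimal"` mode applies that
everywhere).  The resected volume is the closed-mesh volume difference,
cross-checked against a depth-times-area sweep estimate.  On the default
phantom the estimate converges in three rounds, removes almost exactly the
closed-form bump volume, and re-simulation restores the native endpoints
to within the angular resolution.

## The comparison layer

`compare_conditions()` differences native and cam endpoint tables per
motion and flags a limitation when the difference strictly exceeds the
threshold (5 degrees by default — "restricted by more than 5 degrees" is
a strict inequality; a difference of exactly 5 is not flagged).
`error_vs_reference()` subtracts reference (tracking-system-style)
limitations from simulated ones at full precision, rounding only at
output; `error_stats()` reports the median (mean of the middle two for
even n), the 25th-75th percentile interquartile range with type-7 linear
interpolation, and the maximum absolute error.  `detection_confusion()`
scores simulated flags against reference flags.  The ROM CSV uses a long
`subject,source,condition,motion,angle_deg` schema with angles written to
0.1 degree.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(n_az = 64)          # right hip, 2 o'clock cam
ph <- generate_phantom(spec)
cfg <- sim_config(max_translation = 0)

native <- simulate_standard_set(phantom_model(ph, "native"), cfg)
cam <- simulate_standard_set(phantom_model(ph, "cam"), cfg)
cmp <- compare_conditions(
  rom_record("phantom", "simulation", "native", native),
  rom_record("phantom", "simulation", "cam", cam))
cmp
autoplot(cmp)
```

On the default phantom this reports losses of 2.5 degrees in abduction,
35.9 at 30 degrees flexion, 26.9 at 60 degrees and 14.9 degrees of
internal rotation at 90 degrees flexion, the last three flagged at the
5 degree threshold — the anterosuperior cam signature.

## Problem sizes, tolerances and limitations

The test suite and the acceptance script use `n_az = 48` phantom meshes
(about 9,000 femur faces with the cam refinement), a five-phantom cohort
with cam heights drawn from 2-5 mm, two-motion CT round-trips, and
0.1 degree endpoint resolution; these sizes were chosen so the full
validation remains a coffee-break run on one core while every geometric
tolerance stays an order of magnitude below the quantities asserted.

What passing these suites shows — and does not show.  The phantom is an
idealized concentric ball-in-cup: it validates the geometry kernel, the
pose model, the endpoint search, the image pipeline and the comparison
arithmetic against exact oracles.  It does not emulate real anatomy
(aspherical heads, labrum and cartilage, capsular constraints, pelvic tilt),
scanner physics beyond partial-volume averaging, or segmentation of real
CT contrast; absolute ROM values from real data over-estimate the
soft-tissue-constrained joint, which is why comparisons are framed as
native-versus-deformity differences rather than absolute angles.  Combined
sport-specific motion paths are out of scope; sweeps are single-axis with
fixed prepositioning.
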