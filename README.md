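# hipsim

CT-based dynamic simulation of hip range of motion (ROM) for
femoroacetabular impingement (FAI) assessment, in R.

Cam-type FAI — an aspherical prominence at the femoral head-neck junction —
limits hip motion by bony contact against the acetabular rim, but static
radiographs cannot tell whether a given bump actually blocks motion.
`hipsim` answers the question dynamically: given triangulated femur and
pelvis surfaces (from CT segmentation or the built-in phantom), it sweeps
clinically defined motions, checks bone-on-bone collisions at every pose,
and registers the angle at which impingement halts the motion.

For a pose with flexion φ (about the pelvis Z axis), abduction α (pelvis
X) and internal rotation ρ (femoral long axis, intrinsic), the femur is
reoriented by `R = R_flex(φ) · R_abd(α) · R_int(ρ)` about the hip rotation
center. A colliding pose may spend up to 3 mm of corrective femoral-head
translation, chosen to maximize the minimal articular clearance (the
equidistant criterion); a pose needing more is *impinged*, and the
endpoint is bracketed to 0.1°. A motion restricted by **more than 5°**
relative to the native hip counts as a detected limitation; simulated and
reference limitation differences are summarized by median, interquartile
range, and maximum absolute error.

The package covers the full workflow:

- **Geometry kernel** — STL/PLY/OBJ I/O, rigid transforms, AABB-tree
  collision queries with penetration estimates, capped penetration-resolving
  translation (`query_contact()`, `resolve_translation()`).
- **Anatomy** — ISB pelvis/femur frames, least-squares hip-center sphere
  fit with equidistant refinement, rigid fiducial registration with FRE.
- **ROM engine** — `simulate_standard_set()`: maximum flexion, abduction,
  and internal rotation at 0°/30°/60°/90° flexion.
- **Impingement reporting** — contact zones on the head-neck clock face
  (12 = superior, 3 = anterior on a right hip), aggregate impingement maps,
  and virtual resection planning (`resection_estimate()`).
- **Hip phantom** — a parametric ball-in-cup hip with a spherical-cap cam
  (defaults match a 1 cm × 3.5 mm nylon screw head at the anterosuperior
  11–2 o'clock band), closed-form endpoint oracles, synthetic CT
  voxelization (0.265 mm pixels, 1.0 mm slices; nylon density 1.15 vs bone
  1.9) and marching-tetrahedra segmentation.
- **Comparison layer** — native-vs-cam tables, strict 5° limitation flags,
  detection confusion counts, error statistics, ROM CSV and report I/O,
  with tibble outputs, `tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(hipsim)

spec <- phantom_spec(n_az = 64)              # right hip, 2 o'clock cam
ph   <- generate_phantom(spec)
cfg  <- sim_config(max_translation = 0)      # concentric regime

native <- simulate_standard_set(phantom_model(ph, "native"), cfg)
cam    <- simulate_standard_set(phantom_model(ph, "cam"), cfg)
compare_conditions(rom_record("ph1", "simulation", "native", native),
                   rom_record("ph1", "simulation", "cam", cam))
#> # A tibble: 6 × 5
#>   motion        native   cam difference limited
#>   <chr>          <dbl> <dbl>      <dbl> <lgl>
#> 1 max_flexion    141.  141.         0   FALSE
#> 2 max_abduction   73.6  71.1        2.5 FALSE
#> 3 max_ir_0        90    90          0   FALSE
#> 4 max_ir_30       90    54.1       35.9 TRUE
#> 5 max_ir_60       55    28.1       26.9 TRUE
#> 6 max_ir_90       31.6  16.7       14.9 TRUE
```

The cam costs nothing in flexion or neutral internal rotation but removes
14.9° of internal rotation at 90° flexion and over 25° in mid-flexion —
the classic anterosuperior cam signature. The closed-form oracle for this
phantom (`analytic_standard_set(spec, cfg)`) agrees with each simulated
endpoint to about 0.1°.

A command-line interface wrapping the same functions is installed at
`inst/scripts/hipsim` (`phantom`, `simulate`, `resect`, `compare`
subcommands).

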