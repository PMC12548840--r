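---
title: "Methods: lumbar loading in three deadlift variants"
author: "lumbarlift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lumbar loading in three deadlift variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lumbarlift)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, the numerical choices, and what
the synthetic-data design does and does not establish about real lifts.

## The problem

Deadlift variants load the lumbar spine differently. The stiff-legged
deadlift (SLDL) forces a near-horizontal trunk at the start of the pull,
a larger lumbar flexion range of motion and a larger extensor torque than
the conventional (DL) or trap-bar (TBDL) variants; the question is how
those differences propagate into the stress carried by the vertebral
bodies, the trabecular centres and the intervertebral discs, and whether
they cross recognised damage thresholds. The package reproduces that
analysis chain at desk scale: synthetic instrumented trials feed
inverse dynamics, whose torque peaks drive a parametric finite-element
model of L1–L5, whose stress fields feed regional statistics, risk
thresholds and sensitivity analyses.

## The trial generator

The generator is not a fixture: it is the study-condition model, and its
defaults are the conditions the analysis assumes throughout.

* **Variants.** Flexion ranges 32–90° (DL), 0–90° (SLDL), 35–90° (TBDL);
  first-peak torques 749, 893, 640 N·m; trial duration 2 s (one metronome
  cycle); barbell mass 120 kg. The load is also described in the source
  protocol as 75% of the single-repetition maximum; the generator treats
  the barbell mass as configuration with 120 kg as the default.
* **Torque profile.** A monotone piecewise-cubic Hermite spline through
  five knots: baseline at 0.6 × first peak (so the first hard-pull phase
  is non-empty), the first peak, a trough at 0.5 × first peak, a second
  peak at 0.85 × first peak (the second peak is always smaller than the
  first), and an end value of 0.15 × first peak — roughly the bar weight
  times its standing moment arm, so the lockout is mechanically
  plausible. Monotonicity between knots means the curve has exactly two
  interior maxima and one interior minimum, which is what the four-phase
  segmentation requires. Peak time fractions are (0.32, 0.78) for DL,
  (0.26, 0.74) for SLDL — the stiff-legged peak arrives earlier — and
  (0.34, 0.78) for TBDL.
* **Flexion profile.** A quintic smoothstep from the bottom position to
  lockout: monotone, with zero angular velocity and acceleration at both
  ends, so endpoint differentiation is benign.
* **Trunk model.** A single rigid supra-lumbar segment. Its mass comes
  from the elliptical-frustum torso model (semi-axes 0.16 × 0.11 m
  tapering to 0.14 × 0.09 m over 0.45 m at 1050 kg/m³, about 22 kg); its
  centroidal inertia uses the slender-rod approximation m·L²/12; the
  centre of mass sits at 45% of the 0.45 m trunk line. These
  anthropometrics are configuration, shared between the generator and the
  inverse-dynamics stage, as segment parameters always are in practice.
* **Markers and bar.** Trunk markers (L5, L3, L1, T2, C7) lie on the
  trunk line at anatomical arc distances; pelvis markers are static; the
  bar hangs at arm's length below the shoulder with a fixed 0.12 m
  anterior offset from the lumbar joint, which keeps its moment arm
  positive through lockout.
* **Consistency contract.** The bar force magnitude is solved per frame
  so that the Newton–Euler balance on the exact segment states reproduces
  the prescribed torque to machine precision. Round-trip tests therefore
  have an exact oracle: inverse dynamics on noise-free output must return
  the prescribed curve (observed agreement ~1e-13 relative).
* **Noise.** Isotropic Gaussian marker noise, SD 0.5 mm, seeded,
  added after the kinematic construction; it is the only stochastic
  component. Force series are noise-free.

What passing tests show about real data — and what they do not: the
generator produces ideal rigid-body kinematics with stationary Gaussian
noise. Real lifts add soft-tissue artifact, marker occlusion and
drop-outs, multi-segment spine motion and force-plate drift; agreement at
0.5 mm noise bounds the pipeline's numerical error, not its robustness to
those effects.

## Filtering and kinematics

Both data streams pass a 4th-order Butterworth low-pass filter applied
forward and backward (zero phase; squared magnitude response), 10 Hz for
kinematics and 100 Hz for forces. The series is extended by odd
reflection and the filter is initialised at steady state, so constants
and trends pass without edge transients. At the cutoff each pass applies
the −3 dB gain, so the round trip halves the amplitude — the packaged
test measures exactly that.

The lumbar flexion angle is the sagittal-plane angle between the L5→L1
marker line and the vertical (0° upright, 90° horizontal). The source
study pastes L1/L3/L5 markers but never defines the angle; since its
reported 58°/55°/90° equal the widths of its reported flexion ranges, the
range of motion (max − min of the filtered series) is the reproduced
quantity, and the marker pair is configurable so a T2-based trunk line
can be swapped in.

## Inverse dynamics

The joint balance is written about the lumbar joint centre with the
gravito-inertial term combining centroid acceleration and gravity:

τ = I·α + ω×(I·ω) + m·r_c×(a_c − a_g) − Σ r×F_ext.

The printed form of this balance in the source is notationally loose
("ωIω", "F_ext×r_c", gravity-only mass term); the package implements the
canonical rigid-body reading above, with extensor torque positive (the
sagittal torque is minus the Y component in the X-facing, Y-left, Z-up
laboratory frame). Angular and centroid accelerations come from
second-order central differences of the filtered series (one-sided at the
ends); the 500 Hz force series is filtered and decimated to the marker
frames. With these choices the recovered first peaks sit within about
0.5–0.8% of the prescribed values — the 2% acceptance margin absorbs the
filter and differencing bias.

Phase segmentation detects strict local maxima with prominence at least
5% of the series range (the source defines the phases but no detector);
if more than two qualify, the two largest are kept, ties to the earliest
frame. Boundaries are (start, first peak, trough, second peak, end).

## The parametric finite-element model

The subject-specific CT geometry is unavailable, so the model is an
idealised parametric stack, and that decision defines the reproduction
surface: orderings, percentage contrasts and regional patterns, not
absolute magnitudes.

* **Geometry.** Five identical elliptical-prism vertebral bodies
  (44 mm wide × 34 mm deep × 27 mm high), each split into a cortical
  shell of exactly 1 mm normal thickness (the inner boundary is the true
  normal offset of the outer ellipse) and a cancellous core; four 10 mm
  discs, each split into a nucleus (40% of the radius) and three
  concentric annulus layers (20% each); 0.5 mm endplates above and below
  each disc; six ligament groups (anterior and posterior longitudinal,
  flavum, interspinous, supraspinous, intertransverse) as 30 mm² truss
  lines spanning each vertebral junction at fixed angular stations.
  The part census is 5 cortical + 5 cancellous + 4 nucleus + 8 endplate
  + 12 annulus + 6 ligament groups. Posterior bony elements are omitted;
  statements about stress concentration at pedicles and processes are
  out of this model's scope.
* **Mesh.** A structured "polar" triangulation of the cross-section
  (centre node, concentric rings sharing angular stations, with dedicated
  rings on every material boundary) extruded in z and split into
  tetrahedra. The diagonal of every vertical quad face passes through the
  face's smallest global node id; with plane-major numbering this rule is
  quad-local, so adjacent prisms always agree and the undecomposable
  cyclic patterns cannot occur — the mesh is conforming by construction,
  which realises the "tied/binding" contact of the model as shared nodes.
  Meshing is fully deterministic. Layers of the basal (L5) vertebra are
  graded geometrically towards the fixed boundary (first layer about a
  sixteenth of the target edge), because the lumbosacral clamp corner is
  where the reference analysis localises the global stress maximum and a
  uniform coarse layering under-resolves it.
* **Materials.** Thirteen isotropic linear-elastic materials (cortical
  12 000 MPa / ν 0.3; annulus layers 550/490/440 MPa; cancellous 100 MPa
  / ν 0.2; endplate 25 MPa; ligaments 8–15 MPa; nucleus 1 MPa with ν 0.5
  clamped to 0.4999). The annulus is tabulated transversely isotropic and
  the cancellous bone hyperelastic in the source; both are solved
  isotropic linear — consistent with the source's own statement that
  nonlinear and time-dependent behaviour was excluded.
* **Loads.** Inferior L5 surface fully fixed; superior L1 surface carries
  1425 N of vertical compression as a uniform traction (tributary-area
  nodal shares) plus the variant's first-peak torque as a sagittal
  moment, realised as a linearly varying axial force couple with zero net
  force; the couple constant is chosen so the net moment is exact. The
  source states the boundary conditions are set from the flexion angle,
  peak moment and vertical load but does not print the moment magnitudes;
  pairing the 1425 N with the first-peak torques is the package's
  reading, and with these section properties the moment dominates (the
  vertical-only contribution to the disc peak is ~1%), so the percentage
  contrasts track the torque ratios (893/749 − 1 ≈ 19%).

## The solver

Linear statics with constant-strain (4-node) tetrahedra and 2-node truss
elements, assembled in vectorised R into a sparse symmetric operator and
factorised directly (the default working meshes stay well below 10⁵
degrees of freedom; tests and the acceptance runs use 5–7 mm target
edges, giving 20–40k tets and solves in seconds). Dirichlet conditions
support non-zero prescribed displacements (used by the rigid-platen
composite benchmark). The relative residual is checked against 1e-8;
direct factorisation delivers ~1e-14. Stresses are recovered per element
(no nodal averaging except in exports), and peaks are element-wise von
Mises values.

Verification rests on independent oracles: the single-element stiffness
against a Vandermonde-based closed form, a uniform-pressure patch test
(exact for the linear field), a two-material composite column against the
parallel load-sharing formula, equilibrium of reactions, exact linearity,
and monotone strain-energy convergence on a bending benchmark.

Numerical caveats, stated rather than hidden:

* The near-incompressible nucleus (ν 0.4999) locks volumetrically in
  constant-strain elements; it behaves as a stiff hydrostatic core with
  low von Mises intensity — qualitatively right (the disc loads
  peripherally) but not a mixed-formulation treatment.
* The clamped lumbosacral corner and the bi-material junction corners are
  weakly singular; their peak values are resolution-dependent, as in any
  linear model with re-entrant material corners. At the package's working
  resolutions (5–7 mm with basal grading) the lumbosacral concentration
  dominates and L5 carries the largest cortical peak, consistent with the
  reference pattern; under strong further refinement the junction
  corners — an artifact of the sharp idealised interfaces — begin to
  compete. The comparative surface (orderings across variants, percentage
  contrasts) is insensitive to this, as all load cases share the mesh.

## Regional statistics, risk, validation, sensitivity

* **Regions.** The disc's elements are tiled 3×3 by empirical terciles of
  the two transverse centroid coordinates, labeled row-major A…I with the
  anterior row first and E central; the nucleus centroid falls in E by
  construction. The source's note naming the corner regions is internally
  inconsistent (one label is assigned to two corners); the row-major
  convention is adopted.
* **Quantitative difference.** The source never defines its "quantitative
  difference"; the package uses the pooled-SD standardized mean
  difference versus region E, with the source's class boundaries β = 0.8
  (significant above) and γ = 1.27 (very significant at or above).
  Printed QD values in the source's tables are treated as classification
  inputs, not as outputs to reproduce; likewise its CV columns are not
  consistently SD/mean, while the package computes CV = SD/mean exactly.
  Whether the source computed QD over per-subject replicates (n = 8) or
  per-element samples is unstated; the element-wise definition is the
  documented stand-in.
* **Risk.** Exceedance = (peak − threshold)/threshold × 100 with strict
  flagging, thresholds 1000 MPa (cortical damage), 3.0 MPa (trabecular
  fatigue), 40 MPa (disc tolerance). The worked examples — +14% for a
  45.6 MPa disc peak, −0.3% for a 997 MPa cortical peak — are pure
  arithmetic on the reference study's reported peaks.
* **Validation.** Relative errors of the reference model's indicator
  values against published literature benchmarks (0.6%–4.0%), shipped as
  package data; the analysis also prints this package's own idealised
  compression stiffness for context, which is *not* expected to match
  subject-specific values.
* **Sensitivity.** Cortical modulus ±10%, nucleus modulus ±20%, vertical
  load ±5%, moment ±5%, each re-solved at both ends; levels ≥5% high,
  3–5% medium, <3% low (bands read off the reference protocol's printed
  intervals). Two structural facts are worth noting. A pure vertical-load
  perturbation scales the solution linearly, so its change rate equals
  the perturbation exactly in a moment-free case. And in a
  stiffness-dominated parallel composite the stress change under a
  modulus perturbation is bounded by the perturbation itself (load-share
  compensation); in this idealised column the cortical shell carries
  ~97% of the bending stiffness, so its modulus case lands well below
  10% — lower than in the heterogeneous subject-specific reference model,
  where calibration spread makes the cortical modulus the high-
  sensitivity parameter. The nucleus modulus is negligible in both, and
  the moment is the strongest load-side driver here.

## Problem sizes

Package defaults keep the reference 2 mm target edge in the geometry
configuration; the analysis scripts and acceptance runs work at 5 mm
(≈36k tets, ≈20k DOF) and the test suite at 6–9 mm, sizes chosen so the
whole chain — three trials, three FE solves, regional statistics and the
sensitivity protocol — runs in minutes on a laptop while leaving every
qualitative conclusion unchanged.

## Known limitations

Single rigid trunk segment (no multi-joint chain); idealised symmetric
geometry without posterior elements, lordosis or level-to-level size
differences; linear elasticity throughout; tied interfaces (no contact);
element-wise peaks on meshes with weakly singular corners; synthetic
noise far tamer than real motion-capture artifact. Each limits the claims
to the comparative, model-level surface the package reproduces.
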