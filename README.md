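# lumbarlift

Lumbar-spine biomechanics of three deadlift variants — the conventional
deadlift (DL), the stiff-legged deadlift (SLDL) and the trap-bar /
hexagonal-bar deadlift (TBDL) — for strength-training and injury-risk
research. The package implements the full analysis chain from raw motion
data to finite-element stress statistics:

1. **Synthetic trials.** Marker trajectories (100 Hz) and bar-load series
   (500 Hz) for a 120 kg lift, built so that the lumbar joint torque is
   known exactly ("ground truth"): flexion ranges 32–90° (DL), 0–90°
   (SLDL), 35–90° (TBDL) and a double-peak sagittal torque profile with
   first peaks 749 / 893 / 640 N·m.
2. **Kinematics.** Zero-phase 4th-order Butterworth filtering (10 Hz
   kinematics, 100 Hz forces) and the L5→L1 sagittal flexion angle with
   its range of motion (ROM).
3. **Inverse dynamics.** The Newton–Euler joint balance for the rigid
   supra-lumbar trunk segment, moments about the lumbar joint centre,

   τ = I·α + ω×(I·ω) + m·r_c×(a_c − a_g) − Σ r×F_ext,

   reported as the scalar sagittal torque (extensor positive), plus the
   four-phase segmentation of the lift (first pull → transition → second
   pull → standing) delimited by the two torque peaks and the trough.
4. **Finite elements.** A parametric L1–L5 model (elliptical vertebral
   bodies with a 1 mm cortical shell, four discs with nucleus + three
   annulus layers, 0.5 mm endplates, six ligament line groups), meshed
   with conforming linear tetrahedra, loaded with 1425 N of vertical
   compression plus each variant's first-peak torque as a sagittal
   moment, and solved as a static linear-elastic problem with von Mises
   stress recovery.
5. **Stress statistics.** 3×3 regional disc statistics with the
   standardized quantitative difference against the central region E
   (class boundaries β = 0.8, γ = 1.27), injury-threshold risk reports
   (cortical 1000 MPa, trabecular 3.0 MPa, disc 40 MPa), literature
   validation arithmetic, and a material/load sensitivity protocol.

The subject-specific CT geometry of the original study is not available,
so absolute stress magnitudes are not the comparison surface; orderings
(SLDL > DL > TBDL), percentage contrasts and the regional patterns are.

## Worked example

```r
library(lumbarlift)

trial <- generate_trial(default_action_template("SLDL", noise_sd_mm = 0))
range_of_motion(lumbar_flexion_series(trial$markers))
#> [1] 89.99988

tq <- lumbar_torque_series(trial)
first_peak_torque(tq)
#> [1] 894.2118
as.data.frame(segment_phases(tq))[, 1:3]
#>         phase start_frame end_frame
#> 1  first_pull           1        51
#> 2  transition          51       102
#> 3 second_pull         102       146
#> 4    standing         146       201
```

The stiff-legged trunk starts parallel to the ground, so the ROM is the
full 90°, and the recovered first-peak torque lands on the prescribed
893 N·m to within the filtering/differencing error (≈0.1%). The
finite-element contrast on the coarse (5 mm) mesh:

```r
params <- lumbar_geometry_params(target_edge_mm = 5)
mesh <- assign_materials(mesh_geometry(build_geometry(params)))
sys <- assemble_system(mesh)
sapply(c(DL = 749, SLDL = 893), function(M)
  peak_stress_by_part(solve_static(sys, build_load_case(mesh, "x", M)),
                      "L4-L5"))
#>       DL     SLDL
#> 196.4981 233.7754   # +19% for the stiff-legged load case
```

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate_trials.R      # trials for DL / SLDL / TBDL
Rscript analysis/02_flexion_kinematics.R   # flexion series + ROM table
Rscript analysis/03_inverse_dynamics.R     # torque series, phases, peaks
Rscript analysis/04_fe_stress.R            # FE solves, per-part peaks, VTK
Rscript analysis/05_regional_disc_stats.R  # 3x3 disc regions, QD classes
Rscript analysis/06_risk_validation.R      # thresholds + literature errors
Rscript analysis/07_sensitivity.R          # parameter sensitivity protocol
```

Each step reads the previous step's artifacts, so they can be re-run
individually. `run_pipeline()` offers the same stages as a single
programmatic entry point.

## Vignette

`vignettes/lumbar-deadlift-methods.Rmd` documents the model assumptions,
the generator's design, the numerical choices in the solver and the known
limitations of the idealised geometry.
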