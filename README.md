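# ozaplan

Virtual-trajectory planning for basilar apex (BX) aneurysm surgery.

Basilar apex aneurysms sit deep in the interpeduncular cistern, and the
surgeon's line of sight passes over the internal carotid artery (ICA). When
the corridor points too low on the lateral skull, a standard pterional
craniotomy is not enough and the more invasive orbitozygomatic approach
(OZA — removal of the orbital rim and zygomatic arch) is needed. `ozaplan`
implements a quantitative way to make that call before opening:

1. **The ABC line.** Let **A** be the basilar artery apex and **B** the
   ipsilateral ICA bifurcation. The ray from A through B, extended beyond B,
   is the visual trajectory into the interpeduncular cistern; its exit point
   through the cranium, **C**, is the centre of the cranial window the
   approach must provide. `ozaplan` computes C by casting the ray against a
   watertight triangulated skull surface (Möller–Trumbore intersection,
   outer-table exit).
2. **Craniometry.** Five quantities drive the decision: height of A and
   height of B above the dorsum sellae, lateral width of B from the midline,
   and the distances from C to the zygomatic arch (**C–Z**) and to the
   lateral canthus (**C–L**). C–Z and C–L inversely reflect the need to
   remove the zygoma and the orbital rim.
3. **Decision rule.** Both distances < 3 cm → OZA recommended; both > 4 cm →
   pterional sufficient; anything between → indeterminate, review the case.
4. **Statistics.** Pearson correlations of C–Z / C–L with the three
   anatomical predictors, tested two-sided at the Bonferroni-corrected level
   α = 0.05/3 ≈ 0.017.

Because no imaging cohort can be redistributed, the package ships a
parametric synthetic-anatomy generator: an ellipsoidal cranial phantom with
landmark set (dorsum sellae, external auditory canals, zygomatic arch
polylines, lateral canthi) and vascular point pairs drawn from
moment-matched truncated normal distributions calibrated to published
cohort statistics (height of A 4.9 ± 3.8 mm, height of B 5.7 ± 3.1 mm,
width of B 15.7 ± 3.4 mm, with their printed ranges). A voxel phantom path
(rasterisation + surface re-extraction, optional NIfTI export) mimics the
CT-to-surface step. The measured per-patient table of five surgically
treated BX aneurysms is included as a plain-text fixture.

The audience is neurosurgical researchers and imaging scientists studying
approach selection, and anyone needing a fully reproducible, testable
geometry pipeline for landmark-based trajectory analysis.

## Worked example

```r
library(ozaplan)

skull <- generate_skull()                      # 70 x 90 x 65 mm phantom
A <- c(0, -8, 4.9)                             # basilar apex (mm)
B <- c(15.7, 10, 5.7)                          # ICA bifurcation (mm)
traj <- compute_point_c(A, B, skull$mesh)
traj
#> <oza_trajectory> C = (54.22, 54.17, 7.66) mm, t_B = 23.90, t_C = 82.54 mm
measure_all(skull, traj, "right", A, B)[, 3:7]
#>   height_A_mm height_B_mm width_B_mm cz_mm cl_mm
#>           4.9         5.7       15.7  31.4  23.7
```

The trajectory for a cohort-average anatomy exits the skull 82.5 mm from
the apex; point C lies 31.4 mm from the zygomatic arch and 23.7 mm from the
lateral canthus — an indeterminate case under the 30/40 mm rule (C–L argues
for orbital rim removal, C–Z is borderline).

A full synthetic cohort, its correlation report and the five-patient
decision check:

```r
cohort <- simulate_cohort(cohort_params(n = 80), skull, seed = 7)
pearson_with_bonferroni(cohort)
#> Pearson correlation report (n = 80, corrected alpha = 0.017)
#>   outcome predictor       r        p significant
#> 1 cz      height_A  -0.532  3.87e- 7 TRUE
#> 2 cz      height_B   0.702  3.98e-13 TRUE
#> 3 cz      width_B   -0.0861 4.48e- 1 FALSE
#> 4 cl      height_A  -0.296  7.70e- 3 TRUE
#> 5 cl      height_B   0.223  4.69e- 2 FALSE
#> 6 cl      width_B    0.592  7.44e- 9 TRUE

tab <- load_table2_fixture()
classify_oza(tab$cz_mm, tab$cl_mm)[, c("cz_mm", "cl_mm", "label")]
#>   cz_mm cl_mm label
#> 1  87    85.1 pterional_sufficient
#> 2  57    47.9 pterional_sufficient
#> 3  36    31   indeterminate
#> 4  15    29.5 oza_recommended
#> 5  23.3  28.7 oza_recommended
```

A higher apex tilts the trajectory downward (C–Z shrinks, r < 0); a higher
carotid bifurcation tilts it upward (C–Z grows, r > 0) — the geometric
mechanism behind the approach rule. `plot_point_c()` draws the point-C
scatter relative to the external auditory canal, `autoplot()` the
correlation report, and `run_pipeline(run_config(...))` executes the whole
chain (generate → project → measure → classify → correlate) into a
directory with a JSON manifest that reproduces every numeric artifact
bit-exactly. `inst/cli/ozaplan.R` exposes the same steps as shell
subcommands.

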