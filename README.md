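# ctanthro

Three-dimensional CT body composition with survival prognostics.

In oncology, the partition of body mass into skeletal muscle, visceral fat
and subcutaneous fat carries prognostic information beyond BMI, but it is
usually estimated from a single axial CT slice at the third lumbar
vertebra (L3). `ctanthro` implements a whole-body, 3D alternative: every
voxel of an abdomino-pelvic or thoraco-abdomino-pelvic CT is classified
into muscle / subcutaneous fat / visceral fat, and the tallies are turned
into whole-body masses using tissue densities and atlas-derived
*adaptive extrapolation factors* that compensate for the anatomy outside
the acquisition field. The matching 2D L3-level areas are computed for
comparison, and a statistics layer relates the measurements to overall
survival.

## The model

For tissue voxel tallies `N_muscle`, `N_subcutaneous fat`,
`N_visceral fat` measured inside the acquisition field:

    MBM3D = N_muscle           x k_muscle           x V_voxel x rho_muscle
    SFM3D = N_subcutaneous_fat x k_subcutaneous_fat x V_voxel x rho_fat
    VFM3D = N_visceral_fat     x k_visceral_fat     x V_voxel x rho_fat
    FBM3D = VFM3D + SFM3D

with `V_voxel` the voxel volume in mL, `rho_muscle` = 1.06 g/mL,
`rho_fat` = 0.923 g/mL, and each extrapolation factor `k` the mean ratio,
over a CT atlas, of whole-body voxels of that tissue to the voxels seen in
the acquired body area (`k = 1` for a whole-body acquisition). All masses
(kg) and L3 areas (cm2) are normalized by squared body height (kg/m2,
cm2/m2).

Because no patient scans ship with the package, a synthetic phantom
generator (`generate_phantom()`) builds stylized whole-body CT volumes
with voxel-exact ground-truth labels, and `generate_cohort()` simulates a
526-patient-style survival cohort with a known proportional-hazards
structure; every stage is validated against these ground truths.

## Worked example: phantom to masses

```r
library(ctanthro)

spec <- phantom_spec(spacing = c(4, 4, 6))        # 4 x 4 x 6 mm voxels
ph   <- generate_phantom(spec)                    # whole-body phantom
cr   <- crop_field(ph$volume, ph$truth, "abdomen_pelvis")

atlas <- lapply(1:5, function(i) {                # 5-subject CT atlas
  p  <- generate_phantom(sample_phantom_spec(i, spec))
  c2 <- crop_field(p$volume, p$truth, "abdomen_pelvis")
  atlas_entry(p$truth, c2$truth)
})
k <- build_extrapolation_factors(atlas, "abdomen_pelvis")
#> <extrapolation_factors> field abdomen_pelvis (atlas n = 5)
#>           muscle subcutaneous_fat     visceral_fat
#>           4.1295           3.5649           1.0000

masks  <- segment_volume(cr$volume)               # HU windows + wall rule
masses <- compute_masses(masks, k, mass_constants(spec$spacing),
                         spec$height_m)
#> <mass_result> raw (kg):
#>  VFM3D  SFM3D  FBM3D  MBM3D
#>  3.636 22.680 26.310 19.410
#> normalized (kg/m2, height 1.75 m):
#> VFM3D SFM3D FBM3D MBM3D
#> 1.187 7.405 8.593 6.339
```

The factors say: this abdomino-pelvic field sees about 1/4.13 of the
body's muscle and 1/3.56 of its subcutaneous fat, while all visceral fat
lies inside the field (`k = 1`). The extrapolated masses agree with the
whole-body ground truth of the same phantom (VFM 3.64, SFM 22.94,
FBM 26.58, MBM 20.21 kg) to within 4%. `locate_L3()` plus
`compute_l3_areas()` give the 2D counterparts (here VFA2D 28.7,
SFA2D 48.1, FBA2D 76.8, MBA2D 30.8 cm2/m2).

## Worked example: prognostic analysis

```r
co <- read_cohort_csv(system.file("extdata", "synthetic_cohort_526.csv",
                                  package = "ctanthro"))
b  <- run_pipeline(pipeline_config(mode = "covariates_only", cohort = co))
b
#> <report_bundle> covariates_only, n = 526 (132 dead / 329 alive at 1 y)
#> ROC / Youden cutoffs:
#>          parameter cutoff   auc sensitivity specificity accuracy direction p_value
#>  line_of_treatment  1.500 0.517       0.485       0.559    0.538      less 0.55219
#>              VFM3D  0.556 0.571       0.409       0.729    0.638      less 0.01634
#>              SFM3D  5.309 0.554       0.879       0.258    0.436      less 0.06728
#>              FBM3D  4.724 0.579       0.652       0.483    0.531      less 0.00800
#>              ...
```

`direction = "less"` marks "low marker = risk": patients below the Youden
cutoff are the high-risk group. The bundle also carries Kaplan-Meier
curves with log-rank tests for markers with a significant AUC, univariate
Cox tables for the whole population and per sex (e.g. VFM3D: HR 0.52 per
kg/m2, p = 1.3e-07 here, reflecting the protective visceral-fat effect
built into the simulated cohort), per-cancer-type forest-plot data, and
the Spearman correlation matrix of the eight parameters. With
`output_dir` set, everything is written as CSV plus a JSON manifest. A
command-line wrapper lives in `inst/scripts/ctanthro-cli.R`
(`simulate`, `analyze`, `run-all`).

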