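# cbmap — cortical bone mapping of vertebral CT

`cbmap` measures vertebral cortical structure from calibrated clinical
CT at and below the scanner's spatial resolution, and analyzes how it
changes under treatment. It is aimed at bone-imaging researchers who
have periosteal surface meshes and QCT volumes (or who want fully
synthetic, ground-truthed stand-ins) and need per-vertex cortical
metrics, canonical-shape registration, and group-level statistical
parametric maps.

## The method

Density profiles are sampled perpendicular to the bone surface at each
mesh vertex. The true (unblurred) profile is modeled piecewise along
the inward normal: soft-tissue background `y_bg`, a cortical plateau
`y_c` (Ct.BMD) from the periosteal edge `x0` to `x1`, a **linearly
decreasing endocortical transition** from `x1` to `x2`, and a
cancellous plateau `y_t` (Cn.BMD) beyond. The scanner is modeled as a
Gaussian point spread function of width `sigma`; fitting the *blurred*
model to the samples (closed-form erf/ramp convolution, variable
projection, bounded Levenberg–Marquardt with multi-start) recovers the
parameters even when the cortex is thinner than the blur. Derived
metrics per vertex:

* `Ct.Th = (x1 + x2)/2 − x0` — cortical thickness, periosteal surface
  to the **midpoint** of the endocortical transition (mm),
* `Ec.Th = x2 − x1` — endocortical thickness, the transition width (mm),
* `Ct.BMD = y_c`, `Cn.BMD = y_t` (mg/cm³),
* `CMSD = 0.1 × Ct.Th × Ct.BMD` — cortical mass surface density (mg/cm²).

Maps are smoothed over geodesic neighborhoods on the mesh, registered
onto a canonical shape (ICP + thin-plate spline), and compared across
timepoints and treatment arms with t tests and permutation
max-statistic statistical parametric mapping (family-wise error
controlled; non-significant regions gray, out-of-scope posterior
elements dark gray). A synthetic-data module generates blurred shell
phantoms and two-timepoint cohorts with known ground truth,
parameterized by the published baseline and 12-month-change
distributions of a three-arm osteoporosis-treatment QCT study
(placebo n = 20, teriparatide n = 19, romosozumab n = 17).

See the vignette (`vignettes/cortical-bone-mapping.Rmd`) for the model,
the identifiability analysis that drives the two-pass
density-anchored fitting scheme, and all numerical choices.

## A worked example

Recover a 0.5 mm cortex under a 1.2 mm PSF — well below nominal
resolution — from a noiseless profile:

```r
library(cbmap)
p <- cortical_params(x0 = 0, x1 = 0.45, x2 = 0.55,
                     y_bg = 20, y_c = 900, y_t = 120, sigma = 1.2)
prof <- gen_profile(p, spacing = 0.2, noise_sd = 0)
fit <- fit_profile(prof, fit_config(sigma = 1.2))
round(unlist(fit$metrics), 3)
#>   ct_th   ec_th  ct_bmd  cn_bmd    cmsd
#>   0.500   0.103 900.435 120.000  44.998
```

The fitted cortical thickness is 0.500 mm (truth 0.5), the transition
width 0.103 mm (truth 0.1), and CMSD 45.0 mg/cm² — the mass of a
0.5 mm slab at 900 mg/cm³ per the `0.1 × Ct.Th × Ct.BMD` identity.

Simulate and analyze a miniature three-arm two-timepoint cohort (3
subjects/arm, 40 vertices/subject — small enough to run in under a
minute; the study-scale presets are the defaults):

```r
spec <- cohort_spec(n = c(placebo = 3, teriparatide = 3, romosozumab = 3),
                    n_vertices = 40, seed = 7)
res <- run_pipeline(gen_cohort(spec))
res
#> Cohort summary: mean (SD) percentage changes from baseline
#>  metric        group n  mean   sd p_vs_baseline p_vs_placebo p_vs_teriparatide
#>   ct_th      placebo 3  -2.3  4.4        0.4622
#>   ct_th teriparatide 3   4.5  6.6        0.3597       0.2234
#>   ct_th  romosozumab 3  13.7  8.8        0.1155       0.0699            0.2283
#>   ...
#>  cn_bmd  romosozumab 3  18.9  5.3        0.0250       0.0060            0.8673
#>   cmsd  romosozumab 3  13.7  8.8        0.1155       0.0699            0.2283
```

Each row is an arm's mean (SD) percentage change from baseline of one
cortical metric, with two-tailed t tests versus baseline, versus
placebo and versus teriparatide; at n = 3 only the largest effects
(the romosozumab cancellous BMD gain of ~19 %) reach significance.
With the anchored fitting scheme the Ct.Th and CMSD rows coincide by
construction (the vignette explains why).

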