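# mpileak

Quantification of pulmonary vascular leakage from co-registered magnetic
particle imaging (MPI) and micro-CT volumes of the mouse thorax.

Increased pulmonary vascular permeability is a hallmark of acute lung
injury and accompanies pulmonary fibrosis, but the standard readouts
(Evans blue extravasation, BALF protein) are terminal, whole-lung
averages. MPI images a superparamagnetic iron oxide (SPIO) tracer in 3D
with signal proportional to local tracer amount; hours after injection,
tracer found in lung tissue marks extravasation through a disrupted
endothelial barrier. Anatomy comes from a paired micro-CT scan,
co-registered via tracer-filled bed fiducials, with the lung delineated
on CT. The quantitative endpoint is the **SPIO extravasation index**

```
SEI = ( Σ_lung PXLI / Σ_body PXLI ) / V_lung      [cm⁻³]
```

the fraction of whole-body tracer signal found in the lung per unit lung
volume — gain- and dose-invariant, bounded by `1/V_lung`.

The package is aimed at preclinical imaging groups who want this
workflow as tested, scriptable code. Since no animal data are deposited,
it includes a seeded digital torso phantom (analytic body / lung lobes /
heart / liver / spleen compartments, bed fiducials, Gaussian PSF,
additive noise, known rigid frame offset, exact signal budget) so every
stage — and the whole pipeline — can be validated against ground truth.

**Modules:** phantom simulation (`phantom_config`, `make_phantom`),
fiducial detection/matching and closed-form rigid registration
(`detect_fiducials`, `match_fiducials`, `estimate_rigid`,
`resample_mask_to_grid`), CT segmentation (`segment_body`,
`segment_lung`, `load_mask`), quantification (`compute_sei`,
`fit_calibration`, `leakage_map`), statistics (`mann_whitney`,
`summarize_groups`, `evans_blue_ug_per_g`), and orchestration
(`quantify_animal`, `run_study`, plus a thin CLI at
`inst/cli/mpileak.R`). Volumes are NIfTI-1; tables CSV; results JSON.

## Worked example

```r
library(mpileak)

ph  <- make_phantom(phantom_config(preset = "oa", seed = 7))   # injured animal
res <- quantify_animal(ph$ct, ph$mpi,
                       fiducial_set(ph$truth$fiducial_centers_mm$ct,
                                    frame = "CT"))
res$sei
#> <sei_result> SEI = 0.08204 /cm^3 (lung 41.0459 / body 1001.11,
#>              V_lung 0.4997 cm^3, 51219 voxels clamped)
ph$truth$true_sei_cm3
#> [1] 0.09007062
```

The pipeline detected the three bed fiducials (registration error
0.002 mm), segmented body and lung from CT, moved the masks onto the MPI
grid and recovered an SEI of 0.082 cm⁻³ against a ground truth of
0.090 cm⁻³ — about 9 % low, the expected PSF boundary-spill bias at the
default 0.7 mm blur (see the vignette's *Known limitations*). For a full
two-group study:

```r
study <- run_study(list(base_seed = 500,
  groups = list(list(name = "OA",  n = 6, preset = "oa"),
                list(name = "CTR", n = 6, preset = "ctr"))))
study$comparison
#> <group_comparison> OA (n=6): 0.0817 +/- 0.0003238 vs CTR (n=6): 0.02105 +/- 0.0002194
#>   fold difference 3.88; Mann-Whitney U = 36, two-sided p = 0.002165 (exact)
```

The injured-vs-control separation (~3.9×, exact two-sided p = 2/924) is
the phantom-scale analogue of the in vivo finding the index was designed
for.

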