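---
title: "Quantifying pulmonary vascular leakage from co-registered MPI and CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulmonary vascular leakage from co-registered MPI and CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A healthy pulmonary endothelium keeps macromolecules and nanoparticles in
the blood. When it is disrupted — acutely (e.g. oleic-acid-induced lung
injury) or chronically (bleomycin-induced fibrosis) — circulating
particles extravasate into the lung interstitium. Magnetic particle
imaging (MPI) detects superparamagnetic iron oxide (SPIO) tracers
tomographically, with signal proportional to the local tracer amount and
no attenuation by tissue or the air–tissue interface, which makes it well
suited to imaging where leaked tracer ends up. MPI carries no anatomy,
however, so each MPI volume is paired with a micro-CT scan, co-registered
through tracer-filled fiducial markers on the animal bed, and the lung is
delineated on CT.

`mpileak` implements this workflow end to end and, because animal and
scanner data are not publicly deposited, ships a digital phantom so every
stage can be exercised and validated against known ground truth.

## The SPIO extravasation index

At imaging time (hours after injection) the tracer remaining in
circulation has been cleared to the reticuloendothelial organs; signal in
the lung indicates extravasation. The index quantifying it is

$$\mathrm{SEI} \;=\; \frac{\sum_{\mathrm{lung}} \mathrm{PXLI}_{i,j,k}}
{\sum_{\mathrm{body}} \mathrm{PXLI}_{i,j,k}} \cdot \frac{1}{V_{\mathrm{lung}}}
\qquad [\mathrm{cm}^{-3}],$$

the fraction of whole-body tracer signal found in the lung, normalised by
lung volume. Normalising by the body sum cancels the arbitrary MPI gain
and the injected dose; dividing by $V_{\mathrm{lung}}$ makes indices
comparable across animals with different lung sizes. The index is
provably bounded: $0 \le \mathrm{SEI} \le 1/V_{\mathrm{lung}}$.

Three numerical decisions, configurable but deliberate, sit behind
`compute_sei()`:

* **Negative voxels are clamped to zero** before summation and the count
  is reported. Reconstructed MPI volumes can contain negative values;
  without clamping, the index can leave its provable bounds. The clamp
  introduces a small positive bias wherever per-voxel signal is
  comparable to the noise floor (see *Known limitations*).
* **Sums are taken on the MPI native grid.** CT-derived masks are moved
  onto the MPI grid by nearest-neighbour resampling through the rigid
  transform. Interpolating MPI intensities instead would redistribute
  signal across the lung boundary and bias both sums.
* **Fiducials are excluded** from the body sum through an exclusion mask
  (they contain tracer but sit on the bed, outside the animal), with a
  2.5 mm default radius so PSF-blurred fiducial signal cannot enter the
  sums.

The denominator uses the CT-derived body mask rather than the full field
of view; the choice is recorded in every result's provenance.

## Registration

Three (or more) tracer-filled fiducials are detected in the MPI volume by
relative thresholding (default half the volume maximum), 26-connected
component grouping, and intensity-weighted centroids. Correspondence to
the CT-frame fiducial table uses the inter-point distance signature —
rigid motion preserves pairwise distances, so for three points the
triangle side lengths decide the match. If two matchings agree within
0.25 mm (near-isosceles placement) the match is declared **ambiguous and
the pipeline stops**: a silent guess would corrupt the SEI
unrecoverably. The rigid transform itself is the closed-form
least-squares (SVD/Kabsch) solution with reflection correction and no
scale — both modalities are metrically calibrated, and the phantom's bed
fiducials share one physical frame. The fiducial registration error
(RMS residual) is recorded with every registration; simulated noiseless
registrations recover generating transforms to machine precision, and
the registration is validated in the tests against an independent
brute-force Euler-angle search.

## Segmentation

Micro-CT Hounsfield thresholds: body at $\ge -300$ HU (largest
26-connected component, internal holes filled so the air-density lungs
lie inside the body), lung as in-body voxels in $[-900, -200]$ HU with a
radius-1 morphological opening to cut thin airway-like bridges and a
0.01 cm³ minimum component size. The thresholds are standard micro-CT
heuristics, stated and configurable, since the original workflow relied
on manual slice-wise selection; hand-drawn masks can be imported through
`load_mask()`, which enforces grid-geometry agreement to 0.1 µm rather
than resampling silently. Whether large hilar vessels belong in the lung
region is genuinely undetermined in a manual protocol; the automated
window excludes soft-tissue-density vessels, and this choice is a config
note, not a claim. Lung volume is exactly voxel count × voxel volume —
no partial-volume weighting — so the volume entering the SEI is the
volume of the mask actually summed over.

## The digital phantom

`make_phantom()` builds a mouse-torso scene from analytic ellipsoids
(body, two lung lobes, heart, liver, spleen) and spherical bed fiducials,
rasterised on the CT grid in HU and on the MPI grid as a tracer
deposition map. The two frames are related by a small seeded rigid motion
(rotation up to 3°, translation up to 1 mm per axis), emulating animal
transfer between scanners. The MPI volume is the deposition map convolved
with an isotropic Gaussian PSF and degraded with additive Gaussian noise.
Everything is seeded: identical configurations are bit-identical.

Default conditions, chosen once to represent the emulated study:

| parameter | default | rationale |
|---|---|---|
| grid | 96×96×128 @ 0.3 mm | covers a mouse torso; 0.144 mm available for CT-fidelity runs |
| lung volume | 0.5 cm³ | adult mouse total lung volume |
| injected total | 1000 a.u. | arbitrary MPI units; all results are gain-invariant |
| liver / spleen fraction | 0.80 / 0.12 | liver-dominant clearance of dextran-coated SPIO at 8 h |
| leakage fraction | 0.045 (injured), 0.010 (control) | reproduces the in vivo SEI scale (≈0.09 vs ≈0.02 cm⁻³) and its ≈4.5× separation |
| PSF FWHM | 0.7 mm | high-resolution small-FOV scan mode; the true scanner PSF is unstated, so this is a knob, not a claim |
| MPI noise SD | 5×10⁻⁴ a.u. | ≈4 % of the per-voxel liver signal |
| CT noise SD | 20 HU | typical preclinical micro-CT noise |
| fiducials | 3 × 2 µL spheres, 50 a.u. each | stock-concentration tracer, far brighter than any organ |
| heterogeneity | 0.5 | patchy lung deposition via a log-normal smooth random field |

The heterogeneity field multiplies the lung deposition by
$\exp(h\,G(x))$ with $G$ a smooth seeded sum of Gaussian bumps, then
renormalises so the deposited lung fraction is exactly the configured
value — patchiness changes *where* the signal sits, never *how much*.

The PSF uses per-axis sigmas in world units (anisotropic spacing is
handled correctly) and column-normalised truncated kernels, which makes
the blur exactly mass-preserving including at the grid boundary. The
phantom's signal budget is exact by construction: the noiseless in-body
deposition sums to the injected total, and the whole grid to the
injected total plus the fiducial signals.

**What the phantom does not emulate:** magnetisation physics and the
Langevin response, projection-space acquisition and vendor
reconstruction (modelled only as PSF width plus noise), realistic
airway/vascular anatomy, respiratory motion, and tracer kinetics over
the post-injection window. Passing tests therefore demonstrate that the
*analysis* recovers known truth under stated imaging conditions — not
that any scanner achieves those conditions.

## Group comparison

Two-group comparisons use the Mann–Whitney U test computed from midrank
sums. With combined $n \le 20$ and no ties the two-sided p-value is
exact (permutation distribution of U; the tests verify it against full
enumeration of all $\binom{n_1+n_2}{n_1}$ labelings); otherwise the
normal approximation with tie correction and continuity correction is
used. The two-sided p doubles the smaller tail, capped at 1 — the common
software convention; the switch point and method are recorded in the
output. Group summaries report means ± SD ($n-1$) and the fold
difference of means. The Evans blue helper inverts a linear
absorbance standard curve to µg dye per g tissue, mirroring the ex vivo
reference assay.

## Validation strategy and problem sizes

The in vivo numbers of the emulated study derive from animals and
scanners and cannot be recomputed at desk scale, so validation is
property-based: exactness of the SEI arithmetic against phantom ground
truth (to 1e-9), gain invariance and bounds on randomised volumes,
machine-precision recovery of 200 random rigid transforms plus agreement
with a brute-force Euler search, exact Mann–Whitney equality with an
enumeration oracle and nominal type-I error at $n=6/6$, PSF mass
conservation, and leakage-map partition consistency. End-to-end, the
full pipeline is required to recover the phantom's true SEI with median
absolute relative error below 10 % over 20 seeded phantoms at default
conditions, and a 6 vs 6 two-group study must separate the injured and
control presets with a fold difference within 15 % of the configured
leakage ratio. These sizes (20 phantoms, 12-animal studies, 2000-run
null simulations) were chosen as the smallest that make the checks
statistically meaningful while keeping a full validation run in the
minutes range on one CPU.

## Known limitations

* **PSF boundary spill.** Blur moves lung-edge signal into surrounding
  tissue (and vice versa); since the injured lung is hotter than its
  surroundings, the pipeline slightly *under*-estimates high SEIs, and
  the error grows monotonically with PSF width. At the default 0.7 mm
  FWHM the bias stays within the 10 % validation band; at 2 mm it will
  not.
* **Clamping bias at low signal.** In the control preset the healthy
  lung's per-voxel signal is comparable to the noise SD, and clamping
  negatives inflates the lung sum slightly, *over*-estimating low SEIs.
  Both biases compress the recovered group fold difference relative to
  the configured ratio.
* **Rigid-only registration** cannot model breathing-state differences
  between the MPI and CT acquisitions.
* The analytic anatomy is deliberately simple; segmentation thresholds
  that work here may need adjustment on real micro-CT data.

## A worked example

```{r, eval = FALSE}
library(mpileak)

study <- run_study(list(
  base_seed = 500,
  groups = list(list(name = "OA",  n = 6, preset = "oa"),
                list(name = "CTR", n = 6, preset = "ctr"))),
  out_dir = "study_out")
study$comparison          # means, SDs, fold difference, exact MW p
plot(study$comparison, ylab = "SEI (1/cm^3)")

# single-animal pipeline, step by step
ph   <- make_phantom(phantom_config(preset = "oa", seed = 7))
fidT <- fiducial_set(ph$truth$fiducial_centers_mm$ct, frame = "CT")
res  <- quantify_animal(ph$ct, ph$mpi, fidT)
res$sei                   # SEI with sums, V_lung, clamp count
ph$truth$true_sei_cm3     # ground truth for comparison
map  <- leakage_map(ph$mpi, res$masks, block_mm = 2)  # hotspot map
```
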