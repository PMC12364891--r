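# hippovessel

Segmentation and quantification of **hippocampal supply vessels** from 7 T
T1-weighted (MPRAGE) MRI, plus a **mediation analysis engine** linking
systemic physiology to hippocampal volume through those vascular features.

## Why

At 7 T, unsaturated inflowing blood makes arteries markedly brighter than
stationary tissue on an ordinary MPRAGE scan, so the anatomical image doubles
as an MR angiogram. The hippocampus is among the most ischemia-vulnerable
structures in the brain, and its atrophy tracks cardiovascular risk. This
package implements, as reusable and tested R code, a pipeline that

1. enhances thin bright tubular structure with a 3D Haar-transform
   coefficient amplification (cube size 7, thresholds α₁ = 60, α₂ = 30,
   β = 10, gains γ₁ = 40, γ₂ = 0.5·γ₁ on [0, 255]-normalized intensities):

   C_En = C_H if |C_H| > α₁; γ₁·C_H if α₂ ≤ |C_H| ≤ α₁; γ₂·C_H if
   β ≤ |C_H| < α₂; 0 otherwise;

2. detects tubes with the multiscale Frangi vesselness
   V = (1 − e^{−R_A²/2α²}) · e^{−R_B²/2β²} · (1 − e^{−S²/2c²}) on the
   Hessian eigenvalues ordered |λ₁| ≤ |λ₂| ≤ |λ₃| (bright-vessel polarity);

3. thresholds the map at 5% of its maximum, removes white-matter,
   cerebellar, temporal, supramarginal and orbitofrontal labels, and keeps
   the connected components touching each (dilated) hippocampus;

4. reports per-hemisphere vessel voxel counts / mm³ volumes, mean
   WM-normalized signal intensity (SI; the WM mean is exactly 1), and
   lateralization indices LI = (right − left)/(right + left);

5. fits X → M → Y mediation path models (M a vessel metric, Y a hippocampal
   volume; covariates age, sex, ICV in both equations), with indirect effect
   a·b, direct effect c′, exact decomposition c = c′ + a·b, and 95%
   percentile-bootstrap confidence intervals — across the full grid of
   23 systemic variables × {total, left, right} × {vessel volume, SI} =
   138 models, with 50,000-iteration confirmation of significant rows.

Since no imaging data ship with the package, a synthetic-data module renders
vessel phantoms with ground-truth masks and simulates cohort tables with
known path coefficients; the entire test suite runs against those.

## Worked example

Segment the default digital phantom (two supply tubes of radius 2.5 voxels
at 1.6× WM intensity, SNR 20, plus a distractor vessel) and check recovery
against the built-in ground truth:

```r
library(hippovessel)

ph  <- make_phantom()                      # phantom + truth masks
res <- run_subject(ph$t1w, ph$labelmap, ph$wm_mask, subject_id = "phantom-42")
print(res)
#> <subject result> phantom-42: left 441 vox (186.0 mm^3, SI 1.425); right 446 vox (188.2 mm^3, SI 1.426)
#>   LI volume 0.0056, LI SI 0.0005

dice_coefficient(res$left_mask,  ph$vessel_truth_left)   # 0.862
dice_coefficient(res$right_mask, ph$vessel_truth_right)  # 0.868
```

Both vessel trees are recovered at Dice ≈ 0.86 with zero voxels leaking in
from the distractor; the recovered SI ≈ 1.43 sits between the true lumen
contrast (1.6× WM) and tissue because the detected object includes the
partial-volume margin. The near-zero LIs reflect the phantom's symmetric
geometry.

Mediation on a simulated cohort with known structure (n = 191, a = 0.5,
b = 0.4, c′ = 0.1):

```r
dd <- make_cohort(cohort_spec(n = 191, a = 0.5, b = 0.4, c_prime = 0.1, seed = 7))
tr <- attr(dd, "truth")
b  <- bootstrap_mediation(dd, mediation_spec(tr$x, tr$m, tr$y),
                          n_boot = 5000, seed = 7)
print(b)
#> <mediation fit> sdnn -> vessel_si_total -> hippo_vol_total (n = 191)
#>   a = 0.5142, b = 0.4409, c' = 0.0512, indirect = 0.2267, total = 0.2779
#>   indirect CI [0.13, 0.3449] *
#>   direct   CI [-0.1139, 0.2221]
#>   total    CI [0.1072, 0.4599] *
#>   5000 bootstrap iterations, seed 7
```

The generating indirect effect (0.20) is recovered at 0.227 with a CI
excluding zero (`*`), while the weak direct path is correctly not flagged.
`generics::tidy()` / `glance()` give the same numbers as tibbles,
`run_grid()` runs all 138 models, and `ggplot2::autoplot()` draws the forest
plot of the grid.

A thin command-line front end wraps the same functions
(`inst/cli/hippovessel.R`): `enhance`, `vesselness`, `segment`, `phantom`,
`simulate-cohort`, `mediate`, `run-subject`, `run-cohort`.

## Layout

- `R/` — implementation: volumetric containers and NIfTI I/O, Haar
  enhancement, vesselness, segmentation and metrics, mediation engine,
  synthetic generators, pipeline drivers, plots.
- `tests/testthat/` — unit, property and acceptance suites, including
  brute-force oracles for the enhancement and the path estimator.
- `vignettes/hippovessel-methods.Rmd` — the model, parameter choices,
  numerical decisions, and known limitations.
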