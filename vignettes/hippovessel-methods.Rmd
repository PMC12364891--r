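---
title: "Segmenting hippocampal supply vessels and testing vascular mediation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting hippocampal supply vessels and testing vascular mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hippovessel)
```

## The problem

At 7 T, inflowing unsaturated blood in a T1-weighted MPRAGE acquisition is
markedly brighter than stationary tissue, so a routine anatomical scan doubles
as a crude MR angiogram. `hippovessel` turns that contrast into per-subject
measurements of the arterial supply of the hippocampus — vessel volume
(voxel counts), inflow-weighted signal intensity (a velocity proxy), and
left–right lateralization — and then asks, across a cohort, whether those
vascular features statistically mediate associations between systemic
physiology (blood pressure, heart-rate variability, inflammatory markers, and
so on) and hippocampal volume.

The package has two halves:

1. an **imaging pipeline**: intensity normalization, a 3D Haar-transform
   coefficient amplification, multiscale Frangi vesselness, thresholding with
   anatomical exclusion, and hippocampus-connected component selection;
2. a **statistical engine**: a two-equation mediation (path) model with
   percentile-bootstrap inference and a grid runner covering
   23 systemic variables × 3 hemisphere pairings × 2 vessel metrics =
   138 models.

Because no imaging data ship with the package, a synthetic-data module
generates (i) 3D phantoms with known vessel geometry and (ii) cohort tables
with known path coefficients, so every stage is exercised end to end with
ground truth.

## The enhancement stage

For every voxel, a reference cube of 7×7×7 voxels is grouped with the 7
companion cubes whose centers sit at offsets {0,1}³ — the 2×2×2 corner of the
surrounding 3×3×3 cube neighborhood. For each of the 343 intra-cube positions,
the 8 samples across cubes form a vector that is transformed with the
orthonormal 8-point Haar matrix. The 7 detail coefficients `C_H` pass through
a piecewise gain,

* `|C_H| > α₁` — kept unchanged (strong structure),
* `α₂ ≤ |C_H| ≤ α₁` — multiplied by `γ₁` (weak structure),
* `β ≤ |C_H| < α₂` — multiplied by `γ₂` (near the noise floor),
* `|C_H| < β` — set to zero (noise),

with the published operating point α₁ = 60, α₂ = 30, β = 10, γ₁ = 40,
γ₂ = 0.5·γ₁, calibrated for intensities normalized to [0, 255]. The DC
coefficient is never amplified: amplifying it would rescale tissue background
wholesale and destroy anatomy, whereas leaving it intact makes a constant
volume a fixed point of the whole stage (a property the tests assert). After
the inverse transform, the reference-cube contribution is accumulated and
overlapping contributions are averaged; volume borders are handled by
reflection padding so the output grid equals the input grid.

Three choices here were genuinely open and are worth recording:

* **Which 8 of the 27 neighboring cubes.** Any 8-of-27 selection admits an
  8-point transform; we use the {0,1}³ corner because it makes the cross-cube
  difference structure symmetric at single-voxel offsets and yields exactly
  eight cubes without arbitrary omissions.
* **Boundary ties.** The printed bands overlap at α₂ and β. We assign
  `|C_H| = α₂` to the stronger γ₁ band and zero only strictly below β —
  deterministic, and it favors retaining signal.
* **Magnitude thresholding.** The gain is a function of `|C_H|` and preserves
  sign; thresholding the floor of a signed coefficient would make the rule
  asymmetric between bright-over-dark and dark-over-bright edges for no
  physical reason.

A consequence users should understand: on a normalized two-level image, a
*high-contrast* structure produces details above α₁ and passes through
unchanged — the stage amplifies *faint* structure (sub-voxel vessels,
partial-volume margins) and deletes sub-β noise. Its value is greatest exactly
where small vessels live.

## Vesselness

The enhanced volume is filtered with the standard multiscale Hessian
vesselness for bright tubes: at each scale σ the Gaussian-derivative Hessian
is computed (σ²-normalized; separable moment-corrected kernels so polynomial
inputs give exact derivatives), its eigenvalues are ordered
|λ₁| ≤ |λ₂| ≤ |λ₃| with an analytic closed-form solver (verified against
LAPACK in the tests), and

V = (1 − exp(−R_A²/2α_f²)) · exp(−R_B²/2β_f²) · (1 − exp(−S²/2c²)),

with R_A = |λ₂|/|λ₃|, R_B = |λ₁|/√|λ₂λ₃|, S = √(λ₁²+λ₂²+λ₃²), and V = 0
whenever λ₂ ≥ 0 or λ₃ ≥ 0 (bright-vessel polarity). The final map is the
voxelwise maximum over scales, with the argmax scale kept as a side output.

Parameters: α_f = β_f = 0.5 (the filter's classical recommendation) and
c = half the maximum Hessian Frobenius norm per scale. Scales default to
{0.5, 0.75, 1.0, 1.5} mm, bracketing vessel radii of roughly one to three
voxels at 0.75 mm isotropic resolution; σ is specified in millimetres and
converted per axis, so anisotropic grids are handled consistently.

One honest limitation follows directly from the closed form: an ideal bright
sphere has R_B = 1 and is suppressed by the factor e^{−1/(2β_f²)} = e^{−2}
relative to an ideal tube. When both structures also saturate the S-term
(which happens on clean phantoms whenever the largest scale reaches the
sphere), the tube-to-sphere response ratio is pinned at e² ≈ 7.4. Claims of
order-of-magnitude blob suppression are only reachable with a smaller β_f or
when the S-term additionally penalizes the blob; we keep the classical
weights and document the measured ~7.4× separation rather than overstating it.

## From vesselness to hippocampal supply vessels

The vesselness map is thresholded at 5% of its maximum (the map's own scale
is arbitrary, so a max-referenced fraction is the natural reading of a
"greater than 5%" cut; a percentile variant is available in the
configuration). Voxels whose parcellation label belongs to white matter,
cerebellum, temporal, supramarginal or orbitofrontal cortex are removed —
those regions contain bright non-arterial structure that would otherwise
contaminate the mask. Connected components of the survivors
(26-connectivity) that overlap the 1-voxel-dilated hippocampus mask of a
hemisphere are that hemisphere's supply-vessel tree; components touching
neither hippocampus are dropped. A component in contact with both hippocampi
goes to the side with more contact voxels; an exact tie assigns it to both
and flags the component id for QC review.

Metrics follow directly: voxel count and count × voxel-volume (mm³) per side;
mean WM-normalized signal intensity over each side's mask, where the T1w
volume is first divided by the mean intensity inside a caller-supplied pure
white-matter mask (making the WM mean exactly 1 and the SI dimensionless and
scale-invariant); and lateralization indices LI = (right − left)/(right +
left) for volume and SI, bounded in [−1, 1]. An empty vessel mask yields a
missing SI, never zero, so downstream statistics treat it as missing data.

## The mediation engine

Each model is a saturated recursive path model estimated by two least-squares
equations: the mediator equation M ~ X + covariates gives `a`; the outcome
equation Y ~ X + M + covariates gives `b` and the direct effect `c′`. The
indirect effect is `a·b` and the total effect decomposes exactly as
`c = c′ + a·b` — per fit and per bootstrap replicate, which the tests assert
at 1e-10. Estimates are unstandardized. Covariates (age, sex, intracranial
volume by default) enter *both* equations; adjusting only one equation would
leave the mediator–outcome path confounded by head size, and both-equation
adjustment is the convention of the SEM frameworks this analysis mirrors.
Missing data are handled by listwise deletion per model, with the
complete-case count reported alongside every fit. Fasting insulin and IL-6
are log(1 + x)-transformed by default (both are skewed concentrations,
bounded below by zero).

Inference is by case-resampling bootstrap: subjects are drawn with
replacement, both equations are refit jointly per resample, and the 2.5th and
97.5th percentiles of each effect's draws form the 95% interval (percentile,
not BCa — matching the interval definition this analysis replicates). An
effect is significant when zero lies outside its interval. Resamples with a
singular design are rejected and redrawn; if more than 1% of draws degenerate
the run aborts with a reliability error rather than returning fragile
intervals. The generator is Mersenne-Twister with inversion normals and
rejection sampling, set locally (global RNG state is saved and restored), so
a seed pins every interval bit-for-bit across runs and platforms.

The grid runner crosses the 23 systemic variables with the three hemisphere
pairings (mediator and outcome always on the same side, totals with totals)
and the two mediator metrics, fits and bootstraps each of the 138 models with
a per-model seed derived deterministically from the master seed and the model
index, and re-tests every significant row at a higher iteration count
(50,000 by default) — both passes are retained in the results table. No
multiple-testing correction is applied across the grid by default, mirroring
the analysis being replicated; applying one is a caller decision on the tidy
results table (one `p.adjust`-style call away). Failed models become rows
flagged `failed`, never silent omissions.

## What the synthetic data emulate — and what they do not

**Phantoms.** The default phantom is a 48³ grid at 0.75 mm isotropic with two
hippocampus ellipsoids (aseg codes 17/53), a cerebral-WM slab (2/41), a
cerebellum-tagged slab (47), two curved supply tubes of radius 2.5 voxels
(~1.9 mm — the caliber of the arterial trunks feeding the hippocampus)
terminating at each hippocampus, and one distractor tube far from both.
Vessels are rendered at 1.6× the WM mean — the empirical inflow contrast of
hippocampal supply vessels at this field strength — with sub-voxel Gaussian
edge blur (σ = 0.25 voxel) for partial-volume margins; the lumen keeps the
exact vessel intensity, so the truth masks and the rendered image agree by
construction. Noise is white Gaussian with σ set from an SNR of 20, defined
as the vessel-over-WM contrast (90 intensity units at the defaults) over σ,
i.e. σ = 4.5; this keeps the noise floor below the enhancement's β threshold
on the normalized scale, which is the regime the published thresholds are
designed for. Hippocampal gray matter is rendered isointense with the
surrounding parenchyma: the parcellation, not image contrast, delineates it
in the real pipeline, and a synthetic GM step edge would otherwise land in
the amplification band and weld a spurious bright shell onto the
hippocampus-connected component — an artifact of phantom construction, not a
property of real data.

These defaults were fixed by a one-time calibration so that the full pipeline
recovers each tube at Dice ≈ 0.86 — away from the ceiling, leaving headroom
for regression detection. Two earlier candidate settings were rejected for
cause: a one-voxel edge blur makes the rendered vessel physically wider than
its own truth mask (the "truth" then mislabels the object), and defining SNR
against the background tissue contrast puts the noise floor at the β
threshold, outside the method's design envelope.

What phantoms do **not** emulate: flow physics (contrast is imposed, not
simulated from spin history), bias fields, anatomy-conforming vessel
tortuosity, or the real parcellation's irregular geometry. Passing the
phantom suite therefore demonstrates the pipeline's correctness and its
noise/geometry robustness at matched contrast — not clinical accuracy on real
7 T data.

**Cohorts.** Subject tables draw age uniform on 30–59 years, sex Bernoulli
(115/191 female, coded 1), and ICV normal (1.5 × 10⁶ ± 1.5 × 10⁵ mm³),
emulating a midlife community cohort of n = 191. Hemisphere-specific imaging
columns center on the reported group means (hippocampal volume 3730/3620 mm³,
vessel volume 224/190 mm³, vessel SI 1.64/1.61), which builds a small
rightward asymmetry into every simulated cohort. The designated X → M → Y
triple follows the linear path model with user-set coefficients (defaults
a = 0.5, b = 0.4, c′ = 0.1, unit noise — the calibration point used
throughout the test suite); all other columns are drawn without structural
relation to the target. Systemic variables are standard normal except insulin
and IL-6, which are log-normal so the log1p precondition holds by
construction; cross-variable correlation is available (`rho_x`) but defaults
to 0 to keep null-calibration tests interpretable. Generated tables carry
their truth in an attribute, enabling closed-loop recovery tests: across 200
cohorts the mean indirect estimate sits within ±0.02 of 0.20, 95% interval
coverage lands in the low-to-mid 90s, and the null (a = 0) significance rate
stays near 5%.

## Numerical choices and degenerate inputs

* Intensity normalization is affine min→0, max→255; a constant volume raises
  a degenerate-range error rather than dividing by zero.
* Reflection padding uses the edge-excluding convention (no doubled edge
  sample); enhancement output is cropped back to the input grid and every
  retained voxel averages exactly 343 overlapping cube estimates.
* Gaussian-derivative kernels are truncated at 4σ (minimum radius 2) and
  moment-corrected, so the Hessian of a sampled quadratic is exact in the
  interior.
* The eigenvalue solver falls back to the triple root λ = tr/3 when the
  deviatoric norm underflows; ties in |λ| ordering are resolved by a fixed
  swap network, so results are deterministic.
* `c_f = 0` (a structureless volume) is guarded; the vesselness is zero there
  regardless.
* LI with right = left = 0 is returned as missing, matching the treatment of
  empty vessel masks.
* Bootstrap intervals use type-7 quantiles (R's default); with 5,000 draws
  the 2.5th/97.5th percentiles are interpolated, which is the convention the
  interval definition implies.
* Tests and the acceptance script run the simulation studies at 100–200
  cohorts with 1,000 bootstrap iterations — the package's chosen sizes for
  its own calibration experiments; the user-facing defaults remain 5,000
  (first pass) and 50,000 (confirmation).

## Known limitations

* The enhancement amplifies *any* faint coherent structure, including
  partial-volume margins of tissue interfaces; on real data the anatomical
  exclusion list (and, in the original workflow, visual inspection) is what
  keeps such structure out of the vessel masks. The package exposes the QC
  overlay and tie flags for exactly that review step.
* Vessel masks recovered from the pipeline are systematically ~half a voxel
  wider than the true lumen, because the amplified partial-volume margin is
  genuinely part of the detected object. Vessel *volumes* are therefore
  upper-bound estimates; SI means dilute toward tissue intensity as the
  margin fraction grows.
* The blob–tube separation is bounded near e² with the classical Frangi
  weights (see above).
* The mediation engine fits complete cases per model; under data missing not
  at random, per-model samples differ and effects are not strictly
  comparable across rows (the `n_used` column makes this visible).
* Lateralization inference uses a sign-flip permutation test of the mean LI —
  distribution-free and consistent with the bootstrap spirit of the rest of
  the analysis; a t-test option exists for users who prefer the classical
  route.
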