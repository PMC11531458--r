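---
title: "Quantifying pulmonary edema from CT voxel densitometry: models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulmonary edema from CT voxel densitometry: models and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edemaquant)
```

## The problem

In acute respiratory distress syndrome (ARDS) the lungs accumulate
extravascular water — pulmonary edema — and the amount of edema carries
prognostic and therapeutic weight. Two bedside-compatible ways of measuring
it are in routine reach: quantitative analysis of a chest CT scan, and
transpulmonary thermodilution (TPTD), which estimates the extravascular lung
water index (EVLWI, ml per kg of ideal body weight) from a cold-bolus
indicator curve. `edemaquant` implements both estimators and the
method-comparison statistics needed to ask whether they agree.

## The CT densitometry model

CT expresses each voxel's attenuation in Hounsfield units (HU): air is
−1000 HU, water 0 HU. Over the physiological range the tissue (non-gas)
fraction of a voxel is, to a good approximation, linear in HU, which gives
the classical gravimetric estimate

$$\text{voxel tissue weight (g)} = \left(1 - \frac{\text{HU}}{-1000}\right)
  \times \text{voxel volume (ml)},$$

i.e. a tissue fraction of $1 + \text{HU}/1000$ at a tissue density of
1 g/ml. Summed over a binary lung mask this yields the **calculated lung
weight**; by linearity the sum equals the mean-HU shortcut
$(1 - \overline{\text{HU}}/(-1000)) \times \text{lung volume}$, and the
package asserts that identity on random inputs. The healthy reference is the
**expected lung weight** from the height-only linear model

$$\text{expected lung weight (g)} = -1806.1 + 1633.7 \times \text{height (m)},$$

and CT edema is the excess, `PE (ml) = calculated − expected`, taking 1 g of
lung fluid as 1 ml of edema. The percentage form divides the excess by the
expected weight. The height model has a positive root at 1.1055 m;
`expected_lung_weight()` refuses heights at or below 1.106 m, where the
linear extrapolation is meaningless.

### Contrast correction via an HU window

Intravenous contrast agent raises voxel HU above what tissue-plus-water
alone would produce, inflating the calculated weight. The corrected analysis
restricts the sums to voxels in the **edema window [−700, 200] HU**: voxels
above 200 HU are treated as contrast, voxels below −700 HU as predominantly
gas. `quantify_lung()` reports the windowed analysis alongside per-window
voxel accounting (`n_excluded_above`, `n_excluded_below`).

Two reporting conventions exist for the *lung volume* under a window: the
in-window voxel count times the voxel volume (the restricted volume,
consistent with the restricted sums), or the full-mask volume. The package
reports the restricted volume as `lung_volume` and always carries the
full-mask value as `lung_volume_unrestricted`, so either convention can be
recovered. Out-of-window voxels are dropped, not reassigned a substitute
density — reassignment rules are scanner- and protocol-specific and no
defensible default exists.

Other numerical choices: the mean HU uses **all** mask voxels (no attempt to
excise airways or vessels — a binary segmentation output is taken at face
value); voxels are fully in or out of the mask (no partial-volume weighting
at the boundary); HU are clamped at ingest to the 12-bit scanner range
[−1024, 3071] (configurable), which also guarantees nonnegative voxel
weights; the aerated volume is
$\sum \mathrm{clamp}(-\text{HU}/1000,\,0,\,1)\times v$, the clamp keeping the
gas content of contrast or hyperdense voxels at zero rather than negative;
and the voxel volume is taken as the header spacing product — if a scan was
reconstructed with overlapping slices the caller must resample first, since
the package deliberately does no resampling or registration.

## The thermodilution model

EVLWI measures *all* extravascular lung water, part of which is
physiological. The package counts everything above a threshold of 7 ml/kg of
ideal body weight (IBW) as edema:

$$\text{PE}_{\text{TPTD}} \text{ (ml)} = (\text{EVLWI} - 7) \times \text{IBW}.$$

(The physiological threshold is an argument, `threshold = 7`; reported
physiological ranges extend down to about 4 ml/kg, and a patient-specific
value would shift every estimate by `(7 − t) × IBW`.) Sub-physiological
EVLWI gives a negative estimate, preserved and flagged rather than
truncated. IBW uses the Devine formula
(male $50 + 0.91(\text{height}_{cm} - 152.4)$ kg, female intercept 45.5 kg);
the ARDSNet predicted body weight — the same coefficients expressed per inch
— is available via `ibw_formula = "ardsnet"`. Which formula a given clinical
dataset used is rarely recorded, and the choice moves
$\text{PE}_{\text{TPTD}}$ by a few percent.

CT and TPTD are not acquired simultaneously. `pair_measurements()` keeps one
pair per patient — the *first* CT scan, to avoid repeated measures — and
requires the CT-to-TPTD gap to be at most 24 h (configurable), on the
physiological argument that EVLWI rarely changes rapidly on that scale.

## Agreement statistics

`bland_altman()` computes the bias (mean of paired differences), the sample
SD of the differences, and limits of agreement (LoA) at bias ± 1.96 SD. The
multiplier is fixed at 1.96 rather than a t-quantile — the convention of the
agreement literature — but is an argument for small-n use. Normal-theory
confidence intervals use $SE(\text{bias}) = s/\sqrt{n}$ and
$SE(\text{LoA}) = s\sqrt{1/n + 1.96^2/(2(n-1))}$. The difference orientation
is the caller's: the pipeline convention is **thermodilution minus CT**, and
the orientation is recorded in every report, since sign conventions vary
between tools.

`spearman_rho()` (average ranks, asymptotic two-sided p),
`paired_location_test()` (paired t or Wilcoxon signed-rank; a t test on
zero-variance differences is refused as degenerate), `overlap_indices()`
(Jaccard and Dice, with the identity $D = 2J/(1+J)$ asserted on every call;
two empty masks are defined as overlap 1 with a warning) and
`summarize_grades()` (three-point segmentation-quality tallies with exact
fractions retained alongside integer display percentages) complete the
module.

### Power of an agreement study

`bland_altman_power()` estimates, by simulation, the probability that both
estimated LoA — including their 95% confidence bounds — fall within a
clinically acceptable ± maximum difference, for differences drawn
$N(\text{bias}, \text{SD})$. Published agreement-study power methods differ
in whether the confidence bounds are included; this package includes them
(the stricter reading), documents the procedure fully, and makes it
seed-deterministic. With planning inputs of bias 30 ml, SD 290 ml and an
acceptability limit of ±700 ml, this stricter criterion yields a power near
0.68 at n = 145 (see `analysis/03_power_grades_overlap.R`); a criterion that
tests only the LoA point estimates would report substantially higher power,
so comparisons across tools must match criteria before comparing numbers.

## The synthetic phantom: validation with an exact inverse

No public CT + thermodilution dataset accompanies this problem, so the
package ships a generator whose ground truth is exact. `generate_phantom()`
builds a per-voxel tissue-fraction field $f \in [0,1]$ (two ellipsoidal
lungs in a soft-tissue body) and maps it to HU by

$$\text{HU} = -1000\,(1 - f),$$

which is *exactly* the inverse of the voxel-weight formula. On a noise-free
phantom the calculated lung weight therefore equals the analytic tissue mass
to floating-point precision — the package's strongest end-to-end check
(relative error < 10⁻⁹ asserted; observed ≈ 10⁻¹⁶). The field supports a
linear gravitational aeration ramp along a chosen axis (a qualitative stand-in
for dependent-region consolidation, clipped to [0,1]; no physiological model
claimed), spherical consolidations, contrast blobs (> 200 HU, set exactly so
contrast arithmetic is checkable to machine precision), and additive
Gaussian HU noise. Zero-mean noise leaves the weight unbiased with an error
scaling as $1/\sqrt{N_{\text{voxels}}}$, which the tests verify across seeds.

What the phantom does **not** emulate: airway trees, vessels, lobar anatomy,
beam hardening, reconstruction kernels, or segmentation error. Passing
phantom tests therefore validates the *arithmetic* of the pipeline, not the
segmentation or scanner physics of real data.

## The synthetic cohort

`generate_cohort()` draws a method-comparison cohort with the statistical
structure the analysis assumes. Defaults, fixed once as the package's study
conditions: n = 145; height $N(173, 10^2)$ cm truncated above 120 cm; weight
$N(90, 26^2)$ kg truncated above 30 kg; 33% female; true edema lognormal
with median 508 ml and quartiles ≈ 305/814 ml (meanlog $\log 508$, sdlog
$\log(814/508)/z_{0.75}$); a TPTD-minus-CT disagreement of mean −104 ml and
SD $1040/1.96 \approx 530.6$ ml, split symmetrically between the two
observations around the shared truth; and a CT-to-TPTD gap $|N(4.8, 5.4)|$ h.
EVLWI is back-derived from the TPTD-side edema through the Devine IBW, so
the thermodilution stage of the pipeline reproduces the generated values
exactly (rows where the back-derivation would need negative EVLWI are
clamped at 0 and flagged). All randomness flows from one explicit seed per
call, with the caller's RNG state restored afterwards.

Downstream, `bland_altman()` recovers the injected bias and SD within
sampling error (asserted across 100 seeds at 3 standard errors), which
validates the estimator, not the clinical claim: agreement numbers from a
simulated cohort inherit the generator's assumptions (normal disagreement
independent of edema magnitude, no proportional bias, no outliers).

## Problem sizes

The validation suite uses phantoms of up to 64³ voxels, 20–50 phantoms per
property, cohorts of 145–600 patients, 100 seeds for recovery checks, 1000
fuzz cases for the rank-correlation and overlap oracles, and 2000–5000
Monte-Carlo replicates for power estimates; these sizes make every
distributional check decisive at 3–4 standard errors while keeping the whole
suite in the tens of seconds.

## Known limitations

* Masks are inputs: the package neither runs nor approximates an AI lung
  segmentation; Jaccard/Dice compare two supplied masks.
* No DICOM ingestion; volumes and masks are NIfTI-1 on a shared grid, and
  grids are checked (shape, spacing within 10⁻³ mm) but never resampled.
* The thermodilution side takes EVLWI as a measurement; thermodilution
  physics (GEDV, PVPI, indicator recirculation) is out of scope.
* The expected-lung-weight model is height-only; its residual SD in real
  cohorts (~160 g) is an irreducible noise floor for CT edema estimates.
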