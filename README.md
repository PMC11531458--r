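# edemaquant

Quantification of pulmonary edema in ARDS lungs from chest CT voxel
densitometry, and its comparison against transpulmonary thermodilution
(TPTD) — for intensivists, radiologists and methods researchers who need a
tested, scriptable implementation of the classical gravimetric CT analysis
and the agreement statistics that go with it.

## What it computes

Each voxel of a CT scan carries a density in Hounsfield units (HU; air
−1000, water 0). Over a binary lung mask the package computes

```
voxel tissue weight (g)   = (1 − HU / −1000) × voxel volume (ml)
calculated lung weight (g) = Σ voxel tissue weights  =  (1 − meanHU / −1000) × lung volume
expected lung weight (g)  = −1806.1 + 1633.7 × height (m)
PE_CT (ml)                = calculated − expected        (1 g fluid ≡ 1 ml)
```

optionally restricted to the edema HU window **[−700, 200]**, which excludes
contrast-agent voxels (> 200 HU). The thermodilution side counts all
extravascular lung water index (EVLWI) above the physiological 7 ml/kg of
ideal body weight: `PE_TPTD (ml) = (EVLWI − 7) × IBW`. Method agreement is
assessed with Bland–Altman bias and 1.96-SD limits of agreement (LoA),
Spearman correlation, paired location tests, Jaccard/Dice mask overlap, and
a Monte-Carlo power analysis for agreement studies. A synthetic phantom
generator with analytically exact tissue-mass ground truth (HU =
−1000(1 − f)) and a synthetic cohort generator make every stage testable
without patient data.

## Worked example

Generate a noisy phantom with a gravitational aeration gradient and a 400-HU
contrast blob, quantify it with and without the edema window:

```r
library(edemaquant)
ph <- generate_phantom(phantom_spec(
  shape = c(48, 48, 48), spacing = c(1.5, 1.5, 1.5),
  base_tissue_fraction = 0.3, gradient_amplitude = 0.3,
  contrast_blobs = list(list(center = c(15, 24, 24), radius_mm = 4, hu = 400)),
  noise_sd = 20, seed = 42))
quantify_lung(ph$volume, ph$truth$mask)
#> Lung quantification (all masked voxels)
#>   lung volume            64.5 ml (19112 voxels; full mask 64.5 ml)
#>   mean HU              -695.4
#>   calculated weight      19.6 g
#>   aerated volume         45.0 ml
#>   tissue volume          19.6 ml
quantify_lung(ph$volume, ph$truth$mask, edema_window())
#> Lung quantification (HU window [-700, 200]; 81 voxels excluded above, 9496 below)
#>   lung volume            32.2 ml (9535 voxels; full mask 64.5 ml)
#>   ...
#>   calculated weight      11.1 g
ph$truth$true_tissue_mass
#> [1] 19.33097
```

The uncorrected weight (19.6 g) overshoots the exact tissue mass (19.3 g) by
the contrast blob's excess; the windowed pass excludes those 81 voxels (and
the 9496 near-air voxels below −700 HU). At patient scale, with a
cohort-typical calculated weight of 1681 g and a 1.73-m patient:

```r
edema_from_ct(1681, expected_lung_weight(1.73), "auto")
#> Pulmonary edema (auto): 660.8 ml (excess weight 64.8%)
edema_from_tptd(14, 1.73, "male")
#>   evlwi    ibw physiological_lung_water pe_tptd sub_physiological
#> 1    14 68.746                  481.222 481.222             FALSE
```

i.e. this patient carries ~661 ml of excess lung weight by CT and ~481 ml of
pathological lung water by thermodilution. Agreement between two edema
series (here 10 made-up pairs, TPTD minus CT):

```r
bland_altman(c(520, -40, 300, 105, -210, 880, 35, -415, 640, 150),
             c(610, 75, 160, 420, -95, 1010, 240, -300, 505, 95))
#> Bland-Altman agreement (n = 10, differences x - y)
#>   bias      -75.5  [-179.4, 28.4] 95% CI
#>   LoA      -360.1  [-544.0, -176.2]
#>             209.1  [25.2, 393.0]   (bias +/- 1.96 x SD, SD = 145.2)
```

The full workflow — synthetic cohort → TPTD edema → 24-h CT/TPTD pairing →
Bland–Altman + Spearman → summary table — is one call:
`run_pipeline(run_config(cohort = cohort_spec(n = 145, seed = 1)))`. The
numbered scripts under `analysis/` are narrative drivers for the three main
analyses (phantom validation, cohort agreement, power/grading/overlap) and
write their tables under `results/`.

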