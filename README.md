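# seedmsi

Automated analysis of multispectral seed imaging (MSI) for wheat seed lots.

Seed-lot imagers photograph 60–80 seeds per frame on a blue conveyor belt,
acquiring co-registered reflectance images at 19 wavelengths (375–970 nm)
plus an sRGB companion. `seedmsi` turns such frames into per-seed phenotype
tables for seed-quality research and downstream genetic mapping (GWAS):

* **Pre-processing** — detection of overexposed (saturated dark-red) seed
  regions on the CIE L\*a\*b\* a\* channel with local adaptive thresholding,
  their calibration from properly exposed pixels of the same seed, and
  removal of the blue belt background on the 780 nm band.
* **Segmentation** — one label per seed: watershed on the Euclidean distance
  transform, edge smoothing via closing-residue skeletons, splitting of
  still-touching seeds along convexity defects with Harris-corner anchored
  cut lines, ellipse-model refinement of contact boundaries, and merging of
  over-segmented fragments.
* **Traits** — per seed: area, convex area, length, width, perimeter,
  length/width ratio (LWR), eccentricity `sqrt(1 − (w/l)²)`, roundness
  `4πA/P²` (all in mm via a user calibration), plus mean reflectance for all
  19 bands; the eight substance-associated bands (375 nm crude protein …
  970 nm water) are tagged for export.
* **Validation statistics** — object-matched mean intersection-over-union
  (mIoU), Pearson agreement with single-pass |z| > 3 outlier removal
  (r², p, RMSE), Lilliefors/KS normality testing, and broad-sense
  heritability `H² = σ²g / (σ²g + σ²e)` from one-way variance components.
* **Synthetic renderer** — seed lots as rotated, perturbed ellipses with
  exact ground-truth masks and analytically computed trait tables, so the
  whole pipeline is testable without instrument data.
* **Phenotype export** — per-genotype trait means in the whitespace
  `FID IID value` dialect consumed by GCTA/PLINK.

Inputs are multiband TIFF stacks (or directories of per-band images named
`<wavelength>nm.tif`) and PNG/TIFF sRGB companions; the vendor's proprietary
container format is out of scope.

## Worked example

Render a 70-seed lot, segment it, and measure traits:

```r
library(seedmsi)

spec <- scene_spec(n_seeds = 70, rng_seed = 42)   # 1096 px, 30% touching pairs
scn  <- render_lot(spec)
scn$stack
#> <msi_stack> lot 'synthetic_lot_seed42': 1096 x 1096 px, 19 bands (375-970 nm)

mask <- segment_lot(scn$stack, scn$rgb, verbose = FALSE)
mask
#> <labeled_mask> 1096 x 1096 px, 70 seeds

mean_iou(mask, scn$truth$mask)$miou
#> [1] 0.9968

lot <- measure_lot(scn$stack, mask, scale_calibration(0.08),
                   valid_pixels = attr(mask, "valid_pixels"))
subset(lot$summary, trait %in% c("area_mm2", "length_mm", "width_mm", "lwr", "refl_780"))
#>      trait   mean     sd   min   max  n
#>   area_mm2 14.380 2.3955 8.653 21.47 70
#>  length_mm  6.081 0.7190 4.187  7.42 70
#>   width_mm  3.010 0.3034 2.393  3.91 70
#>        lwr  2.037 0.2967 1.309  2.72 70
#>   refl_780  0.398 0.0251 0.341  0.46 70
```

All 70 seeds are recovered (the scene contains 70), the matched-object mIoU
against the rendered ground truth is 0.997, and the lot summary shows
realistic wheat morphology: ~6 mm long, ~3 mm wide, LWR ≈ 2. Comparing
automated against ground-truth seed length:

```r
m <- mean_iou(mask, scn$truth$mask)$matches
agreement(lot$records$length_mm[match(m$pred, lot$records$seed_id)],
          scn$truth$traits$length_mm[match(m$truth, scn$truth$traits$seed_id)])
#> agreement: R^2 = 0.9947 (r = 0.9973), p = 1.25e-75, RMSE = 0.05465, n = 67
#>   (3 outliers removed; |standardized residual| > 3 (single pass))
```

A command-line wrapper over the same functions is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/seedmsi.R", package = "seedmsi"))')" \
    simulate --seed 42 --out lot/
# then: segment --stack lot/stack.tif --rgb lot/rgb.png --out lot/mask.tif
#       traits --stack lot/stack.tif --mask lot/mask.tif --scale-mm-per-px 0.08 --out lot/traits.csv
#       validate --pred lot/mask.tif --truth lot/truth_mask.tif
#       export-pheno --traits lot/traits.csv --trait length_mm --out lot/pheno.txt
```

All parameters of every stage can be set from a YAML config
(`run_config()`); each run writes its fully resolved configuration next to
its outputs.

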