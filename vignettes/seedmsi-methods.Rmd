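---
title: "Methods: automated multispectral seed-lot analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated multispectral seed-lot analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Multispectral seed imaging (MSI) instruments photograph a lot of 60-80 wheat
seeds lying on a blue conveyor belt, recording co-registered grayscale
reflectance images at 19 wavelengths from 375 nm (UV) to 970 nm (NIR) plus an
sRGB companion image, at roughly 2192 x 2192 px. Eight of the bands have
reported associations with seed constituents (375 nm crude protein, 450 nm
carotenoids, 525 nm amylopectin, 630 nm amylose, 645/660 nm chlorophylls B/A,
940 nm fat, 970 nm water; see `band_substance_map()`). Turning such frames
into per-seed phenotypes requires three non-trivial steps, which this package
implements: repairing overexposed (saturated dark-red) seed regions,
separating seeds that touch or overlap in the frame, and measuring
morphological and spectral traits per segmented seed. A synthetic renderer
with exact ground truth makes every stage testable without the instrument.

Internally all reflectance is kept on the dimensionless [0, 1] scale (integer
images are divided by their dtype maximum on read); percent scales are a
presentation concern only. Pixel coordinates are (row, col) and all object
connectivity is 8-connected, consistently across labeling, distance
transforms and contour tracing.

## Pre-processing

**Overexposure detection** works on the a\* channel of CIE L\*a\*b\*
(standard sRGB transfer, D65 white point): saturated seed cores render as
dark red, i.e. strongly positive a\*, while healthy seed coat and the blue
belt stay low. The default detector is locally adaptive — a pixel is flagged
when its a\* exceeds the local box mean (window 51 px) by 10 a\* units — with
a fixed-threshold mode (a\* > 45) available. Flagged regions smaller than
5 px are discarded as sensor speckle.

**Calibration** replaces each flagged pixel by the per-channel *median* of
the properly exposed pixels of the *same* seed object, plus zero-mean
Gaussian jitter whose sd equals that object's properly-exposed channel sd
capped at 0.02, so repaired regions are not artificially flat. The median is
used because residual partial saturation skews means. Only the sRGB image is
calibrated; the spectral bands under flagged pixels are instead *excluded*
from per-seed band means through a validity mask, which avoids inventing
reflectance values.

**Background removal** thresholds the 780 nm band, where seeds are bright
(~0.40) and the blue belt is dark (~0.05), with a local box mean (window
201 px) plus an offset of 0.02 reflectance. The offset matters: at exactly 0,
belt-only neighbourhoods have their threshold equal to the local mean, so
roughly half of all belt pixels would be flagged by noise alone and
8-connected noise percolates past any small-object filter. 0.02 equals two
sd of typical sensor noise and leaves genuine seed-belt contrast (~0.35)
untouched. Holes are filled and objects under 50 px removed. A reference band
whose global sd is below 1e-6 yields an empty mask rather than thresholded
noise.

## Segmentation

`segment_lot()` chains four stages; all parameters live in
`segmentation_params()` and the YAML config.

1. **Watershed refinement.** The Euclidean distance transform of the
   foreground is flooded by the watershed transform. Markers are
   distance-map maxima detected within an 11 px footprint; maxima whose
   basin depth is below `watershed_tolerance = 1` px are suppressed
   (h-maxima), and adjacent regions whose peaks sit closer than
   `peak_min_distance_px = 15` are merged, enforcing a minimum marker
   separation. Components under `min_seed_area_px = 200` are dropped. We
   deliberately flood the distance map rather than growing Voronoi-style
   regions from markers: region-growing on the inverted distance map
   misplaces the boundary between touching seeds by many pixels, while the
   flooding watershed places it on the distance-map ridge, i.e. the
   geometric waist.

2. **Edge smoothing.** Jagged boundary indentations bias perimeter and
   roundness. For each object we form the closing residue (object XOR its
   morphological closing with a 5 px disc), skeletonize the residue
   (Zhang-Suen), connect skeleton endpoints of each residue region with
   straight chords, and fill the enclosed slivers into the object. Residues
   under 5 px are ignored (digitization artifacts of convex shapes), repairs
   are reverted if they would change the object's area by more than 5%, and
   repaired pixels never overwrite neighbouring labels, so the object count
   is invariant.

3. **Splitting still-touching seeds.** An object is treated as a touching
   clump when its solidity (area / convex-hull area) is below 0.92 *and* its
   area exceeds 1.35x the lot median: single wheat grains are nearly convex,
   while doubles are both large and non-convex. (A factor of 1.6 would miss
   pairs of below-median seeds, which merge to only ~1.5x the median.) For
   each clump we locate convexity defects deeper than 4 px; within each
   defect the cut anchor is the contour pixel of maximal Harris-Stephens
   corner response (computed on the contour curve rendered as a binary
   image; window 5 px, k = 0.04) within 10 px of the defect's deepest point.
   Anchors of distinct defects are paired greedily by increasing gap (at
   most 60 px) and the clump is cut along the connecting chord; cuts
   producing parts under `min_seed_area_px` are rejected. Deeply overlapping
   pairs often expose only *one* qualifying defect — the waist indents on
   one side only — so with `single_defect_cut = TRUE` a lone deep defect is
   cut towards the nearest opposite boundary point (contour-index distance
   at least 20% of the contour, so the chord crosses the neck).

   Finally, every contact boundary — created by the watershed or by a cut —
   is refined against an ellipse shape model: each seed's *free* contour
   (pixels more than 3 px from the contact) is fitted with a direct
   least-squares (Fitzgibbon) ellipse, and every pixel of the pair,
   including the 1-px cut line, is assigned to the seed whose fitted ellipse
   it is relatively closest to (smaller normalized elliptical radius), with
   connectivity and minimum-area guards; two fit/reassign iterations are
   run. The free contour of a touching seed is an uncontaminated sample of
   its true outline, so the fit recovers the underlying ellipse almost
   exactly, and since grains are both modeled (renderer) and measured
   (second-moment axes) as ellipses this prior is the internally consistent
   choice. The refinement roughly halves the boundary error at seed
   contacts and is what makes perimeter usable as a per-seed trait for
   touching seeds.

4. **Merging over-segmented fragments.** A fragment is merge-eligible when
   its area is below 0.55x or its moment length below 0.6x the lot median —
   set just above a perfect bisection (0.50x area, ~0.53x length) so that a
   seed split in half can actually be repaired. An eligible fragment merges
   into the neighbour with the longest shared boundary, but only if the
   merged object's solidity is at least the area-weighted mean solidity of
   the parts minus 0.02: merging two *genuine* seeds creates a waist and
   fails this test. The procedure iterates to a fixpoint (at most 10
   rounds); isolated small objects are kept, as they may be genuine small
   seeds or debris for downstream filtering.

Label invariants (contiguous ids, one 8-connected component per label) hold
after every stage, and the whole pipeline is deterministic given inputs and
parameters.

## Trait extraction

Per seed, with `s` the mm-per-pixel scale supplied by the user (from
`estimate_scale()`, e.g. a ruler of known length):

* area = pixel count x s^2; convex area = pixels of the filled convex hull
  x s^2 (rasterized so convex area >= area always holds);
* length/width = major/minor axis of the second-moment best-fit ellipse
  (4 sqrt(eigenvalue)), which is rotation-stable, x s;
* perimeter via the Vossepoel-Smeulders corner-corrected chain estimator
  (0.980 per orthogonal step, 1.406 per diagonal, -0.091 per corner):
  naive chain lengths overestimate a digital circle's perimeter by ~4%,
  biasing the roundness of a true disk to ~0.93, while the corrected
  estimator is within ~0.7%;
* lwr = length/width; eccentricity = sqrt(1 - (width/length)^2);
  roundness = 4 pi area / perimeter^2, capped at 1.05 with a flag
  (`roundness_capped`) for digitization excursions above 1.

Labels under 10 px or with a sub-pixel minor axis are flagged invalid and
excluded from lot summaries. Band means are computed for all 19 bands over
each label's pixels intersected with the validity mask (excluding
calibrated-overexposed pixels); the 8 key bands are a presentation/export
selection, not a computation restriction.

## The synthetic renderer

`render_lot()` emulates the acquisition geometry, not its optics: seeds are
rotated ellipses with smooth low-order radial perturbation bounded at 5% of
the minor axis; touching pairs interpenetrate by 10-25% of the minor axis;
the belt is "blue" (reflectance ~0.45 at 450 nm, ~0.05 at 780 nm) while seed
reflectance rises from 0.08 at 375 nm to 0.55 at 970 nm; per-seed band means
combine a per-seed brightness factor (sd 0.06) with per-band deviations
(sd 0.015); pixels add Gaussian sensor noise (sd 0.01) and are clipped to
[0, 1]. A fraction of seeds (default 10%) receives a saturated dark-red core
in the sRGB companion only. Ground-truth labels are rendered before noise
and saturation; contested pixels of interpenetrating pairs go to the seed
with the smaller normalized radius. Ground-truth *traits* are computed
analytically from each seed's boundary polygon (shoelace area, polygon
second moments, arc length), so the oracle does not share code with the
measurement path.

Default scene scale is 1096 px (half the instrument frame) with
`mm_per_px = 0.08`, giving ~6 mm seeds of ~75 px length — semi-axes drawn
from N(38, 4) x N(19, 2) px, realistic coefficients of variation (~10%) for
a wheat lot. Axes are specified in pixels and should be scaled together with
`image_size_px` for full-scale scenes. What passing tests on these scenes
does *not* show: robustness to illumination gradients, specular glare
physics, crease/germ morphology of real grains, clumps of many seeds, or
belt texture; the renderer is a geometry-and-noise emulation, not a
photorealistic model.

`render_population()` layers a one-way genetic design on top: genotype
effects (variance sigma2_g) and lot residuals (variance sigma2_e) shift the
trait-controlling seed length, returning per-lot scene specifications plus
the true effects for recovery testing.

## Validation statistics

* **mean IoU** matches objects one-to-one by maximal pixel overlap (greedy,
  descending); matched pairs contribute intersection/union, unmatched
  objects contribute 0, and the mean is over max(n_truth, n_pred), so both
  over- and under-segmentation are penalized. Two empty masks define
  mIoU = 1 with a warning.
* **agreement** fits y ~ x by least squares, removes points with
  |standardized residual| > 3 in a single pass (the rule is recorded in the
  result object), and reports Pearson r, r^2, the two-sided p, and the RMSE
  of x - y on retained points. Exact linear relations skip outlier removal
  (residuals are pure roundoff there).
* **ks_normality** is the Lilliefors-corrected one-sample KS test against a
  normal with estimated mean/sd (`nortest::lillie.test`), appropriate when
  the reference parameters are plugged in from the sample.
* **heritability** uses method-of-moments on the one-way ANOVA mean squares
  (sigma2_e = MS_within; sigma2_g = (MS_between - MS_within)/r, truncated at
  0; H^2 = sigma2_g/(sigma2_g + sigma2_e)), with the standard effective
  replicate number for unbalanced designs. For a balanced two-replicate
  design this estimator is exact in expectation and matches the information
  in the data; note that with 200 genotypes x 2 reps the sampling sd of
  H^2-hat is ~0.05 at H^2 = 0.2, an identifiability limit no estimator
  escapes, which is why the recovery property tests assert unbiasedness
  across the variance-ratio grid but a fixed error band only where the
  design supports it.

## Problem sizes and budgets

The test suite and the acceptance script work at desk scale by choice:
20 rendered lots at 1096 px with renderer defaults (~1,400 seeds) for the
benchmark quantities, 400-550 px scenes for unit tests, and pure phenotype
simulation (no rendering) for the heritability checks. These sizes keep a
full run in a few minutes while leaving every mechanism — touching pairs,
saturated cores, noise — represented.

## Known limitations

* The hips container of the instrument vendor is not parsed; inputs are
  multiband TIFF stacks or per-band image directories.
* Seeds are assumed roughly ellipsoidal; the ellipse-prior boundary
  refinement and the touching gates would need retuning for strongly
  non-convex seed species.
* Clumps of three or more seeds are handled by greedy pairwise defect cuts
  and may occasionally under-split; the renderer places pairs only.
* The pixel scale must come from user calibration; no instrument metadata
  is read.
* Reflectance-to-substance relations are metadata tags on bands, not
  calibration models.
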