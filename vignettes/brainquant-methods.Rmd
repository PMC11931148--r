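---
title: "Methods: lesion-aware brain volumetry at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-aware brain volumetry at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainquant)
```

## The problem

Children with unilateral cerebral palsy (uCP) carry focal, non-progressive
brain lesions — FLAIR-hyperintense white-matter injury such as
periventricular leukomalacia, and T1/FLAIR-hypointense cavities — together
with volume loss in the hemisphere contralateral to the clinically affected
body side. Conventional volumetric tools assume near-typical anatomy and
fail on such brains. `brainquant` implements a lesion-aware quantification
pipeline: training labels are synthesized by fusing a lesion-affected and a
lesion-filled segmentation ("silver ground truth"), a pair of small 3D
U-Nets segments structures and lesions, and the clinically reported
quantity is the *lesion-free volume* of each region,

\[ V_{\text{lesion-free}} = V_{\text{total}} - V_{\text{lesion}}, \]

evaluated per region by attributing each lesion voxel to the structural
label beneath it. Hemispheric asymmetry and correlation statistics link
these volumes to lesion-extent scores (sqMRI), motor scores (AHA, MACS) and
vision scores.

Everything is testable without patient data: a seeded phantom generator
produces paired pre-/post-lesion T1+FLAIR images with exact voxel ground
truth, analytic region volumes and a toy atlas.

## Intensity normalization

Two steps, both computed from the image itself:

1. **Percentile clipping** at the 1st and 99th percentiles, removing
   intensity outliers.
2. **Robust z-scoring**: every voxel is mapped to \((x - c)/s\), where the
   center \(c\) is the *median* of voxels strictly above the 10th
   percentile (median preferred over mean for robustness; the floor
   suppresses the background peak) and the spread \(s\) is the standard
   deviation of voxels inside a percentile band.

Two genuinely open readings exist for the spread band ("the 90th percentile
range"): the central 90% of intensities (P5–P95) or everything below P90.
The default is the symmetric central band `spread_range = c(5, 95)`; the
alternative is one parameter away (`normalization_params(spread_range =
c(0, 90))`). Percentiles are always linear interpolation between order
statistics (type 7), fixed so independent oracles agree bitwise. Statistics
are computed over all voxels — no brain mask is assumed; the above-P10
center rule absorbs background dominance.

Because clipping thresholds, center and spread are all percentile-
equivariant, the composed transform is invariant under positive affine
rescaling of the input (`y = a x + b`, `a > 0`) to numerical precision —
this is the property that "minimizes scanner variability", and it is tested
to 1e-6.

## Silver ground-truth fusion

Given a lesion-affected segmentation, a lesion-filled segmentation, the
manual lesion mask and the T1 image, labels are fused voxelwise:

1. outside the dilated lesion mask, keep the lesion-affected label;
2. inside the mask, if T1 falls within the CSF intensity window
   (1st–95th percentile of T1 over CSF voxels of the lesion-affected map),
   label CSF;
3. otherwise take the lesion-filled label, with background falling back to
   CSF (cavity interiors are fluid-like).

Decisions the source description leaves open, made here once and exposed as
parameters: the dilation kernel is 26-connected with radius 1 voxel (the
smallest buffer that absorbs boundary uncertainty); the CSF window test is
inclusive at both ends (percentile bounds are attained values); the CSF
sample is drawn from the whole lesion-affected map, including inside the
mask (the literal reading). The vectorized implementation is tested for
exact per-voxel equality against a three-branch reference loop.

Generating the lesion-filled *image* is out of scope (virtual-grafting
style lesion filling is a separate method); the phantom supplies its
pre-lesion image in that role.

## The phantom's stated world

The phantom is three nested ellipsoid shells (CSF envelope, cortical GM,
cerebral WM) in a 128 mm field of view, with paired deep-grey structures
(thalamus, caudate, putamen, pallidum), cerebellar hemispheres, and a
three-part brainstem (midbrain, pons, medulla). Intensities are Gaussian
per tissue with the contrast orderings the method relies on: T1
CSF < GM < WM; FLAIR CSF < WM < GM, with hyperintense lesions above GM
(mean 115 vs GM 90, SD 3). Lesions are spheres placed by rejection sampling
(at most 1000 tries) wholly inside the target tissue and hemisphere; the
default lesion load is three WM hyperintensities (3–6 mm radius) and one WM
cavity (4–7 mm) in the left hemisphere, emulating a unilateral lesion
pattern. Hemispheric volume loss is modelled by scaling structures of one
side about their centroids (factor *f*, so analytic volumes scale by
*f³*); the default acceptance setting is *f* = 0.8, in the range of the
deep-grey asymmetries reported for this population.

Stock grids: 64³ at 2 mm for fast tests, 128³ at 1 mm for volumetric
acceptance (voxelization error of the smallest structure is ~3–5% at 1 mm,
which sets the 5% recovery tolerance), 32³ at 4 mm for single-patch
training subjects.

What the phantom does *not* emulate: cortical folding, partial-volume
mixtures, bias fields, scanner artifacts, registration error, or realistic
lesion morphology. A green test therefore establishes algorithmic
correctness (the code computes the stated quantities exactly or within the
stated discretization error), not clinical segmentation accuracy on real
MRI.

## Segmentation models

Both models use a small encoder–decoder 3D U-Net: two levels, 8 base
channels, 3×3×3 convolutions with ReLU, 2×2×2 max pooling, nearest-
neighbour upsampling with a skip concatenation, 1×1×1 softmax head. The
structural model maps T1 to tissue classes; the lesion model consumes T1,
FLAIR and the structural tissue map one-hot encoded over {background, CSF,
GM, WM} (one-hot rather than an ordinal id channel avoids fake ordering
artifacts). The loss is a weighted sum of soft Dice (over foreground
classes, \(\varepsilon = 10^{-5}\)) and weighted categorical cross-entropy;
training is plain Adam (1e-3), He initialization, and stops when the
validation loss (5 held-out subjects by default) has not improved for 10
epochs. Argmax ties break to the lowest class id. Training is exactly
reproducible under its seed (single-threaded reference mode).

This is a deliberately desk-scale stand-in for a production network whose
exact depth, width, optimizer and augmentation are not part of the claims
here; `model_config` exposes larger settings. Convolution forward/backward
passes are compiled (im2col + BLAS); a pure-R reference implementation is
kept in the package and the test suite checks the two agree exactly, and
checks backpropagation against numerical gradients.

## Volumetry, hemispheres, asymmetry

Region volumes are voxel counts times the voxel volume
(\(|\det A_{3\times3}|/1000\) mL). Lesion voxels are attributed to the
structural label beneath them, which is what makes the lesion-free
subtraction evaluable per region; conservation
(`lesion_free = total - lesion`, ≤ 1e-9 mL) is asserted on every report the
test suite produces. Bilateral regions are split by the sign of the world
*x* coordinate (RAS; x > 0 is anatomical right); voxels exactly on the
midplane are tagged MIDLINE and counted in neither hemisphere (avoids
double counting). The affected hemisphere is contralateral to the clinical
side.

The relative asymmetry of a region is
\(100\,(V_{\mathrm{aff}} - V_{\mathrm{less}})/\mathrm{mean}(V_{\mathrm{aff}},
V_{\mathrm{less}})\). The normalizer is a genuine design choice — the
source description never defines it — and the symmetric mean form (bounded
in ±200%) is the standard lateralization-index convention; a
less-affected-denominator variant is available via the `denominator`
argument. No published asymmetry value should be compared across
conventions. Cerebellar asymmetry uses anatomical hemispheres (no
motor-pathway crossing).

Atlas postprocessing intersects the WM mask with lobar territories and
PLIC boxes (and the cortical GM mask with lobar territories); voxels
outside every territory keep generic WM/CGM labels, so lobar + PLIC +
generic volumes exactly partition each tissue. The toy atlas splits the
brain bounding box into four equal anterior–posterior slabs per hemisphere
and places each PLIC box between the thalamus and pallidum specs.

## Evaluation

Dice is \(2|A\cap B|/(|A|+|B|)\), with two empty masks scoring 1 and one
empty mask 0. HD95 uses surface voxels (mask voxels with a 6-connected
background neighbour; the array boundary counts as background), Euclidean
distances scaled by the voxel spacing, the 95th percentile (linear
interpolation) of each directed distance distribution, symmetrized by the
maximum — the most common benchmark convention; the directed variants are
one argument away (`percentile`, and the two directed values are what the
maximum is taken over). Benchmark tables group regions as CSF, GM, WM,
deep GM (thalamus + putamen + caudate + pallidum), brainstem (midbrain +
pons + medulla) and cerebellum.

The qualitative protocol is a deterministic classifier: defect fractions
≤ 10% are minor, ≤ 25% intermediate, above that major (band edges resolved
closed-left/closed-right; the informal "~" in the source band is ignored
for determinism); one major or more than three intermediate defects reject
a segmentation, any intermediate or more than three minor defects approve
it with remarks, otherwise it is approved.

## Statistics

* **Spearman** is Pearson on mid-ranks; undefined under zero rank variance.
  Tabulated p-values use the t approximation; the primary uncertainty
  object is the bootstrap CI.
* **Bootstrap CIs** resample subject rows with replacement (percentile
  method, default 10,000 resamples, seeded). Coverage for the Spearman
  estimand of a bivariate normal (population Spearman
  \(6/\pi \cdot \arcsin(\rho/2)\)) is checked empirically in the
  acceptance suite.
* **Mann–Whitney U** uses \(U_x = \#\{x < y\} + \tfrac12\#\{x = y\}\) and
  reports \(U = \min(U_x, U_y)\). For \(n_x + n_y \le 12\) without ties the
  two-sided p is exact from the dynamic-programming null distribution
  (checked against exhaustive enumeration of all labelings); otherwise a
  tie-corrected normal approximation with continuity correction. The
  threshold bounds enumeration cost and is documented, not tuned.
* **Wilcoxon signed-rank** drops zero differences, mid-ranks the absolute
  values, reports the smaller rank sum; exact p for \(n \le 12\) without
  ties (checked against all \(2^n\) sign assignments), else the corrected
  normal approximation.
* **ICC** is the two-way random-effects, average-measures,
  absolute-agreement form \((MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)\).
* Stars: `*`, `**`, `***` at p < 0.05, 0.01, 0.001 (strict); p-values in
  association tables are deliberately unadjusted — each structure–function
  relation is tested individually, not as a joint family.
* MACS levels are encoded ordinally I→1, II→2, III→3; missing values are
  dropped pairwise per analysis (simplest defensible rule; not specified
  upstream).

## Numerical and runtime choices

* All percentiles: type-7 linear interpolation.
* Loss \(\varepsilon = 10^{-5}\); argmax ties to lowest id; Adam
  \(\beta_1 = 0.9, \beta_2 = 0.999\).
* Label maps are stored as int16 on disk; intensity volumes as float64, so
  round-trips are exact.
* Serialized interfaces (schemes, configs, manifests, reports) use JSON;
  the deployment environment ships no YAML parser for R and writing one by
  hand was judged worse than deviating on the container format.
* The acceptance training run caps at 40 epochs with 2 patches per subject
  (the loss-halving and Dice ≥ 0.8 conditions are met well before; the cap
  keeps the suite inside its CPU budget). The bootstrap coverage study uses
  1000 resamples per replicate over 2000 replicates for the same reason;
  `bootstrap_ci`'s default stays at 10,000.
* The acceptance-grade phantom volumetry runs at 128³/1 mm; unit tests use
  coarser grids with proportionally looser voxelization tolerances.

## Known limitations

Inputs are assumed co-registered to a common space (no registration or
resampling is performed, and grids must match exactly). The phantom's
simplifications are listed above; in particular, nothing here validates
performance on real distorted anatomy. The U-Net is a miniature; its
accuracy claims extend only to the phantom world. Lesion-filled image
synthesis, DICOM handling, bias-field correction, cortical surface
measures and rater-study reproduction are out of scope.
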