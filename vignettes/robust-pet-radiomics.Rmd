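---
title: "Identifying PET radiomic features robust to degrading factors with digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying PET radiomic features robust to degrading factors with digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiomic models built on PET images are only transportable if the features
they use survive the differences between acquisition pipelines: scanner
design and point-spread function, reconstruction voxel size, CT
metal-artifact contamination of the attenuation correction, and the tumor
delineation method. `phantomrad` implements a phantom-based screening
procedure for this question: simulate phantoms whose ground truth is known
exactly, image them under two protocols that differ in a single factor,
extract an identical radiomic feature roster from both arms, and test each
feature for interchangeability.

A feature is called **robust** to a factor when a paired two-sided Wilcoxon
signed-rank test across lesions does not reject equality (p > 0.05,
deliberately uncorrected — multiplicity correction would make robustness
*easier* to claim, which is the wrong direction for a screening rule). A
feature is **strongly correlated** between arms when Spearman's r > 0.8 and
its p value clears the Bonferroni-corrected level 0.05/K, with K the number
of features actually tested. Systematic bias is quantified by Bland–Altman
analysis of the pairwise differences relative to the pairwise means, with
comparability declared when the 95% t-interval of the mean relative
difference contains zero. Features robust to *every* factor form the
intersection set that a multicenter analysis could rely on.

## The digital phantoms

Three scene families mirror the physical setups such a study uses:

* **Single-lesion beds** host the 27 heterogeneous lesions: six three-layer
  cylindrical layouts (L1–L6, 30 mm diameter — beyond three times the
  widest PSF FWHM) realising all permutations of high/medium/low activity
  over the outer/middle/inner shells, each at layer contrast ratios
  (10, 5), (8, 4) and (4, 2); plus a two-layer cylinder series V1–V8 whose
  volumes grow geometrically from 1 ml to 15.6 ml at an inner-to-outer
  contrast of 6. The lowest lesion layer always sits at ten times the
  background concentration. Layouts L4–L6 place the high activity in the
  interior; their cold rims are the classic failure mode of
  percentage-of-maximum thresholds.
* **A NEMA-IQ-like body** (30 cm water cylinder) carries six fillable
  spheres of 10–37 mm diameter at 10:1 contrast plus ten background
  spheres (5.7–8.4 ml) used as uniform regions of interest.
* **A cheese-phantom cylinder** (30 cm diameter solid-water calibration
  phantom) carries three large (33 ml) and three small (11 ml) fillable
  tubes in prostate-like and head-and-neck-like layouts, with insert holes
  occupied by water-equivalent material or by aluminum (2.800 g/cm³),
  titanium (4.500 g/cm³) or stainless steel (7.700 g/cm³).

Scenes are rasterised by the centre-point rule on a fine simulation grid —
1 mm for lesion beds; 2 mm for the two large cylinders, where a 1 mm grid
would cost ~16M voxels per arm without changing any conclusion at the
4.2–4.8 mm PSF scales under study. Voxelised volumes converge to the
analytic solid volumes as the grid is refined (tested at 2, 1 and 0.5 mm).

## The degradation model

Acquisition and reconstruction are emulated in image space:

1. stationary, isotropic Gaussian PSF with sigma = FWHM/2.3548; 4.8 mm
   represents the analog scanner designs, 4.2 mm the digital one;
2. grid-aligned box-average resampling to the reconstructed voxel size
   (2 mm or 4 mm), always from one parent activity map so voxel-size arms
   share their underlying object exactly;
3. additive Gaussian image noise with standard deviation expressed relative
   to the background mean (10% for the analog arms, 7% for the digital arm,
   chosen as representative of clinical background coefficients of
   variation in short phantom scans), clipped at zero;
4. normalization of each reconstructed image so the mean background equals
   1 exactly — the same convention the feature definitions assume.

Projection-domain physics (Poisson counting, scatter, randoms,
reconstruction algorithms) is deliberately out of scope: the robustness
analysis needs controlled paired contrasts, not absolute image realism, and
the image-domain model provides every contrast the study design uses. The
metal-artifact operator follows the same philosophy: CT streaks are a
sinusoidal angular modulation decaying with distance from the metal centre,
and the PET arm receives a multiplicative bias field that suppresses
apparent uptake near the insert, with amplitude proportional to insert
density (so steel > titanium > aluminum) and decay length 40 mm. Amplitude
zero is a bit-exact no-op. This is a reproducible *emulation* of
attenuation-correction error, not a physical model; what the downstream
statistics consume is only the controlled with/without-artifact pairing.

What the simulator does **not** emulate — patient physiology, motion,
reconstruction non-stationarity, inter-scanner calibration drift — bounds
what passing tests mean: conclusions transfer to real data only to the
extent that a factor's image-domain signature is captured by the paired
contrast.

## Segmentation

Three delineation routes are implemented:

* **Ground truth**: region growing on the pseudo-CT (lesion material maps
  to 100 HU) after Gaussian denoising (kernel radius 2 voxels), with a
  50–150 HU inclusion window and 26-connectivity.
* **40% threshold**: voxels at or above 40% of the lesion maximum, keeping
  the connected component of the maximum; invariant to global intensity
  scaling by construction.
* **COA** (contrast-oriented algorithm): threshold `T = a·I70 + b·bg`,
  where I70 is the mean of the voxels at or above 70% of the lesion
  maximum and `bg` the whole-image background level, estimated as the
  kernel-density mode of the intensities outside the lesions and above an
  air cutoff. The literature the algorithm descends from calibrates its
  coefficients per scanner and does not publish them; we default to
  `a = b = 0.5`, which reproduces the half-way adaptive behaviour on
  homogeneous lesions (threshold midway between tumor mean and
  background), and both coefficients are configurable.

The per-lesion search region is the ground-truth bounding box dilated by 2
voxels, so blur-spread edges are not clipped. Ties at exactly the threshold
are included. When the COA threshold reaches the lesion maximum the lesion
is reported as an empty-mask failure and excluded pairwise, never silently
dropped.

On noise-free blurred spheres at least three FWHM wide with 10:1 contrast,
both PET methods recover volume within ±15%. On inward-hot multilayer
lesions both reject the cold rim and under-segment — the behaviour the
heterogeneous phantoms exist to expose. Intensity recovery after the PSF
falls monotonically from V8 down to V1; note that *volume* recovery under a
percentage-of-maximum threshold is not monotone in lesion size, because the
threshold itself adapts downward as partial-volume losses depress the
maximum.

## Features and preprocessing

The roster holds 133 features: 17 SUV first-order statistics, 3 histogram
descriptors (aucCSH, skewness, kurtosis — kurtosis in the Pearson
convention, normal = 3), 5 shape features, and 36 texture features (GLCM
10, GLRLM 11, GLSZM 10, NGTDM 5) computed under three preprocessing
variants: the plain quantizer, wavelet band-pass filtering (`WF_` prefix),
and equal-probability quantization (`Q_` prefix). The exact published
roster of the study this design follows lives in supplementary material
that is not reproduced in print, so the roster here is a canonical
reconstruction pinned to the stated families, prefixes and total count; it
ships as a YAML file and is treated as configuration.

Discretization defaults to a fixed bin width of W = 0.01 on
background-normalized SUVs, anchored at the in-mask minimum; a fixed bin
number (N = 64) and equal-probability quantization (64 levels, matching the
common histogram-equalization default) are available. The three quantizers
are deliberately *not* interchangeable — FBW moves under any intensity
rescaling, FBN is invariant to positive affine maps, and equal-probability
quantization is invariant to any strictly monotone map. This invariance
partition is the mechanism behind discretization-dependent feature
reproducibility, and it is machine-checked: in a two-arm study whose arms
differ by a pure intensity scale, the features whose values are
bit-identical across arms are exactly the predicted invariant set
(histogram features, shape features, coefficient of variation, and all
`Q_`-features).

Texture matrices follow fixed conventions: 13 unique 3-D directions at
distance 1 merged by summation (GLCM symmetric; GLRLM run counts), zones
and all connectivity 26-connected, out-of-mask neighbours truncate pairs,
runs and zones. With W = 0.01 the level count G can reach several thousand,
so GLCM and GLSZM are held sparsely; dense views exist for inspection and
for the brute-force verification at small G. Every matrix and every derived
feature is cross-checked against independent enumeration oracles to 1e-10
on randomized fixtures, and the count conservation laws (runs × length =
in-mask voxels per direction; zones × size = in-mask voxels; normalized
GLCM sums to 1) are asserted on every fixture.

The wavelet band-pass filter is a one-level 3-D separable orthogonal
decomposition (periodized sym4 by default; the study language names no
basis) in which the six mixed sub-bands are weighted 1:2 against LLL and
HHH before inverse transformation. With all weights 1 the round trip is
lossless to 1e-8, which is the test anchoring the implementation.

## Numerical choices worth knowing

* **Wilcoxon signed-rank**: zero differences dropped (classic convention;
  a Pratt variant is switchable); exact two-sided p by enumerating all
  sign assignments of the midranks for n ≤ 12 (valid under ties), normal
  approximation with tie and continuity correction above. All-zero
  differences give p = 1 — identical arms are maximally robust.
* **Spearman**: Pearson correlation of midranks; exact permutation p for
  n ≤ 8, t approximation otherwise; |r| = 1 maps to p = 0.
* **Bland–Altman**: differences in percent of pairwise means; 95% CI uses
  the t distribution because lesion counts are small (9–27); pairs with
  zero mean are excluded with a warning.
* **Minimum pairs to test**: 5; below that a feature is "untestable",
  never "robust". K for the Bonferroni divisor is recomputed from the
  features actually tested after pairwise degenerate exclusion.
* **Deterministic-study pairing**: the machine-checked invariance
  partition uses an intensity scale factor of 2. Powers of two are exact
  in binary floating point, so ranks, affine-normalized quantities and all
  linear operations are preserved bit-for-bit; a factor such as 1.3
  occasionally collapses almost-equal voxel values and perturbs
  equal-probability midranks on the strongly tied, noise-free phantom
  images, which would misattribute floating-point artifacts to the
  quantizer.
* **Degenerate features** (constant input, single gray level) are returned
  as NA with a per-feature flag and excluded pairwise by the statistics,
  never propagated silently.
* **Surface area** uses the co-area formula on a Gaussian-mollified mask
  indicator (sigma 1 voxel) — far less staircase bias than face counting
  (a voxelized sphere's exposed-face area overestimates the smooth area by
  ~50%, which would invert sphericity orderings).

## The four-factor study and its problem sizes

`run_full_study()` executes: system (NEMA phantom, two analog arms vs one
digital arm, 16 regions), voxel size (2 mm vs 4 mm from one parent map, 16
regions), metal artifact (two cheese configurations × water/Al/Ti/steel, 12
tubes, robustness = robust against water for all three metals), and
segmentation method (27 heterogeneous lesions, 40% vs COA, with ground
truth comparisons and Bland–Altman volume bias on the side). The
cross-factor intersection is reported with per-factor counts. On one CPU
the full study runs in roughly 10 minutes at the default problem sizes,
which were chosen so that each factor retains the study's lesion counts
(16/16/12/27) while staying desk-scale.

The headline numbers of the physical study this design follows (48/22/102/42
robust features per factor; volume biases −50% and −62%) derive from real
scanner data that was never deposited; the simulator is not calibrated to
reproduce them and the package does not claim to. What the in-silico runs
do reproduce — and what the acceptance checks assert — is the *mechanism*:
affine-invariant histogram features and rank-invariant Q-features survive
protocol scale changes that break fixed-bin-width features, SUVmean and
volume are strongly correlated yet not interchangeable across
reconstruction changes, and percentage thresholds under-segment inward-hot
lesions while remaining strongly correlated with ground-truth features.

## Limitations

Image-domain noise is Gaussian and stationary, not reconstructed-Poisson;
lesion layouts L1–L6 are parameterized reconstructions of schematic
drawings, not measured geometry; cheese-phantom hole coordinates are
configurable approximations of the two clinical layouts; the COA
coefficients are a structural default, not a scanner calibration. None of
these affect the paired, single-factor contrasts the statistics consume,
but absolute feature values should not be compared against physical scans.
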