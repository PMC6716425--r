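---
title: "Striatal multi-modality analysis for PD classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal multi-modality analysis for PD classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Parkinson's disease depletes presynaptic dopamine transporters in the
striatum, and dopamine-transporter PET (e.g. ^11^C-CFT) shows this as
reduced tracer binding, classically strongest in the posterior putamen.
PET alone localises anatomy poorly, so a structural T1-MR image of the
same subject is used to delineate the six striatal anatomical regions
(SARs: left/right caudate nucleus, putamen, pallidum); the delineation is
transferred onto the PET by rigid registration, quantified as
striatal-to-occipital ratios (SOR), and the resulting feature vector is
classified PD vs. normal (NL) by an SVM.

`pdstriatum` implements that framework end to end — segmentation,
registration, feature extraction, statistics and classification — together
with a synthetic phantom generator, because the clinical cohort this kind
of pipeline is developed on (tens of PD patients and age-matched controls
with paired scans) is not publicly distributable. Every stage is
exercisable, and tested, on phantoms alone.

# The phantom world

`phantom_config()` states the simulated world once; tests and examples do
not tune it.

* **Geometry.** Each SAR is an axis-aligned ellipsoid in RAS mm
  coordinates: caudates elongated anterior–posterior, putamina lateral and
  longest, pallida small and medial. The parieto-occipital reference is a
  posterior slab intersected with a shrunken (85%) brain envelope so the
  reference tissue stays several mm interior to the brain surface; a
  misplaced reference voxel landing outside the head would otherwise make
  the SOR denominator non-positive. A brain ellipsoid (42 x 46 x 40 mm
  semi-axes) provides the MR contrast envelope and the PET nonspecific
  background.
* **Uptake.** NL striatal uptake is 3.0 (caudate/putamen) and 2.5
  (pallidum) in arbitrary units over an occipital/nonspecific level of
  1.0, so the noise-free whole-putamen mean SOR is exactly 2.0 — a value
  used as an exact oracle in the tests. PD subjects have uptake reduced by
  a per-region fraction (`pd_effect`: 0.50 putamen, 0.35 pallidum, 0.25
  caudate), modulated inside the putamen by a linear anterior-to-posterior
  gradient spanning 0.5x–1.5x of the nominal effect, strongest
  posteriorly — the spatial pattern dopamine-transporter imaging reports.
  No quantitative uptake values were available to copy from a clinical
  table; these effect sizes were chosen once as a clearly separable but
  not degenerate contrast and are not revisited.
* **Variability.** Two per-subject log-normal jitters make the cohort a
  population rather than 67 copies of one object: `uptake_jitter`
  (SD 0.05) scales each region's uptake, and `volume_jitter` (SD 0.03)
  scales each region's semi-axes *independently of group*. The latter is
  what makes the "volume features are irrelevant" experiment meaningful:
  volumes vary, but their distribution is identical in PD and NL.
* **Acquisition.** The MR grid is finer (default 2 mm) than the PET grid
  (3 mm) to mimic modality resolutions; both get additive Gaussian noise
  (`noise_sd`, default 0.05 — 10% of the MR tissue step and 2.5% of the
  striatal PET signal). The true MR-to-PET rigid offset is drawn uniformly
  within ±6° and ±5 mm and stored with the subject, giving registration a
  known ground truth.

What a green phantom test does *not* establish: anatomical realism
(real striata are not ellipsoids), PET physics (no scatter, attenuation,
partial-volume effects beyond grid coarseness), scanner artifacts, or any
claim about clinical accuracy figures. The phantoms validate the
machinery — contracts, invariances, recovery of known truths — not the
clinical performance.

# Segmentation network and loss

The segmenter is a deeply supervised residual 3D encoder–decoder
(`segnet_config()`, `build_segnet()`): residual blocks of
convolution(3³) + instance normalisation + ReLU with identity shortcuts,
2x max-pooling down, nearest-neighbour upsampling and skip concatenation
up, and a 1×1×1 convolution + softmax head at *every* decoder level
(the coarsest head sits on the bottleneck). Auxiliary heads are scored
against stride-subsampled truth with weights 1/2^(level-1), normalised —
the usual deep-supervision recipe when no weights are published.

The loss is

$$L = w_D\,\mathbb{E}_i\!\left[(-\ln \mathrm{Dice}_i)^{\gamma}\right]
    + w_C\,\mathbb{E}_x\!\left[-\ln p_{l(x)}(x)\right],$$

with soft per-label Dice
$\mathrm{Dice}_i = 2\sum_x \delta_{il}(x)p_i(x) / \sum_x(\delta_{il}(x)+p_i(x))$
and defaults $w_D = 0.8$, $w_C = 0.2$, $\gamma = 0.3$. The $\gamma < 1$
exponent flattens the Dice term for well-learned labels and steepens it
for poorly-learned ones, which protects the small striatal structures
from the overwhelming background. Numerical choices:

* Dice smoothing: $\varepsilon = 10^{-6}$ added to numerator and
  denominator, so empty-vs-empty labels score 1 rather than 0/0.
* Probabilities are clamped to $[10^{-7}, 1]$ inside logarithms.
* The gradient factor $u^{\gamma-1}$ with $u=-\ln\mathrm{Dice}$ diverges
  as Dice → 1; $u$ is clamped below at $10^{-6}$ in the gradient only.
* $\mathbb{E}_i$ averages over foreground labels by default
  (`include_background = FALSE`): the loss exists for the small
  structures, and a background Dice of ~1 would dilute it. The background
  is still supervised through the cross-entropy term.
* Argmax ties break to the lowest label code.

All forward/backward passes are hand-derived (this stack has no deep
learning framework) over BLAS-backed im2col convolutions; the full
network gradient is verified against central finite differences in the
tests. Everything is seed-deterministic, including dropout and the
Gaussian-blur augmentation (applied with probability 0.5).

Desk-scale choices: the reference ROI of 96³ voxels survives in the
configuration, but defaults are 32³ with channel ladder 6/12/24, one
convolution per block, which a single CPU trains in about two minutes on
one phantom. The reference recipe (Adam, lr 1e-3) is the default of
`train_segnet()`; the overfit smoke test passes lr 1e-2 because at this
tiny scale the conservative rate simply converges too slowly — a training
schedule choice, not a loss change.

# Registration

`register_rigid()` maximises similarity over the 6 rigid parameters
(rotation centre = fixed-image physical centre) with a deterministic
Nelder–Mead simplex over a ×4/×2/×1 block-mean pyramid;
`register_affine()` refines 12 affine parameters from a pre-rigid start
(the single-modality template arm). Label maps travel strictly by
nearest-neighbour resampling (`propagate_labels()`); intensity resampling
is trilinear. All NIfTI geometry is interpreted as axis-aligned RAS with
0-based voxel indices.

The similarity started as plain NMI (32 bins, first-order Parzen
binning). Three refinements proved necessary, and were adopted as design
choices after measuring rotation recovery on phantoms with known offsets:

1. **Foreground masking.** Three quarters of the volume is noisy
   background; restricting the joint histogram to fixed-image voxels above
   an Otsu threshold removed most of the metric's degree-scale roughness.
2. **Pyramid smoothing.** Each level is Gaussian-smoothed (1 voxel SD);
   trilinear interpolation of unsmoothed noise otherwise modulates the
   metric at exactly the amplitude the optimiser needs to resolve.
3. **Coordinate-descent polish on the correlation ratio.** The head is
   nearly axisymmetric about the anterior–posterior axis, so that rotation
   sits in a shallow, slightly multimodal NMI valley where a simplex
   stalls 2–4° off truth. A translation-first coarse stage, a coarse
   rotation grid seed at the middle level, and a final 1-D line-search
   sweep per parameter on the correlation ratio (smoother than NMI for
   tissue-wise monotone MR/PET relationships) brought median rotation
   recovery from ≈3.5° to ≈0.7° over 20 phantom pairs, with ≤0.1 mm
   median translation error.

The reported `similarity` is evaluated on the same smoothed, masked
full-resolution pair the optimiser saw, so rigid and nested affine
results are directly comparable.

# Features

`extract_features()` emits the canonical 90-vector:

* Each caudate and putamen is split into 3 substructures by k-means
  (`subdivide_region()`), clustered on **voxel physical coordinates in
  mm** — not intensities. Coordinate clustering yields spatially coherent,
  anatomically corresponding thirds (the clusters are relabelled
  anterior → posterior by centroid, so "subregion 3 of the putamen" is
  the posterior third in every subject); intensity clustering would break
  that inter-subject correspondence. This is an interpretation choice the
  source method leaves open, recorded here. 10 restarts, best inertia,
  seed-derived.
* Six intensity statistics per region unit — max, min, median, Q1, Q3
  (type-7 linear interpolation), mean — over 14 units (2×3 caudate
  subregions, 2×3 putamen subregions, 2 whole pallida), each normalised
  as SOR = (striatum − occipital)/occipital against the occipital
  statistic of the *same kind* (max against max, mean against mean …).
  A same-kind denominator keeps every feature a pure ratio, invariant to
  global intensity scaling — verified as a test invariance. A
  mean-denominator variant sits behind `occ_mode = "mean"`.
* The six whole-SAR volumes (voxel count × voxel volume) from the
  original-resolution MR label map, never from the downsampled PET grid.

# Statistics and classification

* **Selection:** per-feature two-sided Welch t-tests (the emulated design
  is 49 vs 18 — pooling variances would be wrong), raw α = 0.01, no
  multiple-testing correction (the screening threshold *is* the method).
  Zero-variance features are excluded with a warning. Implementation is
  vectorised and cross-checked against `stats::t.test` in the tests.
* **Classifier:** linear SVM, C = 1, features standardised by
  training-fold statistics. No SVM package exists in this environment, so
  it is an L2-regularised squared-hinge minimisation by BFGS from a zero
  start — convex, hence deterministic. If a fold selects nothing, the
  single lowest-p feature is used so every fold predicts.
* **Cross-validation:** exact leave-one-out for n = 1; for n > 1,
  repeated random held-out subsets (200 partitions by default; partition
  schemes for leave-n-out are rarely published, so this is a stated
  choice). Selection and standardisation are *refit inside every training
  split*; the no-leakage property is tested by label permutation driving
  accuracy to chance. `compare_arms()` evaluates two arms on bitwise
  identical partitions and runs a paired t-test across n on mean wrong
  predictions.
* **Importance:** a compact bagged CART forest (Gini impurity, 500 trees,
  mtry = ⌊√p⌋ — again written in-package for lack of an installed
  implementation), importances normalised to sum 1 and aggregated per
  statistic kind (mean, median, quartiles, max, min, volume) by summing
  member features; summing keeps the aggregate rows themselves summing
  to 1. `importance_map()` paints the summed subregion importances back
  onto the label grid for heatmap export.

# Pipeline arms

`run_pipeline()` executes one of three arms per manifest row:
`manual_labels` (gold-standard MR labels → rigid MR→PET → propagate),
`multi_modality` (network segmentation instead of gold labels; the
network also predicts the occipital reference, so the arm needs no manual
input), and `single_modality_template` (pre-labelled PET template fitted
by pre-rigid + affine; all labels, including the volume source, come from
the template — that arm never sees the subject's MR). The shipped
template is itself phantom-derived (`build_pet_template()`, an average of
aligned NL phantoms) and is labelled synthetic; a clinical atlas template
cannot be redistributed. Per-subject failures are recorded and the
subject excluded; per-subject feature rows can be cached content-addressed
(MD5 of inputs + arm + seed) for idempotent reruns.

# Known limitations

* Phantoms are geometric; none of the clinical accuracy figures of any
  published study are reproduced or reproducible here, and the package
  deliberately reports its own synthetic-scale numbers only.
* The NIfTI reader/writer covers the axis-aligned RAS subset the pipeline
  emits; oblique or flipped orientations are rejected, not reoriented.
* The registration is rigid/affine only — adequate for same-subject
  MR/PET and for the template arm's stated role, not for deformable
  inter-subject normalisation.
* Desk-scale network defaults (32³ ROI, 3 levels) are far below the 96³
  reference configuration; the architecture accepts the full-scale
  ladder, but nothing here demonstrates full-scale training behaviour.
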