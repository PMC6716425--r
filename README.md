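# pdstriatum

Multi-modality striatal image analysis for Parkinson's disease (PD)
classification, in R.

PD depletes presynaptic dopamine transporters in the striatum;
dopamine-transporter PET shows this as reduced tracer binding, strongest
in the posterior putamen, while a same-session T1-MR image supplies the
anatomy that PET lacks. This package implements the full automatic
analysis framework around that observation, for imaging methodologists who
want a tested, deterministic, single-machine implementation of each stage:

1. **Segmentation** — a deeply supervised residual 3D encoder–decoder
   (`build_segnet()`, `train_segnet()`, `predict_segnet()`) labels the six
   striatal anatomical regions (SARs: left/right caudate, putamen,
   pallidum) plus the parieto-occipital reference on the MR volume. It is
   trained with the composite loss
   `L = w_D E_i[(-ln Dice_i)^γ] + w_C E_x[-ln p_l(x)]`
   (defaults `w_D = 0.8`, `w_C = 0.2`, `γ = 0.3`), whose Dice term
   protects the small striatal structures from the dominant background.
2. **Registration** — rigid MR→PET alignment (and pre-rigid + affine
   template→PET for the single-modality arm) by masked normalised mutual
   information over a multiresolution pyramid with a correlation-ratio
   polish; labels travel by nearest-neighbour propagation
   (`register_rigid()`, `register_affine()`, `propagate_labels()`).
3. **Features** — the 90-dimensional striatal-to-occipital-ratio (SOR)
   representation: caudate and putamen split into three anterior→posterior
   k-means substructures, six intensity statistics per region unit, each
   normalised as `SOR = (striatum − occipital)/occipital`, plus the six
   SAR volumes from the original-resolution MR labels
   (`extract_features()`; 14 units × 6 statistics + 6 volumes = 90).
4. **Statistics & classification** — per-feature Welch t-test screening at
   α = 0.01, a standardised linear SVM with leave-n-out cross-validation
   (selection refit inside every fold), random-forest feature importance
   aggregated per statistic kind, paired arm comparisons, and subregion
   importance maps (`select_features()`, `leave_n_out_cv()`,
   `rf_importance()`, `compare_arms()`, `importance_map()`).

Because clinical paired MR/PET cohorts are not redistributable, the
package includes a first-class phantom generator (`phantom_config()`,
`generate_cohort()`): ellipsoidal bilateral striatal compartments with
elevated uptake, an interior occipital reference slab, a PD effect with an
anterior→posterior putamen gradient, group-independent volume jitter,
additive noise, and a known rigid MR↔PET misalignment. Every stage of the
framework is tested end-to-end on these phantoms.

## Worked example

Simulate a small cohort, run the manual-label arm of the pipeline, and
cross-validate:

```r
library(pdstriatum)

cfg <- phantom_config(grid_shape = c(32, 32, 32), voxel_spacing = c(3, 3, 3),
                      pet_shape = c(28, 28, 28), pet_spacing = c(3.5, 3.5, 3.5))
dir <- tempfile()
manifest <- write_cohort(generate_cohort(cfg, n_pd = 10, n_nl = 6, seed = 1), dir)

pcfg <- pipeline_config(arm = "manual_labels", seed = 1,
                        reg_opts = list(levels = c(4L, 2L), maxit = c(250L, 250L)),
                        cv_ns = 1L)
res <- run_pipeline(manifest, pcfg)
length(res$selection$selected)   # features passing p < 0.01
res$cv$n1
```

```
[1] 55
<cv_result> leave-1-out: acc 1.0000, wrong 0.000 (16 partitions)
```

55 of the 90 features separate the groups at α = 0.01 (all of them SOR
features — the group-independent volumes are never among them), and the
leave-one-out SVM classifies every phantom subject correctly: on a
separable cohort with a 50% posterior-putamen uptake reduction the
pipeline should, and does, reach ceiling. Feature importance by statistic
kind for the same run:

```r
rf_importance(res$features, seed = 1, ntree = 300)$by_statistic
```

```
     statistic  importance
1         mean 0.197321640
2       median 0.183752074
3 3rd quantile 0.295863949
4 1st quantile 0.062929604
5      maximum 0.249762977
6      minimum 0.007525480
7       volume 0.002844276
```

The intensity statistics carry essentially all the discriminative weight
and the minimum the least — edge voxels are the ones a slightly loose
delineation contaminates; the volume aggregate is negligible, because the
phantom volumes are drawn identically for both groups and the pipeline
correctly refuses to use them.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pdstriatum simulate --n-pd 49 --n-nl 18 --seed 1 --out cohort/
Rscript inst/cli/pdstriatum run --manifest cohort/manifest.csv --arm manual_labels --out report/
```

## Acceptance script

`scripts/acceptance.R` re-runs the main computation from scratch against
the installed package — it simulates a phantom cohort, executes the
manual-label arm (registration, label propagation, feature extraction),
cross-validates the classifier, and prints the per-statistic importance
table — then writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/`, `src/` — implementation (Rcpp kernels for convolution, resampling,
  histograms).
- `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code.
- `vignettes/pdstriatum-methods.Rmd` — the models, numerical choices and
  their rationale.
- `inst/cli/pdstriatum` — command-line interface.
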