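# Shared fixtures, all generated in code. Heavy artifacts (trained network,
# phantom cohorts) are memoized for the session so several test files can
# share them without retraining.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# Deterministic, noise-free, perfectly aligned world: exact oracles.
exact_config <- function(...) {
  phantom_config(noise_sd = 0, uptake_jitter = 0, volume_jitter = 0,
                 misalignment_range = list(rotation = 0, translation = 0),
                 ...)
}

# Desk-scale grids used by the training and end-to-end tests: MR 32^3 at
# 3 mm, PET 28^3 at 3.5 mm.
small_config <- function(...) {
  phantom_config(grid_shape = c(32, 32, 32), voxel_spacing = c(3, 3, 3),
                 pet_shape = c(28, 28, 28), pet_spacing = c(3.5, 3.5, 3.5),
                 ...)
}

small_exact_config <- function(...) {
  small_config(noise_sd = 0, uptake_jitter = 0, volume_jitter = 0,
               misalignment_range = list(rotation = 0, translation = 0),
               ...)
}

smoke_segnet_config <- function() {
  segnet_config(channels = c(6, 12, 24), layers = 1, dropout = 0,
                n_labels = 8, input_roi = c(32, 32, 32))
}

# Network overfitted on one noise-free 32^3 phantom (the segmentation smoke
# test); shared with the end-to-end comparisons.
smoke_fit <- function() {
  memo("smoke_fit", {
    s <- generate_subject(small_exact_config(), "NL", "train", seed = 2)
    net <- build_segnet(smoke_segnet_config(), seed = 1)
    fit <- train_segnet(net, list(s), epochs = 200, lr = 1e-2, seed = 11,
                        augment = FALSE, stop_dice = 0.92,
                        stop_metric = "min", check_every = 10)
    list(fit = fit, subject = s)
  })
}

# End-to-end cohort for the comparative experiments: a separable 49 PD /
# 18 NL phantom cohort run through the three arms (gold-standard labels,
# network segmentation, PET-template registration). Registration of the
# template arm uses a cheaper two-level pyramid: that arm is the
# deliberately weaker comparator. The MR->PET rigid transform is computed
# once per subject and shared by the manual and automatic arms (it depends
# only on the images, not on the labels).
headline_tables <- function() {
  memo("headline", {
    cfg <- small_config()
    cohort <- generate_cohort(cfg, n_pd = 49, n_nl = 18, seed = 501)
    fit <- smoke_fit()$fit
    template <- build_pet_template(cfg, n = 6, seed = 900)
    cheap <- list(levels = c(4L, 2L), maxit = c(250L, 250L))
    vecs <- list(manual = list(), auto = list(), template = list())
    errors <- character(0)
    for (s in cohort) {
      res <- tryCatch({
        rig <- suppressWarnings(register_rigid(s$mr, s$pet))
        pred <- predict_segnet(fit, s$mr)
        pl_man <- suppressWarnings(
          propagate_labels(s$labels_mr_space, rig$transform, s$pet))
        pl_auto <- suppressWarnings(
          propagate_labels(pred, rig$transform, s$pet))
        trig <- suppressWarnings(
          register_rigid(template$pet, s$pet, cheap))
        taff <- suppressWarnings(
          register_affine(template$pet, s$pet, trig$transform, cheap))
        pl_tpl <- suppressWarnings(
          propagate_labels(template$labels, taff$transform, s$pet))
        list(
          manual = extract_features(s$pet, pl_man, s$labels_mr_space,
                                    seed = 1, id = s$id, group = s$group),
          auto = extract_features(s$pet, pl_auto, pred,
                                  seed = 1, id = s$id, group = s$group),
          template = extract_features(s$pet, pl_tpl, pl_tpl,
                                      seed = 1, id = s$id, group = s$group))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, paste0(s$id, ": ", conditionMessage(res)))
      } else {
        for (arm in names(vecs)) vecs[[arm]][[s$id]] <- res[[arm]]
      }
    }
    list(manual = feature_table(vecs$manual),
         auto = feature_table(vecs$auto),
         template = feature_table(vecs$template),
         errors = errors, n_total = length(cohort))
  })
}

# Tiny random probability fixtures for loss tests.
random_probs <- function(shape, n_labels, seed = 1) {
  set.seed(seed)
  p <- array(stats::runif(prod(shape) * n_labels, 0.05, 0.95),
             dim = c(shape, n_labels))
  p
}

one_hot <- function(truth, n_labels) {
  p <- array(0, dim = c(dim(truth), n_labels))
  for (i in seq_len(n_labels) - 1L) p[, , , i + 1L] <- (truth == i) * 1
  p
}
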