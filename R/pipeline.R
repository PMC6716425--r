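# End-to-end orchestration: segment -> register -> extract -> classify.
#
# Three arms mirror the framework's comparative experiments:
#   manual_labels            gold-standard MR labels + rigid MR->PET
#   multi_modality           network-segmented MR labels + rigid MR->PET
#   single_modality_template pre-labelled PET template + pre-rigid + affine
# In the two MR-based arms the occipital reference travels with the MR
# label map (gold-standard or network-predicted); in the template arm all
# labels come from the template.

#' Pipeline configuration
#'
#' @param arm `"manual_labels"`, `"multi_modality"`, or
#'   `"single_modality_template"`.
#' @param model trained `segnet` (or checkpoint path) — required for the
#'   multi-modality arm.
#' @param template list with `pet` ([image_volume()]) and `labels`
#'   ([label_map()]) — required for the template arm; see
#'   [build_pet_template()].
#' @param seed master seed propagated to every stochastic stage.
#' @param alpha feature-selection level.
#' @param cv_ns grid of leave-n-out n values for the report.
#' @param n_partitions CV partitions per n (> 1).
#' @param reg_opts options forwarded to the registration calls.
#' @param cache_dir optional directory for content-addressed per-subject
#'   feature caching (reruns are idempotent).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(arm = c("multi_modality", "manual_labels",
                                    "single_modality_template"),
                            model = NULL, template = NULL, seed = 1L,
                            alpha = 0.01, cv_ns = 1L, n_partitions = 100L,
                            reg_opts = list(), cache_dir = NULL) {
  arm <- match.arg(arm)
  if (arm == "multi_modality" && is.null(model))
    stop("multi_modality arm requires a trained segmentation model")
  if (arm == "single_modality_template" && is.null(template))
    stop("single_modality_template arm requires a labelled PET template")
  if (is.character(model)) model <- load_segnet(model)
  structure(list(arm = arm, model = model, template = template,
                 seed = as.integer(seed), alpha = alpha, cv_ns = cv_ns,
                 n_partitions = n_partitions, reg_opts = reg_opts,
                 cache_dir = cache_dir),
            class = "pipeline_config")
}

#' Build a synthetic pre-labelled PET template
#'
#' Averages the PET volumes of `n` normal-control phantoms generated with
#' zero misalignment and no subject variability, and attaches the analytic
#' label map rendered on the PET grid. This is a synthetic stand-in for an
#' atlas-based PET template (which cannot be redistributed); it is only
#' meant to be structurally plausible.
#'
#' @param config a [phantom_config()].
#' @param n phantoms averaged.
#' @param seed RNG seed.
#' @return list with `pet` and `labels`, usable as `template` in
#'   [pipeline_config()].
#' @export
build_pet_template <- function(config, n = 8L, seed = 100L) {
  tcfg <- config
  tcfg$misalignment_range <- list(rotation = 0, translation = 0)
  tcfg$uptake_jitter <- 0
  tcfg$volume_jitter <- 0
  subs <- lapply(seq_len(n), function(i) {
    generate_subject(tcfg, "NL", sprintf("T%02d", i), seed = seed + i)
  })
  acc <- Reduce(`+`, lapply(subs, function(s) s$pet$data)) / n
  pet <- image_volume(acc, subs[[1]]$pet$spacing, subs[[1]]$pet$origin,
                      "PET")
  list(pet = pet, labels = subs[[1]]$labels_pet_space)
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("id", "group", "mr_path", "pet_path")
  missing <- setdiff(need, colnames(manifest))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  manifest
}

subject_cache_key <- function(config, row) {
  paths <- c(row$mr_path, row$pet_path, row$labels_path)
  paths <- paths[!is.na(paths) & nzchar(paths)]
  sums <- unname(tools::md5sum(paths))
  key_src <- paste(c(config$arm, config$seed, sums), collapse = "|")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(key_src, tf)
  unname(tools::md5sum(tf))
}

# Run one subject through the configured arm; returns a feature_vector.
pipeline_subject <- function(row, config) {
  pet <- read_nifti(row$pet_path, modality = "PET")
  if (config$arm == "single_modality_template") {
    tpl <- config$template
    rig <- register_rigid(tpl$pet, pet, config$reg_opts)
    aff <- register_affine(tpl$pet, pet, rig$transform, config$reg_opts)
    pet_labels <- propagate_labels(tpl$labels, aff$transform, pet)
    anat_labels <- pet_labels  # no subject MR information in this arm
  } else {
    mr <- read_nifti(row$mr_path, modality = "MR")
    anat_labels <- if (config$arm == "manual_labels") {
      if (is.na(row$labels_path) || !nzchar(row$labels_path))
        stop("manual_labels arm requires labels_path for subject ", row$id)
      read_nifti(row$labels_path, as_labels = TRUE)
    } else {
      predict_segnet(config$model, mr)
    }
    rig <- register_rigid(mr, pet, config$reg_opts)
    pet_labels <- propagate_labels(anat_labels, rig$transform, pet)
  }
  extract_features(pet, pet_labels, anat_labels,
                   seed = config$seed, id = row$id, group = row$group)
}

#' Run the full diagnostic pipeline over a cohort manifest
#'
#' Executes the configured arm per subject (failures are recorded and the
#' subject excluded), assembles the 90-feature table, selects features at
#' the configured alpha, and evaluates leave-n-out CV over `cv_ns`.
#'
#' @param manifest data.frame or CSV path with columns
#'   `id, group, mr_path, pet_path` and optionally `labels_path`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory: writes `features.csv` and
#'   `report.json`.
#' @return list with `features` (a `feature_table`), `selection`,
#'   `cv` (list of `cv_result` per n), and `errors` (per-subject failure
#'   records).
#' @export
run_pipeline <- function(manifest, config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) stop("empty cohort: nothing to run")
  if (!all(file.exists(manifest$mr_path)) ||
      !all(file.exists(manifest$pet_path))) {
    bad <- manifest$id[!file.exists(manifest$mr_path) |
                         !file.exists(manifest$pet_path)]
    stop("missing image file(s) for subject(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(config$cache_dir))
    dir.create(config$cache_dir, recursive = TRUE, showWarnings = FALSE)
  errors <- list()
  vectors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    fv <- tryCatch({
      if (!is.null(config$cache_dir)) {
        key <- subject_cache_key(config, row)
        cache_file <- file.path(config$cache_dir, paste0(key, ".json"))
        if (file.exists(cache_file)) {
          cached <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
          structure(stats::setNames(cached$values, feature_names()),
                    id = row$id, group = row$group,
                    class = c("feature_vector", "numeric"))
        } else {
          fv <- pipeline_subject(row, config)
          jsonlite::write_json(list(values = as.numeric(fv)), cache_file,
                               auto_unbox = TRUE, digits = NA)
          fv
        }
      } else pipeline_subject(row, config)
    }, error = function(e) e)
    if (inherits(fv, "error")) {
      errors[[row$id]] <- conditionMessage(fv)
    } else {
      vectors[[row$id]] <- fv
    }
  }
  if (length(vectors) == 0)
    stop("all subjects failed; first error: ", errors[[1]])
  tab <- feature_table(vectors)
  sel <- suppressWarnings(select_features(tab, config$alpha))
  cv <- lapply(config$cv_ns, function(n) {
    leave_n_out_cv(tab, n, config$alpha,
                   n_partitions = config$n_partitions,
                   seed = config$seed + n)
  })
  names(cv) <- paste0("n", config$cv_ns)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(tab, file.path(out_dir, "features.csv"))
    report <- list(
      arm = config$arm, seed = config$seed,
      n_subjects = nrow(tab),
      n_selected = length(sel$selected),
      selected = sel$selected,
      errors = errors,
      cv = lapply(cv, function(r) r[c("n", "acc_mean", "wrong_mean",
                                      "n_partitions")])
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(features = tab, selection = sel, cv = cv, errors = errors)
}

#' Plot leave-n-out CV curves
#'
#' Accuracy and mean wrong predictions as a function of n, for one or
#' several arms.
#'
#' @param cv_by_arm named list: arm -> list of `cv_result` per n.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of accuracies (n x arm).
#' @export
plot_cv_curves <- function(cv_by_arm, ...) {
  ns <- vapply(cv_by_arm[[1]], `[[`, numeric(1), "n")
  accs <- vapply(cv_by_arm, function(arm)
    vapply(arm, `[[`, numeric(1), "acc_mean"), numeric(length(ns)))
  accs <- matrix(accs, nrow = length(ns),
                 dimnames = list(ns, names(cv_by_arm)))
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  graphics::matplot(ns, accs, type = "b", pch = 19, lty = 1,
                    xlab = "n held out", ylab = "average accuracy", ...)
  graphics::legend("bottomleft", legend = colnames(accs),
                   col = seq_len(ncol(accs)), lty = 1, pch = 19, bty = "n")
  wrongs <- vapply(cv_by_arm, function(arm)
    vapply(arm, `[[`, numeric(1), "wrong_mean"), numeric(length(ns)))
  wrongs <- matrix(wrongs, nrow = length(ns))
  graphics::matplot(ns, wrongs, type = "b", pch = 19, lty = 1,
                    xlab = "n held out", ylab = "average wrong predictions",
                    ...)
  invisible(accs)
}
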