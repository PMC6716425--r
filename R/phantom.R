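# Synthetic paired MR/PET brain phantoms.
#
# The clinical cohort behind the pipeline (dopamine-transporter PET plus
# T1-MR of PD patients and controls) is not publicly available, so the
# package ships a generator of geometric stand-ins: bilateral striatal
# ellipsoids (caudate, putamen, pallidum) with elevated tracer uptake over a
# nonspecific brain background, a posterior parieto-occipital reference slab,
# a PD-like uptake reduction that is strongest in the posterior putamen, and
# a known rigid MR-to-PET misalignment. Everything is defined analytically
# in mm under the RAS convention, so the same geometry can be rendered on
# grids of any size/spacing.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

default_region_geometry <- function() {
  mirror <- function(g) { g$center[1] <- -g$center[1]; g }
  cau <- list(center = c(9, 12, 8), semiaxes = c(4, 9, 5))
  put <- list(center = c(17, -2, 2), semiaxes = c(5, 11, 6))
  pal <- list(center = c(7.5, -6, -4), semiaxes = c(3.5, 5, 4.5))
  list(
    caudate_R = cau, caudate_L = mirror(cau),
    putamen_R = put, putamen_L = mirror(put),
    pallidum_R = pal, pallidum_L = mirror(pal),
    # the slab is intersected with a shrunken brain envelope so the
    # reference region stays interior (margin >= ~6 mm to the brain surface)
    occipital = list(y_range = c(-40, -29), x_half = 26, z_half = 16,
                     brain_frac = 0.85),
    brain = list(center = c(0, 0, 0), semiaxes = c(42, 46, 40))
  )
}

#' Configuration of the synthetic MR/PET phantom world
#'
#' Defines the cohort the generator emulates: grid geometry for both
#' modalities, per-region ellipsoid geometry (mm), normal-control tracer
#' uptake per striatal region, the occipital reference level, the fractional
#' PD uptake reduction (with an anterior-to-posterior gradient inside the
#' putamen), MR tissue contrast, additive noise, per-subject biological
#' variability, and the range of the true rigid MR-to-PET misalignment.
#'
#' @param grid_shape MR voxels per axis.
#' @param voxel_spacing MR voxel size, mm.
#' @param pet_shape,pet_spacing PET grid (coarser than MR by default, to
#'   mimic PET resolution).
#' @param region_geometry list of per-region ellipsoids plus occipital slab
#'   and brain envelope; see `default_region_geometry` in the source.
#' @param uptake_nl named NL-mean PET uptake per SAR (arbitrary units).
#' @param occipital_uptake reference-region (and nonspecific brain) uptake.
#' @param pd_effect named fractional uptake reduction per SAR for PD
#'   subjects; inside the putamen it is modulated by a linear
#'   anterior-to-posterior gradient spanning 0.5x to 1.5x the nominal value
#'   (strongest posteriorly).
#' @param noise_sd additive Gaussian noise SD applied to both modalities.
#' @param mr_contrast named MR intensity means for background/brain/SAR.
#' @param uptake_jitter SD of per-subject log-normal multiplicative uptake
#'   variability per region (biological spread within a group).
#' @param volume_jitter SD of per-subject log-normal semi-axis scaling,
#'   group-independent (keeps region volumes variable but uninformative).
#' @param misalignment_range list with `rotation` (max deg) and
#'   `translation` (max mm) of the true MR-to-PET rigid offset.
#' @param seed default RNG seed.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid_shape = c(48, 56, 48),
                           voxel_spacing = c(2, 2, 2),
                           pet_shape = c(32, 36, 32),
                           pet_spacing = c(3, 3, 3),
                           region_geometry = default_region_geometry(),
                           uptake_nl = c(caudate_R = 3, caudate_L = 3,
                                         putamen_R = 3, putamen_L = 3,
                                         pallidum_R = 2.5, pallidum_L = 2.5),
                           occipital_uptake = 1,
                           pd_effect = c(caudate_R = 0.25, caudate_L = 0.25,
                                         putamen_R = 0.5, putamen_L = 0.5,
                                         pallidum_R = 0.35,
                                         pallidum_L = 0.35),
                           noise_sd = 0.05,
                           mr_contrast = c(background = 0.05, brain = 1,
                                           sar = 1.5),
                           uptake_jitter = 0.05,
                           volume_jitter = 0.03,
                           misalignment_range = list(rotation = 6,
                                                     translation = 5),
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, length(pet_shape) == 3L,
            all(grid_shape >= 4), all(pet_shape >= 4),
            all(voxel_spacing > 0), all(pet_spacing > 0),
            noise_sd >= 0, uptake_jitter >= 0, volume_jitter >= 0,
            occipital_uptake > 0)
  for (r in sar_names()) {
    g <- region_geometry[[r]]
    if (is.null(g) || any(g$semiaxes <= 0))
      stop("region_geometry must give positive semi-axes for ", r)
    if (is.na(uptake_nl[r])) stop("uptake_nl missing for ", r)
    if (is.na(pd_effect[r]) || pd_effect[r] < 0 || pd_effect[r] >= 1)
      stop("pd_effect for ", r, " must lie in [0, 1)")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 pet_shape = as.integer(pet_shape),
                 pet_spacing = as.numeric(pet_spacing),
                 region_geometry = region_geometry,
                 uptake_nl = uptake_nl, occipital_uptake = occipital_uptake,
                 pd_effect = pd_effect, noise_sd = noise_sd,
                 mr_contrast = mr_contrast, uptake_jitter = uptake_jitter,
                 volume_jitter = volume_jitter,
                 misalignment_range = misalignment_range,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Centered grid: world origin chosen so the grid midpoint sits at 0 mm.
centered_origin <- function(shape, spacing) -(shape - 1) * spacing / 2

phantom_mr_grid <- function(config) {
  list(shape = config$grid_shape, spacing = config$voxel_spacing,
       origin = centered_origin(config$grid_shape, config$voxel_spacing))
}

phantom_pet_grid <- function(config) {
  list(shape = config$pet_shape, spacing = config$pet_spacing,
       origin = centered_origin(config$pet_shape, config$pet_spacing))
}

in_ellipsoid <- function(points, center, semiaxes) {
  ((points[, 1] - center[1]) / semiaxes[1])^2 +
    ((points[, 2] - center[2]) / semiaxes[2])^2 +
    ((points[, 3] - center[3]) / semiaxes[3])^2 <= 1
}

# Label every point (mm) with the region code it falls in; errors if two
# regions claim the same point (overlapping geometry) or a SAR is empty.
label_points <- function(points, geometry, check = TRUE) {
  lab <- integer(nrow(points))
  dict <- sar_labels()
  for (r in sar_names()) {
    g <- geometry[[r]]
    m <- in_ellipsoid(points, g$center, g$semiaxes)
    if (check && any(lab[m] != 0L))
      stop("phantom geometry error: region '", r,
           "' overlaps another region on the grid")
    lab[m] <- dict[[r]]
  }
  occ <- geometry$occipital
  m <- points[, 2] >= occ$y_range[1] & points[, 2] <= occ$y_range[2] &
    abs(points[, 1]) <= occ$x_half & abs(points[, 3]) <= occ$z_half
  if (!is.null(occ$brain_frac)) {
    br <- geometry$brain
    m <- m & in_ellipsoid(points, br$center, br$semiaxes * occ$brain_frac)
  }
  if (check && any(lab[m] != 0L))
    stop("phantom geometry error: occipital slab overlaps a striatal region")
  lab[m] <- dict[["occipital"]]
  lab
}

jitter_geometry <- function(geometry, scales) {
  for (r in names(scales)) {
    geometry[[r]]$semiaxes <- geometry[[r]]$semiaxes * scales[[r]]
  }
  geometry
}

# Noise-free PET uptake at points given in MR-anatomy space (mm).
uptake_at <- function(points, geometry, config, group, uptake_scale) {
  lab <- label_points(points, geometry, check = FALSE)
  up <- numeric(nrow(points))
  brain <- in_ellipsoid(points, geometry$brain$center,
                        geometry$brain$semiaxes)
  up[brain] <- config$occipital_uptake
  dict <- sar_labels()
  up[lab == dict[["occipital"]]] <- config$occipital_uptake
  for (r in sar_names()) {
    m <- lab == dict[[r]]
    if (!any(m)) next
    base <- config$uptake_nl[[r]] * uptake_scale[[r]]
    if (identical(group, "PD")) {
      eff <- config$pd_effect[[r]]
      if (grepl("^putamen", r)) {
        g <- geometry[[r]]
        # anterior (large y) -> 0.5x effect, posterior -> 1.5x
        u <- (g$center[2] + g$semiaxes[2] - points[m, 2]) /
          (2 * g$semiaxes[2])
        grad <- 0.5 + pmin(pmax(u, 0), 1)
      } else grad <- 1
      base <- base * (1 - eff * grad)
    }
    up[m] <- base
  }
  up
}

#' Generate one synthetic paired MR/PET subject
#'
#' Renders the configured anatomy on the MR grid (intensity + gold-standard
#' label map), draws a random rigid MR-to-PET misalignment within the
#' configured range, and renders the PET uptake field on the PET grid through
#' that transform, adding Gaussian noise to both modalities. For PD subjects
#' the striatal uptake is reduced by `pd_effect` with the putamen gradient.
#'
#' @param config a [phantom_config()].
#' @param group `"NL"` or `"PD"`.
#' @param id subject identifier.
#' @param seed RNG seed for this subject (default `config$seed`).
#' @return A `synthetic_subject`: list with `mr`, `pet` ([image_volume()]),
#'   `labels_mr_space`, `labels_pet_space` ([label_map()]),
#'   `true_transform` ([rigid_transform()] MR to PET), `group`, `id`.
#' @export
generate_subject <- function(config, group = c("NL", "PD"), id = "S01",
                             seed = config$seed) {
  group <- match.arg(group)
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    regions <- sar_names()
    vol_scales <- stats::setNames(
      exp(stats::rnorm(length(regions), 0, config$volume_jitter)), regions)
    up_scales <- stats::setNames(
      exp(stats::rnorm(length(regions), 0, config$uptake_jitter)), regions)
    mis <- config$misalignment_range
    rot <- stats::runif(3, -mis$rotation, mis$rotation)
    tra <- stats::runif(3, -mis$translation, mis$translation)

    geometry <- jitter_geometry(config$region_geometry,
                                as.list(vol_scales))
    mr_grid <- phantom_mr_grid(config)
    pet_grid <- phantom_pet_grid(config)
    true_transform <- rigid_transform(rot, tra, center = c(0, 0, 0))

    mr_pts <- voxel_coordinates(mr_grid)
    lab <- label_points(mr_pts, geometry, check = TRUE)
    dict <- sar_labels()
    missing <- regions[!dict[regions] %in% lab]
    if (length(missing))
      stop("phantom geometry error: grid too small to contain region(s) ",
           paste(missing, collapse = ", "))

    mr_int <- rep(config$mr_contrast[["background"]], nrow(mr_pts))
    brain <- in_ellipsoid(mr_pts, geometry$brain$center,
                          geometry$brain$semiaxes)
    mr_int[brain] <- config$mr_contrast[["brain"]]
    mr_int[lab %in% dict[regions]] <- config$mr_contrast[["sar"]]

    # PET samples its world grid; anatomy lives in MR space, displaced by
    # the true transform, so evaluate at T^-1(q).
    pet_pts <- voxel_coordinates(pet_grid)
    inv <- invert_transform(true_transform)
    anat_pts <- apply_transform(inv, pet_pts)
    pet_int <- uptake_at(anat_pts, geometry, config, group, up_scales)
    pet_lab <- label_points(anat_pts, geometry, check = FALSE)

    if (config$noise_sd > 0) {
      mr_int <- mr_int + stats::rnorm(length(mr_int), 0, config$noise_sd)
      pet_int <- pet_int + stats::rnorm(length(pet_int), 0, config$noise_sd)
    }

    mk_arr <- function(v, grid) array(v, dim = grid$shape)
    structure(list(
      mr = image_volume(mk_arr(mr_int, mr_grid), mr_grid$spacing,
                        mr_grid$origin, "MR"),
      pet = image_volume(mk_arr(pet_int, pet_grid), pet_grid$spacing,
                         pet_grid$origin, "PET"),
      labels_mr_space = label_map(mk_arr(lab, mr_grid), mr_grid$spacing,
                                  mr_grid$origin),
      labels_pet_space = label_map(mk_arr(pet_lab, pet_grid),
                                   pet_grid$spacing, pet_grid$origin),
      true_transform = true_transform,
      group = group, id = id, seed = seed
    ), class = "synthetic_subject")
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject %s> group %s, MR %s, PET %s\n", x$id,
              x$group, paste(dim(x$mr$data), collapse = "x"),
              paste(dim(x$pet$data), collapse = "x")))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' @param config a [phantom_config()].
#' @param n_pd,n_nl subjects per group (the emulated clinical cohort had
#'   49 PD and 18 NL).
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @return list of `synthetic_subject`s, PD first.
#' @export
generate_cohort <- function(config, n_pd = 49, n_nl = 18,
                            seed = config$seed) {
  stopifnot(n_pd >= 0, n_nl >= 0)
  n <- n_pd + n_nl
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  groups <- c(rep("PD", n_pd), rep("NL", n_nl))
  ids <- sprintf("%s%02d", groups, c(seq_len(n_pd), seq_len(n_nl)))
  lapply(seq_len(n), function(i) {
    generate_subject(config, groups[i], ids[i], seed = sub_seeds[i])
  })
}

#' Write a cohort to disk as NIfTI + manifest
#'
#' Writes `mr.nii.gz`, `pet.nii.gz`, `labels.nii.gz` per subject, a JSON
#' sidecar with the true transform and group, and a `manifest.csv`
#' (`id, group, mr_path, pet_path, labels_path`) usable by [run_pipeline()].
#'
#' @param subjects list of `synthetic_subject`s.
#' @param dir output directory (created if needed).
#' @return path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(subjects, function(s) {
    sdir <- file.path(dir, s$id)
    dir.create(sdir, showWarnings = FALSE)
    mr_path <- file.path(sdir, "mr.nii.gz")
    pet_path <- file.path(sdir, "pet.nii.gz")
    lab_path <- file.path(sdir, "labels.nii.gz")
    write_nifti(s$mr, mr_path)
    write_nifti(s$pet, pet_path)
    write_nifti(s$labels_mr_space, lab_path)
    side <- list(id = s$id, group = s$group,
                 true_transform = list(rotations = s$true_transform$rotations,
                                       translations =
                                         s$true_transform$translations,
                                       center = s$true_transform$center))
    jsonlite::write_json(side, file.path(sdir, "subject.json"),
                         auto_unbox = TRUE, digits = NA)
    data.frame(id = s$id, group = s$group, mr_path = mr_path,
               pet_path = pet_path, labels_path = lab_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
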