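# Striatal-to-occipital ratio (SOR) feature extraction.
#
# Each caudate and putamen is split into three spatially coherent
# substructures by k-means on voxel physical coordinates (mm), reordered
# anterior -> posterior so subregion indices correspond across subjects.
# Six intensity statistics (max, min, median, Q1, Q3, mean) are computed
# per region unit and normalised as SOR = (striatum - occipital)/occipital
# against the occipital statistic of the same kind; the six whole-SAR
# volumes (mm^3, original MR resolution) complete the 90-feature vector:
# 14 region units x 6 statistics + 6 volumes.

FEATURE_STATS <- c("max", "min", "median", "q1", "q3", "mean")

feature_region_units <- function() {
  units <- list()
  for (r in c("caudate_R", "caudate_L", "putamen_R", "putamen_L")) {
    for (s in 1:3) units[[paste0(r, "_sub", s)]] <-
        list(region = r, sub = s)
  }
  for (r in c("pallidum_R", "pallidum_L")) {
    units[[paste0(r, "_whole")]] <- list(region = r, sub = NA)
  }
  units
}

#' Canonical names of the 90-feature vector
#' @return character vector of length 90.
#' @export
feature_names <- function() {
  units <- names(feature_region_units())
  c(as.vector(t(outer(units, FEATURE_STATS,
                      function(u, s) paste0(u, "_", s, "_SOR")))),
    paste0(c("caudate_R", "caudate_L", "putamen_R", "putamen_L",
             "pallidum_R", "pallidum_L"), "_volume"))
}

#' Subdivide an anatomical region into k spatial substructures
#'
#' k-means on the voxel physical coordinates (mm) of the region, with 10
#' restarts; clusters are relabelled by their centroid's anterior-posterior
#' (y) coordinate, index 1 = most anterior, so indices correspond across
#' subjects with comparable anatomy.
#'
#' @param labels a [label_map()].
#' @param region_id integer label code of the parent region.
#' @param k number of substructures (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @return A `sub_region_partition`: list with `parent_label`, `assignment`
#'   (integer subregion index per region voxel, in voxel storage order),
#'   `voxels` (flat indices into the label grid), and `centroids`
#'   (k x 3 mm, ordered anterior to posterior).
#' @export
subdivide_region <- function(labels, region_id, k = 3L, seed = 1L) {
  vox <- which(labels$data == region_id)
  if (length(vox) == 0)
    stop("region ", region_id, " is empty: cannot subdivide")
  if (length(vox) < k)
    stop("region ", region_id, " has ", length(vox),
         " voxels, fewer than k = ", k)
  coords <- voxel_coordinates(labels)[vox, , drop = FALSE]
  if (nrow(unique(coords)) < k)
    stop("region ", region_id, " has fewer than k distinct voxel positions")
  km <- with_seed(seed, {
    for (attempt in 1:5) {
      res <- tryCatch(
        suppressWarnings(stats::kmeans(coords, centers = k, nstart = 10,
                                       iter.max = 100)),
        error = function(e) NULL)
      if (!is.null(res) && all(res$size > 0)) break
    }
    if (is.null(res)) stop("k-means failed to produce ", k,
                           " nonempty clusters for region ", region_id)
    res
  })
  ord <- order(km$centers[, 2], decreasing = TRUE)  # anterior (+y) first
  relabel <- match(seq_len(k), ord)
  centroids <- km$centers[ord, , drop = FALSE]
  dimnames(centroids) <- NULL
  structure(list(parent_label = region_id,
                 assignment = relabel[km$cluster],
                 voxels = vox,
                 centroids = centroids),
            class = "sub_region_partition")
}

#' Six intensity statistics of a voxel set
#'
#' @param pet an [image_volume()].
#' @param voxel_set integer (flat) voxel indices.
#' @param region label used in error messages.
#' @return named numeric: `max, min, median, q1, q3, mean` (quantiles by
#'   linear interpolation between order statistics, R type 7).
#' @export
region_statistics <- function(pet, voxel_set, region = "region") {
  if (length(voxel_set) == 0)
    stop("empty voxel set for ", region, ": no statistics defined")
  v <- pet$data[voxel_set]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(max = max(v), min = min(v), median = q[2], q1 = q[1], q3 = q[3],
    mean = mean(v))
}

#' Striatal-to-occipital ratio
#'
#' `(striatum - occipital) / occipital`, the reference-region normalisation
#' of tracer uptake.
#'
#' @param stat_region statistic of the striatal region.
#' @param stat_occipital matching statistic of the occipital reference;
#'   must be positive.
#' @return scalar SOR (vectorised over inputs).
#' @export
sor <- function(stat_region, stat_occipital) {
  if (any(stat_occipital <= 0))
    stop("occipital reference statistic is nonpositive; ",
         "reference region invalid")
  (stat_region - stat_occipital) / stat_occipital
}

#' Volume of a labelled region in mm^3
#'
#' Voxel count times voxel volume, computed on the original-resolution MR
#' label map (no downsampling).
#'
#' @param labels a [label_map()].
#' @param region_id integer label code.
#' @param spacing voxel spacing override (defaults to the map's).
#' @return volume in mm^3 (0 with a warning if the region is absent).
#' @export
region_volume <- function(labels, region_id, spacing = labels$spacing) {
  n <- sum(labels$data == region_id)
  if (n == 0) {
    warning("region ", region_id, " absent from label map; volume 0")
    return(0)
  }
  n * prod(spacing)
}

#' Extract the 90-feature SOR vector of one subject
#'
#' 84 SOR features (2 caudates x 3 subregions + 2 putamens x 3 subregions +
#' 2 whole pallida, times 6 statistics, each normalised against the
#' occipital statistic of the same kind) plus the 6 whole-SAR volumes from
#' the MR-resolution label map.
#'
#' @param pet PET [image_volume()].
#' @param pet_labels [label_map()] on the PET grid with the 6 SARs and the
#'   occipital reference.
#' @param mr_labels [label_map()] on the MR grid with the 6 SARs (volume
#'   source).
#' @param seed RNG seed for the k-means subdivisions.
#' @param id,group optional subject metadata carried along.
#' @param occ_mode `"per_stat"` (default: denominator is the occipital
#'   statistic of the same kind) or `"mean"` (always the occipital mean).
#' @return A `feature_vector`: named numeric of length 90 with attributes
#'   `id`, `group`, and `partitions` (the four [subdivide_region()]
#'   results, for importance mapping).
#' @export
extract_features <- function(pet, pet_labels, mr_labels, seed = 1L,
                             id = NULL, group = NULL,
                             occ_mode = c("per_stat", "mean")) {
  occ_mode <- match.arg(occ_mode)
  stopifnot(inherits(pet, "image_volume"),
            inherits(pet_labels, "label_map"),
            inherits(mr_labels, "label_map"))
  if (!same_grid(pet, pet_labels))
    stop("PET image and PET label map are on different grids")
  dict <- pet_labels$labels
  present <- unique(as.vector(pet_labels$data))
  if (!dict[["occipital"]] %in% present)
    stop("missing occipital reference label in PET label map")
  empty <- sar_names()[!dict[sar_names()] %in% present]
  if (length(empty))
    stop("empty SAR(s) in PET label map: ", paste(empty, collapse = ", "))

  occ_vox <- which(pet_labels$data == dict[["occipital"]])
  occ_stats <- region_statistics(pet, occ_vox, "occipital")

  units <- feature_region_units()
  partitions <- list()
  sub_regions <- c("caudate_R", "caudate_L", "putamen_R", "putamen_L")
  for (i in seq_along(sub_regions)) {
    r <- sub_regions[i]
    partitions[[r]] <- subdivide_region(pet_labels, dict[[r]], k = 3L,
                                        seed = seed + i)
  }
  vals <- numeric(0)
  for (un in names(units)) {
    u <- units[[un]]
    vox <- if (is.na(u$sub)) {
      which(pet_labels$data == dict[[u$region]])
    } else {
      p <- partitions[[u$region]]
      p$voxels[p$assignment == u$sub]
    }
    st <- region_statistics(pet, vox, un)
    denom <- if (occ_mode == "per_stat") occ_stats else
      rep(occ_stats[["mean"]], length(st))
    vals <- c(vals, sor(st, denom))
  }
  vols <- vapply(c("caudate_R", "caudate_L", "putamen_R", "putamen_L",
                   "pallidum_R", "pallidum_L"), function(r) {
    region_volume(mr_labels, mr_labels$labels[[r]])
  }, numeric(1))
  out <- stats::setNames(c(vals, vols), feature_names())
  structure(out, id = id, group = group, partitions = partitions,
            class = c("feature_vector", "numeric"))
}

#' Assemble per-subject feature vectors into a feature table
#'
#' @param vectors list of `feature_vector`s (from [extract_features()]).
#' @param ids,groups optional overrides of the per-vector metadata.
#' @return data.frame with `id`, `group`, then the 90 features
#'   (class `feature_table`).
#' @export
feature_table <- function(vectors, ids = NULL, groups = NULL) {
  n <- length(vectors)
  ids <- ids %||% vapply(vectors, function(v) attr(v, "id") %||% NA_character_,
                         character(1))
  groups <- groups %||% vapply(vectors,
                               function(v) attr(v, "group") %||%
                                 NA_character_, character(1))
  mat <- do.call(rbind, lapply(vectors, as.numeric))
  colnames(mat) <- feature_names()
  out <- data.frame(id = ids, group = groups, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_matrix <- function(table) {
  as.matrix(table[, feature_names(), drop = FALSE])
}

#' Write / read a feature table as CSV
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return the table (read) or the path (write), invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(feature_names(), colnames(out))
  if (length(missing))
    stop("feature CSV lacks column(s): ", paste(missing, collapse = ", "))
  class(out) <- c("feature_table", "data.frame")
  out
}
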