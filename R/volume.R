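#' @useDynLib pdstriatum, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical label dictionary for the striatal anatomy
#'
#' Integer codes for the six striatal anatomical regions (SARs; bilateral
#' caudate nucleus, putamen and pallidum), the parieto-occipital reference
#' region used for SOR normalisation, and background.
#'
#' @return Named integer vector mapping region names to label codes.
#' @export
sar_labels <- function() {
  c(background = 0L,
    caudate_R = 1L, caudate_L = 2L,
    putamen_R = 3L, putamen_L = 4L,
    pallidum_R = 5L, pallidum_L = 6L,
    occipital = 7L)
}

#' The six SAR region names (no background, no reference region)
#' @return Character vector of length 6 in canonical order.
#' @export
sar_names <- function() {
  c("caudate_R", "caudate_L", "putamen_R", "putamen_L",
    "pallidum_R", "pallidum_L")
}

#' Construct a 3D image volume
#'
#' A scalar 3D grid with voxel spacing and origin in mm under the RAS
#' (Right-Anterior-Superior) axis convention, plus a modality tag. World
#' coordinates of voxel (i,j,k) (0-based) are `origin + c(i,j,k) * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm per axis (length 3).
#' @param origin world coordinate of voxel (0,0,0) in mm (length 3).
#' @param modality "MR" or "PET" (or "other").
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = c("MR", "PET", "other")) {
  modality <- match.arg(modality)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            length(origin) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), modality = modality),
            class = "image_volume")
}

#' Construct a label map aligned to an image grid
#'
#' @param data 3D integer array of label codes.
#' @param spacing,origin grid geometry as in [image_volume()].
#' @param labels named integer label dictionary; defaults to [sar_labels()].
#' @return A `label_map` object.
#' @export
label_map <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      labels = sar_labels()) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            length(origin) == 3L)
  storage.mode(data) <- "integer"
  extra <- setdiff(unique(as.vector(data)), unname(labels))
  if (length(extra)) {
    stop("label map contains codes absent from the dictionary: ",
         paste(extra, collapse = ", "))
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), labels = labels),
            class = "label_map")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, origin %s mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  present <- sort(unique(as.vector(x$data)))
  cat(sprintf("<label_map> %s voxels, labels present: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(present, collapse = ", ")))
  invisible(x)
}

#' Grid descriptor of a volume or label map
#' @param x an `image_volume` or `label_map`.
#' @return list with `shape`, `spacing`, `origin`.
#' @export
grid_of <- function(x) {
  list(shape = dim(x$data), spacing = x$spacing, origin = x$origin)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' World coordinates of every voxel centre
#'
#' @param grid a grid descriptor (list with shape/spacing/origin) or an
#'   object accepted by [grid_of()].
#' @return n x 3 matrix of mm coordinates, voxel index varying fastest along
#'   the first axis (column-major, matching `as.vector` on the array).
#' @export
voxel_coordinates <- function(grid) {
  if (!is.null(grid$data)) grid <- grid_of(grid)
  sh <- grid$shape
  i <- (seq_len(sh[1]) - 1) * grid$spacing[1] + grid$origin[1]
  j <- (seq_len(sh[2]) - 1) * grid$spacing[2] + grid$origin[2]
  k <- (seq_len(sh[3]) - 1) * grid$spacing[3] + grid$origin[3]
  cbind(rep(i, times = sh[2] * sh[3]),
        rep(rep(j, each = sh[1]), times = sh[3]),
        rep(k, each = sh[1] * sh[2]))
}
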