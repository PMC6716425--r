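# Minimal NIfTI-1 I/O.
#
# The pipeline only needs axis-aligned RAS volumes written by itself (or by
# any tool emitting a diagonal sform), so this reader/writer covers exactly
# that: single-frame 3D volumes, little-endian, datatypes uint8/int16/int32/
# float32/float64, optional gzip (.nii.gz through a gz connection). Oblique
# or flipped sforms are rejected rather than silently reoriented.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume or label map as NIfTI-1
#'
#' Images are stored as float32, label maps as int16, with a diagonal RAS
#' sform built from the grid's spacing and origin. A `.gz` suffix triggers
#' gzip compression. The 352-byte header (348 + extension flag) is assembled
#' in a raw buffer and written in one pass so gz connections never need to
#' seek.
#'
#' @param x an `image_volume` or `label_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "label_map"))
  is_label <- inherits(x, "label_map")
  datatype <- if (is_label) 4L else 16L
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  sh <- dim(x$data)

  hdr <- raw(352)  # 348-byte header + 4-byte extension flag
  put <- function(buf, offset, values, size, type = "integer") {
    b <- writeBin(if (type == "integer") as.integer(values)
                  else as.numeric(values),
                  raw(), size = size, endian = "little")
    buf[(offset + 1):(offset + length(b))] <- b
    buf
  }
  hdr <- put(hdr, 0, 348L, 4)                              # sizeof_hdr
  hdr <- put(hdr, 40, c(3L, sh, 1L, 1L, 1L, 1L), 2)        # dim
  hdr <- put(hdr, 70, datatype, 2)                         # datatype
  hdr <- put(hdr, 72, dt$bitpix, 2)                        # bitpix
  hdr <- put(hdr, 76, c(1, x$spacing, 1, 1, 1, 1), 4, "double")  # pixdim
  hdr <- put(hdr, 108, 352, 4, "double")                   # vox_offset
  hdr <- put(hdr, 112, 1, 4, "double")                     # scl_slope
  hdr[124] <- as.raw(2L)                                   # xyzt_units: mm
  hdr <- put(hdr, 252, 0L, 2)                              # qform_code
  hdr <- put(hdr, 254, 1L, 2)                              # sform_code
  hdr <- put(hdr, 280, c(x$spacing[1], 0, 0, x$origin[1]), 4, "double")
  hdr <- put(hdr, 296, c(0, x$spacing[2], 0, x$origin[2]), 4, "double")
  hdr <- put(hdr, 312, c(0, 0, x$spacing[3], x$origin[3]), 4, "double")
  magic <- charToRaw("n+1")
  hdr[345:347] <- magic

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  if (dt$what == "integer") {
    writeBin(as.integer(as.vector(x$data)), con, size = dt$size,
             endian = "little")
  } else {
    writeBin(as.numeric(as.vector(x$data)), con, size = dt$size,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset written by [write_nifti()]: 3D, little-endian,
#' axis-aligned positive-diagonal (RAS) sform. When `as_labels = TRUE` the
#' result is a [label_map()]; otherwise an [image_volume()].
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as_labels read as integer label map.
#' @param modality modality tag for image volumes.
#' @param labels label dictionary for label maps.
#' @return an `image_volume` or `label_map`.
#' @export
read_nifti <- function(path, as_labels = FALSE, modality = "other",
                       labels = sar_labels()) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  geti <- function(offset, size, n = 1) {
    readBin(hdr[(offset + 1):(offset + size * n)], "integer", n = n,
            size = size, endian = "little")
  }
  getf <- function(offset, n = 1) {
    readBin(hdr[(offset + 1):(offset + 4 * n)], "double", n = n,
            size = 4, endian = "little")
  }
  if (geti(0, 4) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dims <- geti(40, 2, 8)
  if (dims[1] != 3 && !(dims[1] > 3 && all(dims[(dims[1] + 1):8 + 1] <= 1))) {
    stop("only 3D volumes are supported (dim[0] = ", dims[1], ")")
  }
  sh <- dims[2:4]
  datatype <- geti(70, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  vox_offset <- getf(108)
  scl_slope <- getf(112); scl_inter <- getf(116)
  sform_code <- geti(254, 2)
  if (sform_code > 0) {
    srow <- rbind(getf(280, 4), getf(296, 4), getf(312, 4))
    off_diag <- srow[1:3, 1:3]; diag(off_diag) <- 0
    if (max(abs(off_diag)) > 1e-4 * max(abs(srow[1:3, 1:3])) ||
        any(diag(srow[1:3, 1:3]) <= 0)) {
      stop("non-axis-aligned or non-RAS sform in ", path,
           "; reorient to RAS first")
    }
    spacing <- diag(srow[1:3, 1:3])
    origin <- srow[, 4]
  } else {
    spacing <- getf(76, 8)[2:4]
    origin <- c(0, 0, 0)
  }
  if (vox_offset > 348) readBin(con, raw(), n = vox_offset - 348)
  n <- prod(sh)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (!as_labels && is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- array(vals, dim = sh)
  if (as_labels) {
    label_map(arr, spacing, origin, labels = labels)
  } else {
    image_volume(arr, spacing, origin, modality = modality)
  }
}
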