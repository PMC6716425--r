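#' Rigid body transform (6 parameters)
#'
#' Maps world points p (mm) to `R (p - center) + center + translations`,
#' where R is the rotation composed as Rz %*% Ry %*% Rx from the three
#' angles in degrees about the image axes.
#'
#' @param rotations angles in degrees about x, y, z (length 3).
#' @param translations offsets in mm (length 3).
#' @param center rotation centre in mm (length 3).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0),
                            translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotations) == 3L, length(translations) == 3L,
            length(center) == 3L)
  structure(list(rotations = as.numeric(rotations),
                 translations = as.numeric(translations),
                 center = as.numeric(center)),
            class = c("rigid_transform", "spatial_transform"))
}

#' Affine transform (12 parameters)
#'
#' Maps world points p (mm) to `matrix %*% p + translations`.
#'
#' @param matrix invertible 3x3 linear part.
#' @param translations offsets in mm (length 3).
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(matrix = diag(3), translations = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(matrix)) <= 1e-9) stop("affine matrix is numerically singular")
  structure(list(matrix = matrix, translations = as.numeric(translations)),
            class = c("affine_transform", "spatial_transform"))
}

rotation_matrix <- function(rotations_deg) {
  a <- rotations_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler angles (deg, Rz Ry Rx convention) from a rotation matrix.
euler_from_matrix <- function(R) {
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock; fold everything into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Homogeneous 4x4 matrix of a transform
#' @param transform a `rigid_transform` or `affine_transform`.
#' @return 4x4 matrix acting on homogeneous world coordinates (mm).
#' @export
transform_matrix <- function(transform) {
  if (inherits(transform, "rigid_transform")) {
    R <- rotation_matrix(transform$rotations)
    t <- transform$center + transform$translations - R %*% transform$center
    A <- R
  } else if (inherits(transform, "affine_transform")) {
    A <- transform$matrix
    t <- transform$translations
  } else stop("not a spatial transform")
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- t
  M
}

#' Apply a transform to points
#' @param transform a spatial transform.
#' @param points n x 3 matrix of mm coordinates (or length-3 vector).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, 1, 3)
  M <- transform_matrix(transform)
  out <- points %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], nrow(points), 3, byrow = TRUE)
  if (vec) out[1, ] else out
}

#' Invert a spatial transform
#' @param transform a `rigid_transform` or `affine_transform`.
#' @return transform of the same class (rigid keeps its rotation centre).
#' @export
invert_transform <- function(transform) {
  M <- solve(transform_matrix(transform))
  if (inherits(transform, "rigid_transform")) {
    R <- M[1:3, 1:3]
    c0 <- transform$center
    # solve t from: M p = R (p - c) + c + t
    t <- M[1:3, 4] - (c0 - R %*% c0)
    rigid_transform(euler_from_matrix(R), as.numeric(t), c0)
  } else {
    affine_transform(M[1:3, 1:3], M[1:3, 4])
  }
}

#' Compose two transforms (apply `first`, then `second`)
#' @param second,first spatial transforms.
#' @return an `affine_transform` equal to second o first.
#' @export
compose_transforms <- function(second, first) {
  M <- transform_matrix(second) %*% transform_matrix(first)
  affine_transform(M[1:3, 1:3], M[1:3, 4])
}

#' Promote a rigid transform to its affine representation
#' @param rigid a `rigid_transform`.
#' @return equivalent `affine_transform`.
#' @export
as_affine <- function(rigid) {
  M <- transform_matrix(rigid)
  affine_transform(M[1:3, 1:3], M[1:3, 4])
}

#' Serialize / deserialize transforms as JSON
#'
#' @param transform a spatial transform.
#' @param path file path.
#' @return `read_transform` returns the transform; `write_transform` its path.
#' @export
write_transform <- function(transform, path) {
  x <- unclass(transform)
  x$type <- if (inherits(transform, "rigid_transform")) "rigid" else "affine"
  if (!is.null(x$matrix)) x$matrix <- as.vector(x$matrix)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$type, "rigid")) {
    rigid_transform(x$rotations, x$translations, x$center)
  } else {
    affine_transform(matrix(x$matrix, 3, 3), x$translations)
  }
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid> rot (deg): %s; trans (mm): %s; center: %s\n",
              paste(format(x$rotations, digits = 4), collapse = ", "),
              paste(format(x$translations, digits = 4), collapse = ", "),
              paste(format(x$center, digits = 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine> matrix:\n")
  print(x$matrix)
  cat("trans (mm):", paste(format(x$translations, digits = 4),
                           collapse = ", "), "\n")
  invisible(x)
}
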