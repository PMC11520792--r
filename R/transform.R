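#' Proper rigid transform
#'
#' A rotation (3x3 orthonormal, determinant +1) plus a translation
#' (mm), mapping source coordinates into the target frame as
#' `R x + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector, mm.
#' @param tol orthonormality tolerance.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (length(translation) != 3) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  # re-orthonormalise through SVD so composed transforms do not drift
  s <- svd(rotation)
  rotation <- s$u %*% t(s$v)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: angle %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              rotation_angle(x), x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points `n x 3` matrix of coordinates.
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform that applies `b`
#' first, then `a` (matrix convention `a %*% b`).
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*% transform$translation))
}

#' Rotation angle of a transform, degrees
#' @param transform a [rigid_transform()].
#' @return Rotation magnitude in degrees (axis-angle representation).
#' @export
rotation_angle <- function(transform) {
  ctheta <- (sum(diag(transform$rotation)) - 1) / 2
  acos(max(-1, min(1, ctheta))) * 180 / pi
}

#' Rotation matrix about an axis
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Serialize / restore a transform as a homogeneous 4x4 JSON matrix
#'
#' Written row-major under key `matrix_4x4_row_major` so the layout is
#' unambiguous for other tools.
#' @param transform a [rigid_transform()].
#' @param path file path for the JSON output.
#' @return `write_transform` the path invisibly; `read_transform` the
#'   restored [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(matrix_4x4_row_major = as.vector(t(m)), units = "mm"),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(obj$matrix_4x4_row_major, 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}
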