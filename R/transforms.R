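#' Rigid transform
#'
#' A proper rigid motion: 3x3 rotation (orthonormal, det +1) plus a
#' translation in mm. Composition and inversion stay within the class.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (length(translation) != 3) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det +1); reflections are not rigid motions")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Build a rigid transform from Euler angles
#'
#' Rotations are applied in x, then y, then z order (intrinsic frame fixed),
#' angles in degrees.
#'
#' @param angles_deg numeric length-3, rotation about x, y, z axes (degrees).
#' @param translation numeric length-3 (mm).
#' @export
rt_from_angles <- function(angles_deg = c(0, 0, 0), translation = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  rigid_transform(rz %*% ry %*% rx, translation)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform that applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x a `rigid_transform`.
#' @export
rt_invert <- function(x) {
  rigid_transform(t(x$rotation), as.numeric(-t(x$rotation) %*% x$translation))
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x a `rigid_transform`.
#' @param obj an n x 3 matrix of points, a length-3 vector, or a
#'   `triangle_mesh`.
#' @return the transformed object, same type as the input.
#' @export
rt_apply <- function(x, obj) {
  if (inherits(obj, "triangle_mesh")) {
    obj$vertices <- rt_apply(x, obj$vertices)
    return(obj)
  }
  if (is.null(dim(obj))) return(as.numeric(x$rotation %*% obj + x$translation))
  t(x$rotation %*% t(obj) + x$translation)
}

#' Serialize / read a rigid transform as 12 numbers
#'
#' Row-major 3x3 rotation followed by the translation, one value per token,
#' plain text. The format round-trips exactly at full double precision.
#'
#' @param x a `rigid_transform`; `path` a file path.
#' @export
write_transform <- function(x, path) {
  vals <- c(t(x$rotation), x$translation)
  writeLines(paste(sprintf("%.17g", vals), collapse = " "), path)
  invisible(path)
}

#' @rdname write_transform
#' @param path file previously written by [write_transform()].
#' @export
read_transform <- function(path) {
  vals <- scan(path, quiet = TRUE)
  if (length(vals) != 12) stop("transform file must contain 12 numbers")
  rigid_transform(matrix(vals[1:9], 3, 3, byrow = TRUE), vals[10:12])
}
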