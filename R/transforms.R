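#' Construct a rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthogonal, det +1).
#' @param translation numeric(3), mm.
#' @param label one of `"DICOM"`, `"ESTIMATE"`, `"OPTIMAL"`.
#' @return A [RigidTransform-class].
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           label = "DICOM") {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), label = label)
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points an n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return An n x 3 matrix of transformed points.
#' @export
transformPoints <- function(transform, points) {
  p <- rbind3(points)
  out <- p %*% t(transform@rotation)
  sweep(out, 2L, transform@translation, "+")
}

#' Compose two rigid transforms
#'
#' `composeTransform(a, b)` maps `x` to `a(b(x))`.
#'
#' @param a,b [RigidTransform-class] objects.
#' @param label label for the result (defaults to `a`'s).
#' @return A [RigidTransform-class].
#' @export
composeTransform <- function(a, b, label = a@label) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation,
                 label = label)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @param label label for the result (defaults to the input's).
#' @return A [RigidTransform-class].
#' @export
invertTransform <- function(transform, label = transform@label) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, as.numeric(-Rt %*% transform@translation), label = label)
}

#' Rotation matrix from per-axis angles
#'
#' Composes elemental rotations as `Rx %*% Ry %*% Rz` (applied to a column
#' vector, the z rotation acts first).  At the small angles used by the
#' perturbation search the ordering effect is negligible, but the order is
#' fixed so results are reproducible.
#'
#' @param ax,ay,az rotation angles in radians about the x, y and z axes.
#' @return A 3x3 rotation matrix.
#' @export
rotationMatrix <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# coerce a vector or matrix to an n x 3 matrix
rbind3 <- function(points) {
  if (is.null(dim(points))) matrix(points, ncol = 3L) else as.matrix(points)
}
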