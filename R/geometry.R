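# Exact geometric primitives: distances, least-squares rigid superposition,
# dihedral angles, axis rotations. Angles cross the API boundary in degrees;
# radians are used internally.

#' Euclidean distance between two points
#'
#' @param p,q numeric 3-vectors, Angstrom.
#' @return distance in Angstrom.
#' @examples
#' point_distance(c(0, 0, 0), c(0, 0, 5))
#' @export
point_distance <- function(p, q) {
  stopifnot(length(p) == 3L, length(q) == 3L)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("point_distance: inputs must be finite", call. = FALSE)
  vnorm(p - q)
}

#' Rigid transform constructor
#'
#' A proper rigid-body transform y = R x + t. The rotation must be a proper
#' orthonormal matrix (det = +1).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector, Angstrom.
#' @return an object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rigid_transform: rotation must be proper (det = +1)", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rigid_transform: rotation must be orthonormal", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a \code{rigid_transform}.
#' @param x an N x 3 coordinate matrix (or a single 3-vector).
#' @return transformed coordinates, same shape as \code{x}.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  out <- x %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x), 3L, byrow = TRUE)
  if (vec) out[1L, ] else out
}

#' Invert a rigid transform
#'
#' @param transform a \code{rigid_transform}.
#' @return the inverse \code{rigid_transform}.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform: rotation det =", round(det(x$rotation), 6),
      "| translation =", paste(sprintf("%.3f", x$translation), collapse = ", "),
      "\n")
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' between two paired point sets. Reflections are excluded by the usual sign
#' correction on the smallest singular vector.
#'
#' @param mobile N x 3 matrix of coordinates to be moved.
#' @param target N x 3 matrix of reference coordinates.
#' @param weights optional non-negative weights, length N. Default uniform.
#' @return a list with elements \code{transform} (a \code{rigid_transform}
#'   mapping mobile onto target) and \code{rmsd} (weighted RMSD after
#'   superposition, Angstrom).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("kabsch_superpose: point counts differ", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L)
    stop("kabsch_superpose: need at least 3 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("kabsch_superpose: invalid weights", call. = FALSE)
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(target, 2L, ct)

  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-30))
    stop("kabsch_superpose: degenerate (collinear or coincident) point set",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ct - as.numeric(R %*% cm)
  tr <- rigid_transform(R, t_vec)

  moved <- apply_transform(tr, mobile)
  rmsd <- sqrt(sum(w * rowSums((moved - target)^2)))
  list(transform = tr, rmsd = rmsd)
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: with b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3,
#' n1 = b1 x b2, n2 = b2 x b3, the angle is
#' atan2((n1 x n2) . unit(b2), n1 . n2), reported in degrees on (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return the dihedral angle in degrees, in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))  # 0 (cis)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b2) < 1e-9)
    stop("dihedral_angle: p2 and p3 coincide", call. = FALSE)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("dihedral_angle: undefined dihedral (collinear points)", call. = FALSE)
  m <- cross3(n1, n2)
  ang <- atan2(sum(m * unit(b2)), sum(n1 * n2))
  wrap_angle(rad2deg(ang))
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotate points about an arbitrary axis
#'
#' Rodrigues rotation of a point set about the axis through
#' \code{axis_point} with direction \code{axis_dir}.
#'
#' @param points N x 3 coordinate matrix (or a 3-vector).
#' @param axis_point a point on the rotation axis, Angstrom.
#' @param axis_dir axis direction (need not be unit length, must be nonzero).
#' @param angle rotation angle in degrees.
#' @return rotated coordinates, same shape as \code{points}.
#' @export
rotate_about_axis <- function(points, axis_point, axis_dir, angle) {
  if (vnorm(axis_dir) < 1e-12)
    stop("rotate_about_axis: zero-length axis", call. = FALSE)
  k <- unit(axis_dir)
  th <- deg2rad(angle)
  K <- matrix(c(0, k[3L], -k[2L],
                -k[3L], 0, k[1L],
                k[2L], -k[1L], 0), 3L, 3L)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, nrow = 1L)
  centered <- sweep(points, 2L, axis_point)
  out <- centered %*% t(R) +
    matrix(axis_point, nrow(points), 3L, byrow = TRUE)
  if (vec) out[1L, ] else out
}
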