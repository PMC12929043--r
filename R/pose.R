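# Rigid-body nucleosome poses: an oriented disc frame per nucleosome.
# The disc (superhelical) axis is the local +z of the frame ("normal"), the
# dyad axis the local +x; normal x dyad completes a right-handed frame.

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length vector cannot be normalized")
  v / nv
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix; axis any nonzero 3-vector, angle in degrees.
rotation_about <- function(axis, angle_deg) {
  a <- .unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * outer(a, a)
}

# quaternion (scalar-first) <-> rotation matrix --------------------------------

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

matrix_to_quat <- function(M) {
  tr <- M[1, 1] + M[2, 2] + M[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (M[3, 2] - M[2, 3]) / s, (M[1, 3] - M[3, 1]) / s,
           (M[2, 1] - M[1, 2]) / s)
  } else if (M[1, 1] > M[2, 2] && M[1, 1] > M[3, 3]) {
    s <- sqrt(1 + M[1, 1] - M[2, 2] - M[3, 3]) * 2
    q <- c((M[3, 2] - M[2, 3]) / s, 0.25 * s, (M[1, 2] + M[2, 1]) / s,
           (M[1, 3] + M[3, 1]) / s)
  } else if (M[2, 2] > M[3, 3]) {
    s <- sqrt(1 + M[2, 2] - M[1, 1] - M[3, 3]) * 2
    q <- c((M[1, 3] - M[3, 1]) / s, (M[1, 2] + M[2, 1]) / s, 0.25 * s,
           (M[2, 3] + M[3, 2]) / s)
  } else {
    s <- sqrt(1 + M[3, 3] - M[1, 1] - M[2, 2]) * 2
    q <- c((M[2, 1] - M[1, 2]) / s, (M[1, 3] + M[3, 1]) / s,
           (M[2, 3] + M[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# n uniform random rotations as an n x 4 quaternion matrix (scalar-first).
random_quaternions <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

#' Construct a nucleosome pose
#'
#' A pose is the rigid-body placement of one nucleosome: a center (nm) plus an
#' orthonormal right-handed disc frame given by the disc normal (superhelical
#' axis, local +z) and the dyad axis (local +x).
#'
#' @param center Numeric 3-vector, nm.
#' @param normal Unit 3-vector, the disc/superhelical axis.
#' @param dyad Unit 3-vector perpendicular to `normal`; if `NULL` an arbitrary
#'   perpendicular direction is chosen.
#' @param id Integer identifier.
#' @return An object of class `nucleosome_pose`.
#' @export
#' @examples
#' p <- nucleosome_pose(c(0, 0, 0), c(0, 0, 1))
#' plane_angle(p, nucleosome_pose(c(10, 0, 0), c(1, 0, 0)))
nucleosome_pose <- function(center, normal, dyad = NULL, id = 1L) {
  center <- as.numeric(center)
  normal <- as.numeric(normal)
  stopifnot(length(center) == 3, length(normal) == 3)
  if (is.null(dyad)) {
    ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    dyad <- .unit(.cross(ref, normal))
  }
  dyad <- as.numeric(dyad)
  p <- structure(list(center = center, normal = normal, dyad = dyad,
                      id = as.integer(id)), class = "nucleosome_pose")
  validate_pose(p)
  p
}

#' @rdname nucleosome_pose
#' @param p A `nucleosome_pose`.
#' @param tol Numeric tolerance on unit length and orthogonality.
#' @export
validate_pose <- function(p, tol = 1e-9) {
  if (!inherits(p, "nucleosome_pose")) stop("not a nucleosome_pose")
  if (abs(sqrt(sum(p$normal^2)) - 1) > tol) stop("normal is not a unit vector")
  if (abs(sqrt(sum(p$dyad^2)) - 1) > tol) stop("dyad is not a unit vector")
  if (abs(sum(p$normal * p$dyad)) > tol) stop("dyad is not perpendicular to normal")
  invisible(p)
}

#' @export
print.nucleosome_pose <- function(x, ...) {
  cat(sprintf("nucleosome pose #%d  center (%.2f, %.2f, %.2f) nm\n",
              x$id, x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  normal (%.3f, %.3f, %.3f)  dyad (%.3f, %.3f, %.3f)\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$dyad[1], x$dyad[2], x$dyad[3]))
  invisible(x)
}

# vectorized folded plane angle between rows of two normal matrices, degrees
vplane_angle <- function(n1, n2) {
  d <- abs(rowSums(n1 * n2))
  acos(pmin(1, d)) * 180 / pi
}

#' Plane angle between two nucleosome discs
#'
#' Folded angle between the disc planes of two nucleosomes, in degrees on
#' \[0, 90\]: 0 means parallel discs, 90 perpendicular.  Invariant to flipping
#' either disc normal.
#'
#' @param a,b `nucleosome_pose` objects.
#' @return Angle in degrees in \[0, 90\].
#' @export
plane_angle <- function(a, b) {
  validate_pose(a); validate_pose(b)
  acos(min(1, abs(sum(a$normal * b$normal)))) * 180 / pi
}

#' Signed dihedral angle between adjacent nucleosome planes
#'
#' Both disc normals are projected onto the plane perpendicular to
#' `direction`; the returned value is the angle from the projection of
#' `a$normal` to that of `b$normal` about `direction` (right-hand rule),
#' mapped to \[0, 360).  `direction` should be the unit vector from
#' `a$center` toward `b$center` in fiber order; reversing it maps the angle
#' to its 360-degree complement.
#'
#' @param a,b `nucleosome_pose` objects.
#' @param direction Unit 3-vector; defaults to the normalized center-to-center
#'   vector from `a` to `b`.
#' @return Angle in degrees in \[0, 360).
#' @export
signed_dihedral <- function(a, b, direction = NULL) {
  validate_pose(a); validate_pose(b)
  if (is.null(direction)) direction <- b$center - a$center
  u <- .unit(as.numeric(direction))
  pa <- a$normal - sum(a$normal * u) * u
  pb <- b$normal - sum(b$normal * u) * u
  if (sqrt(sum(pa^2)) < 1e-6 || sqrt(sum(pb^2)) < 1e-6)
    stop("degenerate geometry: a disc normal is parallel to the step direction")
  ang <- atan2(sum(u * .cross(pa, pb)), sum(pa * pb)) * 180 / pi
  ang %% 360
}

# circular mean / SD of angles in degrees (full circle)
circular_mean_deg <- function(x) {
  x <- x[is.finite(x)]
  (atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi) %% 360
}

circular_sd_deg <- function(x) {
  x <- x[is.finite(x)]
  R <- sqrt(mean(sin(x * pi / 180))^2 + mean(cos(x * pi / 180))^2)
  if (R <= 0) return(Inf)
  sqrt(-2 * log(R)) * 180 / pi
}

# absolute circular difference in [0, 180]
circular_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
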