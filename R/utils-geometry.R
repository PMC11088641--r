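# Small geometric helpers shared across modules. All coordinates are in mm;
# the package-wide unit system is mm-N-MPa-tonne.

#' Normalise a vector to unit length
#' @param v numeric vector
#' @return unit vector
#' @export
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps * 100) {
    stop("cannot normalise a (near-)zero vector")
  }
  v / n
}

#' Cross product of two 3-vectors
#' @param a,b numeric 3-vectors
#' @return 3-vector `a x b`
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rodrigues rotation matrix about a unit axis
#' @param axis unit 3-vector
#' @param angle_rad rotation angle in radians (right-hand rule)
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_rad) {
  a <- unit_vec(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Rotate point rows about an axis through a point
#' @keywords internal
rotate_points <- function(pts, axis, angle_rad, origin = c(0, 0, 0)) {
  R <- rotation_about_axis(axis, angle_rad)
  sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, `+`)
}

#' Signed angle from a to b about axis n (radians)
#' @keywords internal
signed_angle <- function(a, b, n) {
  a <- unit_vec(a); b <- unit_vec(b); n <- unit_vec(n)
  atan2(sum(cross3(a, b) * n), sum(a * b))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed volumes of tetrahedra (vectorised)
#'
#' @param nodes N x 3 node coordinate matrix (mm)
#' @param tets M x 4 integer connectivity
#' @return numeric vector of signed volumes (mm^3); positive under the
#'   package node-ordering convention
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Boundary faces of a tetrahedral mesh
#'
#' Faces appearing in exactly one tetrahedron. Used for surface-node
#' extraction and the closed-manifold (Euler characteristic) checks.
#'
#' @param tets M x 4 connectivity
#' @return integer matrix (F x 3) of boundary faces (node indices)
#' @export
boundary_faces <- function(tets) {
  f <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
             tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  cnt <- stats::ave(rep(1L, length(key)), key, FUN = sum)
  f[cnt == 1L, , drop = FALSE]
}
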