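## Low-level 3D geometry: torsions, axis rotations, internal-coordinate
## placement (NeRF) and least-RMSD superposition.  Everything here works on
## plain numeric vectors/matrices in Angstrom and degrees.

#' Torsion (dihedral) angle of four points
#'
#' Computes the signed torsion angle about the b--c axis using the IUPAC sign
#' convention (clockwise rotations looking from b towards c are positive; the
#' planar trans arrangement is 180 degrees).
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Rotate points about an axis
#'
#' Rigidly rotates rows of `xyz` by `angle` degrees about the axis through
#' `origin` with direction `axis` (right-hand rule).
#'
#' @param xyz N x 3 matrix of coordinates.
#' @param origin Numeric 3-vector, a point on the axis.
#' @param axis Numeric 3-vector, axis direction (need not be unit length).
#' @param angle Rotation angle, degrees.
#' @return N x 3 matrix of rotated coordinates.
#' @export
rotate_about_axis <- function(xyz, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- matrix(c(
    ct + ux * ux * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy * uy * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz * uz * (1 - ct)
  ), nrow = 3, byrow = TRUE)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

## Natural-extension reference frame placement: position atom D given the
## three previously placed atoms A, B, C, the bond length |C-D|, the bond
## angle B-C-D (degrees) and the torsion A-B-C-D (degrees).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` (determinant +1) and translation `t`
#' minimizing the RMSD between `coords_a %*% t(R) + t` and `coords_b`.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (N >= 3), row i of
#'   `coords_a` corresponding to row i of `coords_b`.
#' @return List with `rotation` (3 x 3), `translation` (length-3) and
#'   `rmsd` (Angstrom).
#' @export
superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3 || ncol(coords_b) != 3)
    stop("superpose: coordinate sets must be N x 3 with equal N")
  n <- nrow(coords_a)
  if (n < 3) stop("superpose: need at least 3 points")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- crossprod(A, B)               # 3 x 3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)        # maps A-frame onto B-frame
  ## explicit residual (the closed-form trace expression suffers catastrophic
  ## cancellation near rmsd 0)
  rmsd <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  t_vec <- cb - as.vector(R %*% ca)
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

## Circular difference between two angles in degrees, result in [0, 180].
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
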