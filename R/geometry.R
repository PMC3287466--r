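#' Signed dihedral (torsion) angle of four points
#'
#' Computes the torsion about the `p2`--`p3` axis by the standard IUPAC
#' convention (cis = 0, trans = 180), via the atan2 of the cross/dot
#' construction, which is numerically stable for all non-degenerate
#' geometries.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstroms, any rigid frame).
#' @return Angle in degrees in the interval (-180, 180], or `NA_real_` when
#'   the geometry is degenerate (coincident consecutive points or three
#'   collinear consecutive points).
#' @examples
#' compute_dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0))  # 180
#' compute_dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))   # 0
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-20 || sum(b2^2) < 1e-20 || sum(b3^2) < 1e-20) {
    return(NA_real_)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    return(NA_real_)  # collinear triple: half-plane undefined
  }
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle in degrees into (-180, 180]
#' @param x numeric vector of angles, degrees
#' @return wrapped angles
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  # map -180 to +180 per the half-open convention
  y[!is.na(y) & y <= -180 + 1e-12 & y >= -180 - 1e-12] <- 180
  y
}

#' Minimal wrap-around angular distance in degrees
#' @param a,b angles, degrees
#' @return distance in [0, 180]
#' @export
angular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference points, places a fourth point `d` such that
#' |p3-d| = `length`, angle(p2, p3, d) = `angle` and
#' torsion(p1, p2, p3, d) = `torsion`.
#'
#' @param p1,p2,p3 reference positions (3-vectors)
#' @param length bond length p3--d, Angstroms
#' @param angle bond angle p2--p3--d, degrees
#' @param torsion torsion p1--p2--p3--d, degrees
#' @return 3-vector position of the new atom
#' @keywords internal
place_atom <- function(p1, p2, p3, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- c(-length * cos(ang),
               length * sin(ang) * cos(tor),
               length * sin(ang) * sin(tor))
  bc <- p3 - p2
  bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  p3 + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Euclidean distance matrix between two coordinate sets
#' @param a,b matrices with 3 columns (rows = atoms)
#' @return nrow(a) x nrow(b) matrix of distances in Angstroms
#' @keywords internal
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
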