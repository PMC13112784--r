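#' Vector geometry kernel
#'
#' Small set of 3-vector primitives shared by every interaction rule:
#' distances, vertex angles, best-fit ring planes and perpendicular-foot
#' projections.  All distances are in Angstrom, all angles in degrees.
#'
#' @name geometry
NULL

vnorm <- function(v) sqrt(sum(v * v))

#' Euclidean distance between two points
#'
#' @param a,b numeric 3-vectors (Angstrom).
#' @return distance in Angstrom.
#' @export
dist3 <- function(a, b) vnorm(as.numeric(a) - as.numeric(b))

#' Angle at vertex `b` formed by points `a`, `b`, `c`
#'
#' @param a,b,c numeric 3-vectors; `b` is the vertex.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_deg <- function(a, b, c) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-10 || nv < 1e-10)
    stop("angle_deg: coincident points give an undefined angle")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Centroid and best-fit plane normal of a ring
#'
#' The normal is the principal axis of least coordinate variance
#' (eigenvector of the smallest eigenvalue of the covariance of the member
#' coordinates), which is robust to slight non-planarity.  Members whose
#' out-of-plane deviation exceeds `planarity_tol` fail the planarity gate.
#'
#' @param coords numeric matrix, one row per ring member (>= 3 rows).
#' @param planarity_tol maximum allowed out-of-plane deviation (Angstrom).
#' @return list with `cn` (centroid), `normal` (unit 3-vector), `coords`,
#'   and `radius` (mean centroid-to-member distance).
#' @export
ring_center_normal <- function(coords, planarity_tol = 0.35) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("ring_center_normal: need >= 3 atoms")
  cn <- colMeans(coords)
  centered <- sweep(coords, 2, cn)
  cv <- crossprod(centered) / nrow(coords)
  eig <- eigen(cv, symmetric = TRUE)
  if (eig$values[2] < 1e-8)
    stop("ring_center_normal: collinear members, degenerate plane")
  normal <- eig$vectors[, 3]
  normal <- normal / vnorm(normal)
  # planarity gate: each member against the best-fit plane of the others
  # (leave-one-out), so a single puckered atom is charged its full
  # displacement rather than a tilt-absorbed residual
  if (is.finite(planarity_tol) && nrow(coords) >= 4) {
    for (i in seq_len(nrow(coords))) {
      rest <- coords[-i, , drop = FALSE]
      cn_i <- colMeans(rest)
      e_i <- eigen(crossprod(sweep(rest, 2, cn_i)) / nrow(rest),
                   symmetric = TRUE)
      dev <- abs(sum((coords[i, ] - cn_i) * e_i$vectors[, 3]))
      if (dev > planarity_tol)
        stop(sprintf("ring_center_normal: member %.2f A out of plane exceeds %.2f A gate",
                     dev, planarity_tol))
    }
  }
  list(cn = cn, normal = normal, coords = coords,
       radius = mean(sqrt(rowSums(centered^2))))
}

#' Foot of the perpendicular from a point onto a plane
#'
#' @param point numeric 3-vector.
#' @param plane list with `cn` (a point on the plane) and `normal`
#'   (unit normal), as returned by [ring_center_normal()].
#' @return the projection `Nr` of `point` onto the plane.
#' @export
foot_of_perpendicular <- function(point, plane) {
  point <- as.numeric(point)
  n <- plane$normal / vnorm(plane$normal)
  point - sum((point - plane$cn) * n) * n
}

#' Dihedral angle over four points
#'
#' Signed torsion a-b-c-d in degrees, in `(-180, 180]`.
#' @param a,b,c,d numeric 3-vectors.
#' @return dihedral angle in degrees.
#' @export
dihedral_deg <- function(a, b, c, d) {
  b1 <- as.numeric(b) - as.numeric(a)
  b2 <- as.numeric(c) - as.numeric(b)
  b3 <- as.numeric(d) - as.numeric(c)
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] / vnorm(b2) - n1[3] * b2[2] / vnorm(b2),
          n1[3] * b2[1] / vnorm(b2) - n1[1] * b2[3] / vnorm(b2),
          n1[1] * b2[2] / vnorm(b2) - n1[2] * b2[1] / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
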