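# Low-level vector geometry shared by the model builder, the annealer and the
# ensemble analytics. All coordinates are in angstroms, all angles in degrees.

DEG <- 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  a / n
}

wrap_angle <- function(theta) {
  # map to (-180, 180]
  out <- (theta + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

#' Measure a dihedral (torsion) angle from four points
#'
#' Computes the signed torsion angle defined by four points using the IUPAC
#' sign convention: looking from `p2` towards `p3`, a clockwise rotation of
#' the `p3`-`p4` bond relative to the `p1`-`p2` bond is positive. The cis
#' (eclipsed) arrangement is 0 degrees and anti is 180 degrees.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors, positions in angstroms.
#' @return The torsion angle in degrees, in the interval (-180, 180].
#' @examples
#' measure_torsion(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)) # cis: 0
#' measure_torsion(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)) # -90
#' @export
measure_torsion <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == 3, length(p2) == 3, length(p3) == 3, length(p4) == 3)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-12 || vnorm(b2) < 1e-12 || vnorm(b3) < 1e-12) {
    stop("consecutive points coincide; torsion undefined", call. = FALSE)
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("collinear points; torsion undefined", call. = FALSE)
  }
  u2 <- b2 / vnorm(b2)
  theta <- atan2(sum(vcross(n1, n2) * u2), sum(n1 * n2)) * DEG
  wrap_angle(theta)
}

# Internal angle (degrees) at p2 formed by p1-p2-p3.
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(pmin(1, pmax(-1, sum(u * v)))) * DEG
}

# NeRF placement: position atom D such that |CD| = r, angle(B, C, D) = theta
# and dihedral(A, B, C, D) = chi (degrees, IUPAC convention, consistent with
# measure_torsion()).
nerf_place <- function(a, b, c, r, theta, chi) {
  th <- theta / DEG
  ph <- chi / DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Rigid transform (rotation R, translation) mapping the triple of template
# points (rows of `from`, 3 x 3) onto `to`. The two triples must be congruent;
# used to place rigid residues whose anchor atoms were positioned by NeRF.
frame_transform <- function(from, to) {
  f <- frame_basis(from)
  g <- frame_basis(to)
  r <- g %*% t(f)
  list(r = r, shift = to[1, ] - as.vector(r %*% from[1, ]))
}

frame_basis <- function(p) {
  e1 <- vunit(p[2, ] - p[1, ])
  v <- p[3, ] - p[1, ]
  e2 <- vunit(v - sum(v * e1) * e1)
  e3 <- vcross(e1, e2)
  cbind(e1, e2, e3)
}

# Rotate the rows of xyz indexed by `idx` about the axis through points a -> b
# by `angle` degrees (right-handed about the a->b direction).
rotate_about_axis <- function(xyz, idx, a, b, angle) {
  if (length(idx) == 0 || abs(angle) < 1e-12) return(xyz)
  k <- vunit(b - a)
  th <- angle / DEG
  ct <- cos(th)
  st <- sin(th)
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  r <- diag(3) * ct + st * kx + (1 - ct) * (k %o% k)
  sub <- xyz[idx, , drop = FALSE]
  sub <- sweep(sub, 2, a)
  sub <- sub %*% t(r)
  xyz[idx, ] <- sweep(sub, 2, a, `+`)
  xyz
}

# Vectorised torsion over an n x 12 matrix of point rows (p1 | p2 | p3 | p4),
# used in hot loops (ring checks over ensembles).
measure_torsion_many <- function(p) {
  b1 <- p[, 4:6, drop = FALSE] - p[, 1:3, drop = FALSE]
  b2 <- p[, 7:9, drop = FALSE] - p[, 4:6, drop = FALSE]
  b3 <- p[, 10:12, drop = FALSE] - p[, 7:9, drop = FALSE]
  cr <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  u2 <- b2 / sqrt(rowSums(b2^2))
  y <- rowSums(cr(n1, n2) * u2)
  x <- rowSums(n1 * n2)
  wrap_angle(atan2(y, x) * DEG)
}
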