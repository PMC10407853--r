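#' @keywords internal
vnorm <- function(v) sqrt(sum(v^2))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed torsion angle
#'
#' Dihedral p1-p2-p3-p4 with the IUPAC sign convention: looking down the
#' p2->p3 bond, a clockwise rotation of the far bond relative to the near
#' bond is positive. Range (-180, 180]; trans is reported as 180.
#'
#' @param p1,p2,p3,p4 Numeric xyz coordinates (Angstrom).
#' @return Signed angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined torsion: three consecutive points are collinear")
  ang <- atan2(sum(vcross(n1, n2) * b2) / vnorm(b2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  # map -180 to the trans convention
  if (identical(ang, -180)) ang <- 180
  ang
}

#' Least-squares plane and maximum deviation
#'
#' Fits the plane minimizing the sum of squared orthogonal distances
#' (smallest principal component of the centred coordinates) and reports
#' the signed deviations of the points along the unit normal.
#'
#' @param points Numeric n x 3 matrix, n >= 3.
#' @return List with `normal` (unit vector), `centroid`, `deviations`
#'   (signed, Angstrom), `max_deviation` (absolute) and `which_max`.
#' @export
lsq_plane <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate plane fit: points are collinear")
  n <- sv$v[, 3]
  dev <- drop(x %*% n)
  list(normal = n, centroid = ctr, deviations = dev,
       max_deviation = max(abs(dev)), which_max = which.max(abs(dev)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `x` onto `y` by the Kabsch algorithm
#' with SVD sign correction, so reflections are never introduced:
#' chirality is preserved and mirror-image templates must be supplied
#' explicitly.
#'
#' @param x,y Equal-size n x 3 coordinate matrices (n >= 3, not collinear).
#' @return Object of class `"superposition"`: `rotation` (3 x 3 proper
#'   orthogonal), `translation` (applied after rotation), `rmsd`
#'   (Angstrom). The fitted coordinates are
#'   `x %*% t(rotation) + translation` row-wise.
#' @examples
#' x <- matrix(rnorm(15), 5, 3)
#' superpose(x, x)$rmsd
#' @export
superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3)
  if (nrow(x) != nrow(y)) stop("point sets differ in size")
  if (nrow(x) < 3) stop("need at least 3 point pairs")
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  if (svd(x0)$d[2] < 1e-9 || svd(y0)$d[2] < 1e-9)
    stop("degenerate configuration: points are collinear")
  h <- crossprod(x0, y0)            # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  r <- sv$v %*% s %*% t(sv$u)       # y ~ x %*% t(r)
  fitted <- x0 %*% t(r)
  rmsd <- sqrt(mean(rowSums((fitted - y0)^2)))
  structure(list(rotation = r,
                 translation = drop(cy - cx %*% t(r)),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Hydrogen-bond geometry from donor, hydrogen and acceptor positions
#'
#' @param d,h,a Numeric xyz coordinates of donor heavy atom, hydrogen and
#'   acceptor.
#' @return List with `d_da`, `d_ha` (Angstrom) and `angle_dha` (degrees,
#'   measured at the hydrogen).
#' @examples
#' hbond_geometry(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
#' @export
hbond_geometry <- function(d, h, a) {
  if (vnorm(d - a) < 1e-8 || vnorm(d - h) < 1e-8 || vnorm(h - a) < 1e-8)
    stop("coincident points in hydrogen-bond geometry")
  u <- d - h; v <- a - h
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  list(d_da = vnorm(d - a), d_ha = vnorm(h - a),
       angle_dha = acos(cosang) * 180 / pi)
}

#' Pseudo-cycle size closed by a hydrogen bond
#'
#' The size of the ring formed when the H...acceptor contact closes a
#' cycle through the covalent framework: the number of atoms on the
#' shortest covalent path from the acceptor to the donor hydrogen,
#' inclusive of both. A size of 10 is the classical beta-turn C10 motif;
#' 7 is a gamma turn.
#'
#' @param mol A [molecule()] with bonds.
#' @param donor_h Index (1-based) of the donor hydrogen.
#' @param acceptor Index of the acceptor heavy atom.
#' @return Integer ring size.
#' @export
hbond_ring_size <- function(mol, donor_h, acceptor) {
  stopifnot(inherits(mol, "fm_molecule"))
  n <- nrow(mol$atoms)
  stopifnot(donor_h >= 1, donor_h <= n, acceptor >= 1, acceptor <= n)
  if (mol$atoms$element[donor_h] != "H")
    stop("donor_h must be a hydrogen atom")
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  dmat <- igraph::distances(g, v = acceptor, to = donor_h)
  if (!is.finite(dmat[1, 1]))
    stop("acceptor and donor hydrogen are not covalently connected")
  as.integer(dmat[1, 1] + 1)
}

#' Aromatic stacking geometry between two rings
#'
#' @param ring_a,ring_b n x 3 coordinate matrices (n >= 3) of the two ring
#'   atom sets.
#' @return List with `centroid_distance` (Angstrom) and `interplane_angle`
#'   (degrees, folded into \[0, 90\]).
#' @export
pi_stack_geometry <- function(ring_a, ring_b) {
  pa <- lsq_plane(ring_a)
  pb <- lsq_plane(ring_b)
  cosang <- abs(sum(pa$normal * pb$normal))
  cosang <- min(1, cosang)
  list(centroid_distance = vnorm(pa$centroid - pb$centroid),
       interplane_angle = acos(cosang) * 180 / pi)
}
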