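# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# RMSD of the optimal proper-rotation superposition by Horn's quaternion
# eigenvalue method (largest eigenvalue of the 4x4 key matrix).
quaternion_rmsd <- function(x, y) {
  x0 <- sweep(x, 2, colMeans(x))
  y0 <- sweep(y, 2, colMeans(y))
  s <- crossprod(x0, y0)
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],       s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(x0^2) + sum(y0^2) - 2 * lam) / nrow(x)))
}

# least-squares plane oracle: minimize the summed squared orthogonal
# distances over spherical-coordinate normals (coarse grid + Nelder-Mead)
plane_sse_oracle <- function(points) {
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sse <- function(ang) {
    n <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    sum((x %*% n)^2)
  }
  best <- Inf
  for (th in seq(0, pi, length.out = 13)) for (ph in seq(0, pi, length.out = 13)) {
    o <- stats::optim(c(th, ph), sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, o$value)
  }
  best
}

# random rigid motion (proper rotation + translation)
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1-2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
    2*(q[2]*q[3]+q[1]*q[4]), 1-2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
    2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1-2*(q[2]^2+q[3]^2)),
    3, 3, byrow = TRUE)
  list(rot = r, trans = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, rg) sweep(xyz %*% t(rg$rot), 2, rg$trans, "+")

# random valid unit cell (never close to degenerate)
random_cell <- function() {
  repeat {
    ang <- runif(3, 60, 120)
    ca <- cos(ang[1]*pi/180); cb <- cos(ang[2]*pi/180); cg <- cos(ang[3]*pi/180)
    if (1 - ca^2 - cb^2 - cg^2 + 2*ca*cb*cg > 0.05) break
  }
  len <- runif(3, 5, 30)
  crystal_cell(len[1], len[2], len[3], ang[1], ang[2], ang[3])
}

# cell volume by the explicit lattice-vector triple product
triple_product_volume <- function(cell) {
  m <- cell_matrix(cell)
  abs(sum(m[, 1] * c(m[2, 2] * m[3, 3] - m[3, 2] * m[2, 3],
                     m[3, 2] * m[1, 3] - m[1, 2] * m[3, 3],
                     m[1, 2] * m[2, 3] - m[2, 2] * m[1, 3])))
}

# random formula over the light elements used throughout
random_formula <- function() {
  els <- sample(c("C", "H", "N", "O", "Cl", "S", "P", "F", "Br"),
                sample(2:5, 1))
  counts <- sample(1:40, length(els), replace = TRUE)
  paste0(els, counts, collapse = "")
}

template_distance <- function(tpl, a, b) {
  sqrt(sum((template_atom(tpl, a) - template_atom(tpl, b))^2))
}
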