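# Vectorized 3-vector geometry kernels.  All functions take matrices of row
# vectors and return values/gradients for every row at once; the gradient
# formulas are the standard analytic ones and are exercised against central
# finite differences in the test suite.

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a^2))

row_unit <- function(a) a / row_norm(a)

# angle at j for triplets (i, j, k), radians, plus d(theta)/d(r_i), d/d(r_k);
# d/d(r_j) = -(gi + gk)
angle_and_grad <- function(ri, rj, rk) {
  u <- ri - rj; v <- rk - rj
  nu <- row_norm(u); nv <- row_norm(v)
  cosang <- pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)
  th <- acos(cosang)
  sin_th <- pmax(sqrt(1 - cosang^2), 1e-8)
  uh <- u / nu; vh <- v / nv
  gi <- (cosang * uh - vh) / (sin_th * nu)
  gk <- (cosang * vh - uh) / (sin_th * nv)
  list(theta = th, gi = gi, gk = gk)
}

# torsion for quadruplets (i, j, k, l), radians in (-pi, pi], with gradients
# w.r.t. all four atoms (standard cross-product formulation)
dihedral_and_grad <- function(ri, rj, rk, rl) {
  b1 <- rj - ri; b2 <- rk - rj; b3 <- rl - rk
  n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
  nb2 <- row_norm(b2)
  m1 <- row_cross(n1, b2 / nb2)
  phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
  n1sq <- pmax(rowSums(n1^2), 1e-12); n2sq <- pmax(rowSums(n2^2), 1e-12)
  # Blondel-Karplus derivatives, adapted to this atan2 sign convention
  gi <- n1 * (nb2 / n1sq)
  gl <- -n2 * (nb2 / n2sq)
  t1 <- n1 * (rowSums(b1 * b2) / (n1sq * nb2))
  t2 <- -n2 * (rowSums(b3 * b2) / (n2sq * nb2))
  gj <- -gi - t1 + t2
  gk <- -gl + t1 - t2
  list(phi = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

dihedral_value <- function(ri, rj, rk, rl)
  dihedral_and_grad(ri, rj, rk, rl)$phi

# wrap angle difference to (-pi, pi]
wrap_angle <- function(x) x - 2 * pi * round(x / (2 * pi))

# place atom d given reference atoms a-b-c, bond |d-c|, angle b-c-d (deg)
# and torsion a-b-c-d (deg): the standard internal-coordinate construction
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- c(bc[2] * n[3] - bc[3] * n[2],
         bc[3] * n[1] - bc[1] * n[3],
         bc[1] * n[2] - bc[2] * n[1])
  c + (-bond * cos(ang)) * bc +
    (bond * sin(ang) * cos(tor)) * (-n) +
    (bond * sin(ang) * sin(tor)) * m
}

# Kabsch least-squares superposition: rotation R and translation t mapping
# `mobile` onto `fixed` (minimizing RMSD); returns transformed coords too
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xform <- sweep(P %*% t(R), 2, cf, `+`)
  list(R = R, center_mobile = cm, center_fixed = cf, xyz = xform)
}
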