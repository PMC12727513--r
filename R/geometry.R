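## Internal geometry primitives: vectors are numeric length-3, coordinate
## matrices are N x 3 (Angstrom).

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## angle a-b-c in degrees
.angle3 <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

## dihedral a-b-c-d in degrees, in (-180, 180]
.dihedral4 <- function(a, b, c, d) {
  b0 <- a - b; b1 <- .unit(c - b); b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(.cross(b1, v) * w)
  ang <- .rad2deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}

.wrap180 <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x <= -180, x + 360, ifelse(x > 180, x - 360, x))
}

## NeRF atom placement: position of atom X bonded to c, with bond length,
## bond angle b-c-X (deg) and torsion a-b-c-X (deg).
.nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- .deg2rad(angle); tor <- .deg2rad(torsion)
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)           # orthonormal frame (bc, m, n)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

## Kabsch: optimal proper rotation R and translation t with
## target ~ mobile %*% t(R) + t. Returns list(rotation, translation, rmsd).
.kabsch <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_ <- ct - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, t_, "+")
  list(rotation = R, translation = t_,
       rmsd = sqrt(mean(rowSums((moved - target)^2))))
}

.apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

## random proper rotation (uniform via QR of Gaussian matrix)
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## rotation matrix about unit axis by angle (deg), Rodrigues
.axis_rotation <- function(axis, angle) {
  u <- .unit(axis); th <- .deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
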