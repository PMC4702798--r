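# Small 3D geometry helpers shared across modules. Coordinates are plain
# numeric matrices (n x 3) or length-3 vectors, units Angstrom throughout.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

# angle at vertex b (degrees)
vec_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}

# angle between two direction vectors, folded into [0, 90] (degrees);
# used for ring-plane comparisons where normals have no preferred sign
axis_angle <- function(u, v) {
  ang <- acos(pmin(1, pmax(-1, abs(sum(unitv(u) * unitv(v)))))) * 180 / pi
  ang
}

# pairwise Euclidean distances between rows of a (n x 3) and b (m x 3),
# chunked so large probe grids never materialise a huge intermediate
pdist <- function(a, b, chunk = 2000L) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  n <- nrow(a)
  out <- matrix(0, n, nrow(b))
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  bb <- rowSums(b^2)
  for (ii in idx) {
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), bb, "+") -
      2 * a[ii, , drop = FALSE] %*% t(b)
    out[ii, ] <- sqrt(pmax(d2, 0))
  }
  out
}

# minimum distance from each row of a to any row of b
min_dist <- function(a, b) {
  if (nrow(b) == 0L) return(rep(Inf, nrow(a)))
  apply(pdist(a, b), 1, min)
}

# rotation matrix about a unit axis by angle (degrees), Rodrigues form
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Kabsch least-squares rigid superposition of mobile onto fixed (both n x 3,
# rows paired). Returns rotation R (applied as x %*% R), translation t, and
# the RMSD of the fitted points: transformed = mobile %*% R + t (row-wise).
kabsch <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), nrow(mobile) >= 3)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t <- cf - as.numeric(cm %*% R)
  fitted <- sweep(mobile %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - fixed)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

apply_rigid <- function(xyz, rotation, translation) {
  sweep(matrix(as.numeric(xyz), ncol = 3) %*% rotation, 2, translation, "+")
}

rmsd_xyz <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# least-squares plane normal and centroid of a point set (n >= 3)
plane_fit <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

# dominant principal axis of a point set, sign fixed so that the axis points
# along the first-to-last row direction (deterministic for chain segments)
principal_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  ax <- sv$v[, 1]
  ref <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(ax * ref) < 0) ax <- -ax
  ax
}

# signed dihedral-style rotation (degrees in [-180, 180]) between axes u and v
# projected on the plane perpendicular to the connecting axis w
projected_rotation <- function(u, v, w) {
  w <- unitv(w)
  pu <- u - sum(u * w) * w
  pv <- v - sum(v * w) * w
  if (vnorm(pu) < 1e-9 || vnorm(pv) < 1e-9) return(NA_real_)
  pu <- unitv(pu)
  pv <- unitv(pv)
  ang <- acos(pmin(1, pmax(-1, sum(pu * pv)))) * 180 / pi
  s <- sign(sum(w * pracma_cross(pu, pv)))
  if (s == 0) s <- 1
  ang * s
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic Fibonacci sphere: n approximately uniform unit vectors
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
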