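# Small 3D geometry helpers shared across modules.
# Convention: right-handed coordinates in mm, limb axis along +z,
# origin at the midpoint of the limb axis.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

# Rotation matrix about arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, theta) {
  a <- unitv(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Orthonormal frame completing a unit normal n: returns 3x3 matrix with
# columns (u, v, n); u chosen deterministically.
complete_frame <- function(n) {
  n <- unitv(n)
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unitv(pracma_cross(ref, n))
  v <- pracma_cross(n, u)
  cbind(u, v, n)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Segment/infinite-cylinder intersection. Cylinder axis through `c0` with
# unit direction `ax` and radius r (mm). Returns total chord length of the
# segment p->q lying inside the cylinder.
segment_cylinder_chord <- function(p, q, c0, ax, r) {
  d <- q - p
  L <- vnorm(d)
  if (L == 0) return(0)
  u <- d / L
  # project out axis component
  w0 <- (p - c0) - sum((p - c0) * ax) * ax
  uperp <- u - sum(u * ax) * ax
  a <- sum(uperp^2)
  b <- 2 * sum(w0 * uperp)
  cc <- sum(w0^2) - r^2
  if (a < 1e-14) {                      # segment parallel to axis
    return(if (cc <= 0) L else 0)
  }
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0)
  s <- sqrt(disc)
  t1 <- (-b - s) / (2 * a)
  t2 <- (-b + s) / (2 * a)
  lo <- max(0, min(t1, t2))
  hi <- min(L, max(t1, t2))
  max(0, hi - lo)
}

# Does segment p->q pass within radius r of the infinite cylinder axis
# (c0, ax)? Used for bone occlusion tests.
segment_hits_cylinder <- function(p, q, c0, ax, r) {
  segment_cylinder_chord(p, q, c0, ax, r) > 0
}

# Minimum distance from point x to segment a->b, plus the arclength
# parameter t in [0,1] of the closest point.
point_segment_dist <- function(x, a, b) {
  d <- b - a
  L2 <- sum(d^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((x - a) * d) / L2))
  p <- a + t * d
  list(dist = vnorm(x - p), t = t, point = p)
}

# Best-fit rigid transform (rotation + translation, Kabsch) mapping point
# set X (n x 3) onto Y (n x 3). Returns list(R, t) with Y ~ X %*% t(R) + t.
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  H <- t(X0) %*% Y0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  list(R = R, t = t)
}

apply_rigid <- function(X, tr) sweep(X %*% t(tr$R), 2, tr$t, `+`)
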