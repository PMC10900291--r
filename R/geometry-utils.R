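# Internal vector-geometry helpers. All angles in radians unless noted.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("degenerate axis", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped to the half-open interval (-pi, pi].
#' @export
wrap_pi <- function(x) {
  -((-x + pi) %% (2 * pi) - pi)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# planar angle a-b-c at vertex b, in [0, pi]
angle_at <- function(a, b, c) {
  u <- unit_vec(a - b)
  v <- unit_vec(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

# Right-handed (IUPAC) torsion p1-p2-p3-p4 in (-pi, pi]; 0 for the
# syn-periplanar (cis) arrangement.  Returns NA_real_ when either bonded
# triple is collinear (cross-product norm below `tol`).
torsion <- function(p1, p2, p3, p4, tol = 1e-8) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vec_norm(n1) < tol || vec_norm(n2) < tol) return(NA_real_)
  m1 <- cross3(n1, b2 / vec_norm(b2))
  wrap_pi(-atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Analytic gradient of the torsion with respect to the four points.
# Standard force-field formula; returns a list of four 3-vectors (rad/angstrom).
torsion_gradient <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- vec_norm(b2)
  g1 <- -nb2 / sum(n1 * n1) * n1
  g4 <- nb2 / sum(n2 * n2) * n2
  f12 <- sum(b1 * b2) / sum(b2 * b2)
  f32 <- sum(b3 * b2) / sum(b2 * b2)
  g2 <- -(1 + f12) * g1 + f32 * g4
  g3 <- -(g1 + g2 + g4)
  list(g1, g2, g3, g4)
}

# Random proper rotation (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rotation by `angle` radians about unit `axis` (Rodrigues)
axis_rotation <- function(axis, angle) {
  u <- unit_vec(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
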