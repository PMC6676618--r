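# Small 3D geometry toolkit: unit vectors, rotations, dihedrals, Kabsch
# superposition. All angles in degrees at the API surface.

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector", call. = FALSE)
  v / n
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix: angle (radians) about unit axis (Rodrigues).
#' @noRd
rotation_about <- function(axis, angle) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation taking unit vector a onto unit vector b (minimal angle).
#' @noRd
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  ax <- cross3(a, b)
  s <- vnorm(ax)
  co <- sum(a * b)
  if (s < 1e-10) {
    if (co > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about(p, pi))
  }
  rotation_about(ax, atan2(s, co))
}

#' @noRd
angle_between <- function(u, v) {
  .deg(acos(max(-1, min(1, sum(unit(u) * unit(v))))))
}

# Signed dihedral p1-p2-p3-p4 in degrees, in (-180, 180].
#' @noRd
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- .deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}

# Absolute circular difference of two angles in degrees, mapped to [0, 180].
#' @noRd
circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Least-squares rigid superposition (rotation + translation, no reflection).
# Returns list(rmsd, R, t): x_aligned = x %*% R + t approximates y.
#' @noRd
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  xa <- x0 %*% R
  rmsd <- sqrt(sum((xa - y0)^2) / nrow(x))
  list(rmsd = rmsd, R = R, t = cy - as.numeric(cx %*% R))
}
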