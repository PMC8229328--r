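# Minimal unit-quaternion helpers for strapdown orientation tracking.
# Quaternions are length-4 numeric vectors (w, x, y, z), scalar first.

quat_mul <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

# Quaternion for a rotation vector (axis * angle, rad).
quat_from_rotvec <- function(rv) {
  ang <- sqrt(sum(rv^2))
  if (ang < 1e-12) return(c(1, rv / 2))
  c(cos(ang / 2), rv / ang * sin(ang / 2))
}

# Rotation matrix (body -> navigation) from a unit quaternion.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Shortest-arc quaternion rotating unit vector a onto unit vector b.
quat_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 degrees: any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(c(0, v))
  }
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  q <- c(1 + d, v)
  q / sqrt(sum(q^2))
}
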