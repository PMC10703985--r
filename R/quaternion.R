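## Unit quaternions are length-4 numeric vectors c(w, x, y, z), scalar first.
## All rotations are world-to-segment passive orientations unless stated.

quat_identity <- function() c(1, 0, 0, 0)

quat_norm <- function(q) sqrt(sum(q * q))

quat_normalize <- function(q) {
  n <- quat_norm(q)
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

quat_conj <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

quat_mul <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis * axis))
  if (n == 0) return(quat_identity())
  h <- angle / 2
  c(cos(h), sin(h) * axis / n)
}

#' @noRd
quat_angle <- function(q) {
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1L]))
}

## Rotation vector (axis * angle) of a unit quaternion, in (-pi, pi].
quat_to_rotvec <- function(q) {
  if (q[1L] < 0) q <- -q
  v <- q[2:4]
  s <- sqrt(sum(v * v))
  if (s < 1e-12) return(2 * v)  # small-angle limit: q ~ (1, v/2)
  axis <- v / s
  angle <- 2 * atan2(s, q[1L])
  axis * angle
}

quat_to_rotmat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3L, byrow = TRUE)
}

## Shepperd's method; returns scalar-first unit quaternion with w >= 0.
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1L] < 0) q <- -q
  quat_normalize(q)
}

## Rodrigues rotation matrix about a unit axis.
axis_angle_rotmat <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle); v <- 1 - c_
  x <- axis[1L]; y <- axis[2L]; z <- axis[3L]
  matrix(c(
    x * x * v + c_,     x * y * v - z * s_, x * z * v + y * s_,
    x * y * v + z * s_, y * y * v + c_,     y * z * v - x * s_,
    x * z * v - y * s_, y * z * v + x * s_, z * z * v + c_
  ), nrow = 3L, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Evaluate an expression with a temporary RNG seed, restoring RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
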