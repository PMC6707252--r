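# Small geometry helpers shared across modules. All coordinates are physical
# nanometres in (z, y, x) order; direction vectors use the same component order.

#' Normalize a vector to unit length
#' @param v numeric vector
#' @return unit-length vector
#' @keywords internal
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Cross product of two 3-vectors (same component order in and out)
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues)
#'
#' @param axis unit 3-vector
#' @param angle_rad rotation angle, right-handed about `axis`
#' @return 3x3 rotation matrix acting on column vectors
#' @keywords internal
rotation_about_axis <- function(axis, angle_rad) {
  a <- unit_vec(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Signed angle from vector a to vector b about a rotation axis
#' @keywords internal
signed_angle_about <- function(a, b, axis) {
  a <- unit_vec(a); b <- unit_vec(b); ax <- unit_vec(axis)
  atan2(sum(cross3(a, b) * ax), sum(a * b))
}

#' Wrap degrees into [-180, 180)
#' @keywords internal
wrap_deg <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  out[out >= 180] <- out[out >= 180] - 360
  out
}

# Squared Euclidean distances between row-point matrices a (n x 3) and b (m x 3),
# returned as an n x m matrix. Chunk callers are responsible for memory.
dist2_matrix <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}

# RNG scope guard: run `expr` under a local seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
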