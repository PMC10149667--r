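# Internal vector / rotation / RNG helpers. All angles in degrees at the API
# surface; radians only inside trigonometric calls.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop("degenerate ", what, ": cannot normalize a (near-)zero vector",
         call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle_deg`
#' degrees about the (not necessarily unit) 3-vector `axis`.
#'
#' @param axis Numeric length-3 rotation axis.
#' @param angle_deg Rotation angle in degrees (right-hand rule about `axis`).
#' @return A 3x3 proper rotation matrix.
#' @export
#' @examples
#' rotation_about_axis(c(0, 0, 1), 90) %*% c(1, 0, 0)
rotation_about_axis <- function(axis, angle_deg) {
  k <- unitize(axis, "rotation axis")
  th <- angle_deg * DEG
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Seeded uniform random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (QR of a Gaussian matrix with sign
#' fix), reproducibly when `seed` is given.
#'
#' @param seed Optional integer seed.
#' @return A 3x3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  with_local_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    Q
  })
}

is_proper_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

# Round half away from zero at a given increment (physical scale reading).
round_half_away <- function(x, increment = 1) {
  sign(x) * floor(abs(x) / increment + 0.5) * increment
}

# Evaluate `expr` under a temporary RNG state when seed is non-NULL,
# restoring the caller's state afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic sub-stream seed derived from a top-level seed; kept inside
# 32-bit signed range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483647)
}
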