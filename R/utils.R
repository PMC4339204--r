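# Small numerical helpers shared across modules.

#' Row-wise cross product of two n x 3 matrices
#' @noRd
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Row-wise Euclidean norms
#' @noRd
rownorms <- function(m) sqrt(rowSums(m^2))

#' Normalize rows to unit length (zero rows left untouched)
#' @noRd
normalize_rows <- function(m) {
  n <- rownorms(m)
  n[n == 0] <- 1
  m / n
}

#' Rotation matrix from extrinsic XYZ Euler angles (radians)
#' @noRd
euler_rotation <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' Stochastic stages take explicit integer seeds; the caller's RNG stream is
#' restored afterwards so package functions never perturb user randomness.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a bounded child seed from a base seed and an index
#' @noRd
child_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647
}

#' Population variance (divides by n, not n - 1)
#' @noRd
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Ramanujan approximation of the ellipse perimeter with semi-axes a, b
#'
#' Accurate to well below 0.1% for the eccentricities used here.
#' @param a,b semi-axes (same units)
#' @return perimeter in the units of `a`
#' @export
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}
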