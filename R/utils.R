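#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix from axis and angle
#'
#' Right-handed rotation by `angle` radians about the (normalised) `axis`,
#' via Rodrigues' formula.
#'
#' @param axis numeric length-3 vector; need not be unit length.
#' @param angle rotation angle in radians.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(diag(3))
  u <- axis / n
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Evenly distributed directions on the unit sphere
#'
#' Fibonacci (golden-spiral) lattice of `n` unit vectors, used to initialise
#' annealing runs from evenly distributed approach directions.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)            # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- phi * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

# squared-distance free cross-set distance matrix, rows of a vs rows of b
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# deterministic FNV-1a style hash of a serialised R object, hex string.
# Used to stamp output artifacts with their configuration.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

nd_warn <- function(...) warning(sprintf(...), call. = FALSE)
nd_msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

# apply a rigid pose (rotation about `center`, then translation) to coords
apply_pose <- function(coords, pose, center) {
  coords <- matrix(coords, ncol = 3)
  sweep(coords, 2, center) %*% t(pose$R) +
    matrix(rep(center + pose$t, each = nrow(coords)), ncol = 3)
}

new_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is_rotation(R), length(t) == 3, all(is.finite(t)))
  list(R = R, t = as.numeric(t))
}
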