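#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' All stochastic operations draw from sub-streams derived from one user seed,
#' so that individual stages can be re-run in isolation and still reproduce
#' the output they produced inside a larger run.
#'
#' @param seed integer master seed.
#' @param stream character tag naming the consuming operation.
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483587)
}

# Evaluate expr under a local RNG seed, restoring global RNG state afterwards.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Minimum-image convention for displacement components under an orthorhombic box.
min_image <- function(d, box_len) d - box_len * round(d / box_len)

# Minimum-image displacement matrix (n x 3): rows of `a` minus vector `b`.
min_image_disp <- function(a, b, box) {
  d <- sweep(a, 2L, b)
  for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
  d
}

# All minimum-image distances between rows of A (n x 3) and rows of B (m x 3).
pbc_dist_mat <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- min_image(outer(A[, k], B[, k], "-"), box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Uniform random points in a ball of radius R (n x 3).
runif_ball <- function(n, R = 1) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- R * stats::runif(n)^(1 / 3)
  u * r
}

# Random 3D rotation matrix (uniform over SO(3)).
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-12) { q <- q / nq; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Orthonormal basis (e1, e2) of the plane perpendicular to unit vector u.
tangent_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

# Near-even directions on the unit sphere (golden-spiral construction).
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# amu / Angstrom^3 -> g / cm^3
AMU_PER_A3_TO_G_CM3 <- 1.66053906660
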