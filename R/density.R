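# Density fields: anything the partitioner can evaluate at arbitrary points.
# Three concrete kinds are provided: analytic sums of atom-centered Gaussian
# shells (the synthetic route), trilinearly interpolated cube-file volumes,
# and arbitrary user functions.

#' Evaluate a density field at Cartesian points
#'
#' @param field A density field (`gaussian_density`, `cube_density`,
#'   `function_density`) or a plain function of an n x 3 matrix.
#' @param points n x 3 matrix, bohr.
#' @return Densities at the points, electron bohr^-3.
#' @export
eval_density <- function(field, points) {
  UseMethod("eval_density")
}

#' @export
eval_density.function <- function(field, points) {
  as.numeric(field(as_point_matrix(points)))
}

#' Density field from explicit Gaussian shells
#'
#' `rho(r) = sum_s a_s exp(-alpha_s |r - c_s|^2)`. Amplitudes may be
#' negative (deformation terms); evaluation clamps nothing, callers decide
#' how to treat negativity.
#'
#' @param centers s x 3 matrix of shell centers, bohr.
#' @param amplitudes Shell amplitudes, electron bohr^-3.
#' @param exponents Positive shell exponents, bohr^-2.
#' @return An object of class `gaussian_density`. Its total electron count
#'   (closed form) is in field `n_electrons`.
#' @export
density_from_shells <- function(centers, amplitudes, exponents) {
  centers <- as_point_matrix(centers)
  amplitudes <- as.numeric(amplitudes)
  exponents <- as.numeric(exponents)
  if (nrow(centers) != length(amplitudes) ||
      length(amplitudes) != length(exponents)) {
    stop("centers, amplitudes and exponents must describe the same shells")
  }
  if (any(exponents <= 0)) stop("shell exponents must be positive")
  structure(
    list(centers = centers, amplitudes = amplitudes, exponents = exponents,
         n_electrons = sum(amplitudes * (pi / exponents)^1.5)),
    class = "gaussian_density"
  )
}

#' @export
eval_density.gaussian_density <- function(field, points) {
  points <- as_point_matrix(points)
  out <- numeric(nrow(points))
  for (s in seq_along(field$amplitudes)) {
    d2 <- (points[, 1] - field$centers[s, 1])^2 +
          (points[, 2] - field$centers[s, 2])^2 +
          (points[, 3] - field$centers[s, 3])^2
    out <- out + field$amplitudes[s] * exp(-field$exponents[s] * d2)
  }
  out
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat(sprintf("<gaussian density: %d shell(s), %.8g electrons>\n",
              length(x$amplitudes), x$n_electrons))
  invisible(x)
}

# resolve a density argument to values on grid points
.density_values <- function(density, grid) {
  if (is.numeric(density)) {
    if (length(density) != nrow(grid$points)) {
      stop("density values length does not match the grid")
    }
    as.numeric(density)
  } else {
    eval_density(density, grid$points)
  }
}
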