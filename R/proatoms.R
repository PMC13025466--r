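# Reference proatom densities.
#
# A proatom is a spherically averaged neutral isolated-atom electron density
# used as the reference shape for one atom in a molecule. The built-in
# library uses sums of s-type Gaussian shells,
#   rho0(r) = sum_j a_j * exp(-alpha_j * r^2),
# because every quantity the package needs downstream (population, dipole,
# exterior electrostatic potential) then has a closed form. These are model
# proatoms: their populations are exact (n0 = Z) but their shapes are not
# fitted to real atomic densities; users needing fidelity supply radial
# tables via proatom_from_table().

#' Build a neutral Gaussian-shell model proatom
#'
#' Constructs the built-in model proatom for element `atomic_number`: a sum
#' of `n_shells` spherical Gaussians with exponents in geometric progression
#' (scaled with Z^(4/3) so heavier atoms are more compact) and amplitudes
#' normalized so the population is exactly Z electrons.
#'
#' @param atomic_number Integer Z in 1..36.
#' @param n_shells Number of Gaussian shells (>= 1, default 3).
#' @return An object of class `radial_proatom` with fields `atomic_number`,
#'   `amplitudes` (electron bohr^-3), `exponents` (bohr^-2) and `population`
#'   (electrons).
#' @examples
#' p <- build_neutral_proatom(6)
#' proatom_population(p)  # exactly 6
#' @export
build_neutral_proatom <- function(atomic_number, n_shells = 3L) {
  z <- as.integer(atomic_number)
  if (length(z) != 1L || is.na(z) || z < 1L || z > length(ELEMENT_SYMBOLS)) {
    stop("unsupported element: the built-in proatom library covers Z = 1..",
         length(ELEMENT_SYMBOLS))
  }
  n_shells <- as.integer(n_shells)
  if (n_shells < 1L) stop("n_shells must be >= 1")
  # geometric exponent ladder; each shell carries an equal electron share
  exponents <- 2.0 * z^(4 / 3) * 4^(-(seq_len(n_shells) - 1L))
  share <- z / n_shells
  amplitudes <- share * (exponents / pi)^1.5
  new_radial_proatom(z, amplitudes, exponents)
}

new_radial_proatom <- function(atomic_number, amplitudes, exponents) {
  if (any(amplitudes <= 0) || any(exponents <= 0)) {
    stop("shell amplitudes and exponents must all be positive")
  }
  structure(
    list(
      atomic_number = as.integer(atomic_number),
      symbol = ELEMENT_SYMBOLS[atomic_number],
      amplitudes = as.numeric(amplitudes),
      exponents = as.numeric(exponents),
      population = sum(amplitudes * (pi / exponents)^1.5)
    ),
    class = "radial_proatom"
  )
}

#' Build a proatom from Gaussian shells
#'
#' Low-level constructor for a spherical density
#' `rho0(r) = sum_j a_j exp(-alpha_j r^2)` with explicit shell parameters.
#'
#' @param atomic_number Integer Z (used for the nuclear charge / symbol).
#' @param amplitudes Positive shell amplitudes, electron bohr^-3.
#' @param exponents Positive shell exponents, bohr^-2.
#' @return A `radial_proatom`.
#' @export
proatom_from_shells <- function(atomic_number, amplitudes, exponents) {
  if (length(amplitudes) != length(exponents)) {
    stop("amplitudes and exponents must have equal length")
  }
  new_radial_proatom(as.integer(atomic_number), amplitudes, exponents)
}

#' Evaluate a proatom density at radial distances
#'
#' @param p A `radial_proatom` or `table_proatom`.
#' @param distances Nonnegative distances from the nucleus, bohr.
#' @return Densities in electron bohr^-3 (strictly positive).
#' @export
evaluate_proatom <- function(p, distances) {
  UseMethod("evaluate_proatom")
}

#' @export
evaluate_proatom.radial_proatom <- function(p, distances) {
  r <- as.numeric(distances)
  if (any(r < 0)) stop("distances must be nonnegative")
  drop(exp(-outer(r^2, p$exponents)) %*% p$amplitudes)
}

#' Closed-form proatom population
#'
#' Reference population n0 = integral of rho0 over all space. For
#' Gaussian-shell proatoms this is the closed form
#' `sum_j a_j (pi/alpha_j)^(3/2)`; for tabulated proatoms it is the value
#' computed by radial quadrature at construction time.
#'
#' @param p A proatom.
#' @return Population in electrons.
#' @export
proatom_population <- function(p) {
  p$population
}

#' Place and scale a proatom in a molecule
#'
#' A scaled proatom is `c_A * rho0_A(|r - R_A|)` with a positive scaling
#' coefficient; its population is `c_A * n0_A`.
#'
#' @param base A `radial_proatom` (or `table_proatom`).
#' @param center Length-3 nuclear position, bohr.
#' @param coefficient Positive dimensionless scaling coefficient (default 1).
#' @return An object of class `scaled_proatom`.
#' @export
scaled_proatom <- function(base, center, coefficient = 1) {
  if (!inherits(base, c("radial_proatom", "table_proatom"))) {
    stop("base must be a radial or tabulated proatom")
  }
  coefficient <- as.numeric(coefficient)
  if (length(coefficient) != 1L || !is.finite(coefficient) || coefficient <= 0) {
    stop("coefficient must be a positive scalar")
  }
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center))) {
    stop("center must be a finite length-3 vector (bohr)")
  }
  structure(
    list(base = base, center = center, coefficient = coefficient,
         population = coefficient * base$population),
    class = "scaled_proatom"
  )
}

#' Evaluate a scaled proatom at Cartesian points
#'
#' @param p A `scaled_proatom`.
#' @param points An n x 3 matrix (bohr) or a length-3 vector.
#' @return Densities at the points, electron bohr^-3.
#' @export
evaluate_scaled_proatom <- function(p, points) {
  stopifnot(inherits(p, "scaled_proatom"))
  p$coefficient * evaluate_proatom(p$base, .dist_to_center(points, p$center))
}

#' @export
print.radial_proatom <- function(x, ...) {
  cat(sprintf("<proatom %s (Z=%d): %d Gaussian shell(s), n0 = %.12g e>\n",
              x$symbol, x$atomic_number, length(x$amplitudes), x$population))
  invisible(x)
}

#' @export
print.scaled_proatom <- function(x, ...) {
  cat(sprintf("<scaled proatom %s, c = %.6g, N0 = %.8g e, at (%.4g, %.4g, %.4g) bohr>\n",
              x$base$symbol, x$coefficient, x$population,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# ---- tabulated proatoms -----------------------------------------------------

#' Proatom from a radial table
#'
#' Builds a proatom from sampled values (r, rho0(r)). Inside the tabulated
#' range the density is a cubic spline of log(rho) (which enforces
#' positivity); beyond the last point it decays as rho(r_max) *
#' exp(-beta (r - r_max)) with beta taken from the final log-slope. The
#' population is computed by composite radial quadrature of 4 pi r^2 rho(r)
#' plus the closed-form exponential tail.
#'
#' @param atomic_number Integer Z.
#' @param r Increasing radial abscissae, bohr (first may be 0).
#' @param rho Positive densities at `r`, electron bohr^-3.
#' @return An object of class `table_proatom`.
#' @export
proatom_from_table <- function(atomic_number, r, rho) {
  r <- as.numeric(r); rho <- as.numeric(rho)
  if (length(r) != length(rho) || length(r) < 4L) {
    stop("need >= 4 matched (r, rho) samples")
  }
  if (is.unsorted(r, strictly = TRUE) || any(r < 0)) {
    stop("r must be strictly increasing and nonnegative")
  }
  if (any(rho <= 0)) stop("tabulated densities must be positive")
  # fmm boundary handling: a natural spline flattens log(rho) at r = 0,
  # where the true radial density has finite curvature
  spl <- stats::splinefun(r, log(rho), method = "fmm")
  n <- length(r)
  beta <- (log(rho[n - 1L]) - log(rho[n])) / (r[n] - r[n - 1L])
  if (!is.finite(beta) || beta <= 0) beta <- 1.0
  obj <- structure(
    list(atomic_number = as.integer(atomic_number),
         symbol = ELEMENT_SYMBOLS[atomic_number],
         r_max = r[n], rho_max = rho[n], beta = beta,
         spline = spl, population = NA_real_),
    class = c("table_proatom")
  )
  # population: dense Simpson on [0, r_max], analytic exponential tail
  obj$population <- .table_population(obj)
  obj
}

.table_population <- function(p) {
  m <- 4001L
  rr <- seq(0, p$r_max, length.out = m)
  f <- 4 * pi * rr^2 * evaluate_proatom(p, rr)
  h <- rr[2] - rr[1]
  simpson <- h / 3 * (f[1] + f[m] + 4 * sum(f[seq(2, m - 1, 2)]) +
                      2 * sum(f[seq(3, m - 2, 2)]))
  # tail: 4 pi rho_max int_{R}^inf r^2 exp(-beta (r - R)) dr
  R <- p$r_max; b <- p$beta
  tail <- 4 * pi * p$rho_max * (R^2 / b + 2 * R / b^2 + 2 / b^3)
  simpson + tail
}

#' @export
evaluate_proatom.table_proatom <- function(p, distances) {
  r <- as.numeric(distances)
  if (any(r < 0)) stop("distances must be nonnegative")
  out <- numeric(length(r))
  inside <- r <= p$r_max
  out[inside] <- exp(p$spline(r[inside]))
  out[!inside] <- p$rho_max * exp(-p$beta * (r[!inside] - p$r_max))
  out
}

#' @export
print.table_proatom <- function(x, ...) {
  cat(sprintf("<tabulated proatom %s (Z=%d): r <= %.4g bohr, n0 = %.8g e, tail beta = %.4g>\n",
              x$symbol, x$atomic_number, x$r_max, x$population, x$beta))
  invisible(x)
}

#' Read a proatom radial table from a text file
#'
#' Expects two whitespace-separated columns (r in bohr, rho in electron
#' bohr^-3); lines starting with `#` are comments.
#'
#' @param path File path.
#' @param atomic_number Integer Z of the element the table describes.
#' @return A `table_proatom`.
#' @export
read_proatom_table <- function(path, atomic_number) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no data rows in ", path)
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) < 2L)) {
    stop("malformed radial table (need two columns) in ", path)
  }
  r <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  rho <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  if (anyNA(r) || anyNA(rho)) stop("non-numeric entries in radial table ", path)
  proatom_from_table(atomic_number, r, rho)
}
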