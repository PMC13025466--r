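# Synthetic molecular densities with known ground truth.
#
# Two families are generated: exact scaled promolecules (the partitioner
# must recover the generating coefficients c*), and charge-transfer
# perturbations of the neutral promolecule (electrons moved from a donor to
# an acceptor atom by a pair of opposite Gaussian monopoles), which are not
# promolecular, so the recovered coefficients differ from 1 and the donor /
# acceptor acquire charges of known sign. Both keep the total electron
# count in closed form.

#' Synthetic exact promolecule
#'
#' Builds a molecular density that is exactly
#' `sum_A c_A rho0_A(|r - R_A|)` from the built-in model proatoms, with the
#' generating coefficients recorded as ground truth.
#'
#' @param elements Element symbols or atomic numbers.
#' @param positions m x 3 nuclear positions, bohr.
#' @param coefficients Positive scaling coefficients c*_A (default all 1).
#' @param n_shells Shells per proatom (default 3).
#' @return An object of class `synthetic_system`: `elements`,
#'   `atomic_numbers`, `positions`, `proatoms`, `density`
#'   (a `gaussian_density`), `true_coefficients`, `n_electrons`, `mode`.
#' @export
make_promolecular_system <- function(elements, positions, coefficients = NULL,
                                     n_shells = 3L) {
  z <- if (is.character(elements)) atomic_number(elements) else as.integer(elements)
  positions <- as_point_matrix(positions)
  m <- length(z)
  if (nrow(positions) != m) stop("one position per element required")
  if (m > 1L && min(stats::dist(positions)) < 1e-6) {
    stop("degenerate geometry: coincident atoms")
  }
  if (is.null(coefficients)) coefficients <- rep(1, m)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != m || any(coefficients <= 0)) {
    stop("coefficients must be positive, one per atom")
  }
  proatoms <- lapply(z, build_neutral_proatom, n_shells = n_shells)
  sh <- .collect_shells(proatoms, positions, coefficients)
  density <- density_from_shells(sh$centers, sh$amplitudes, sh$exponents)
  structure(
    list(elements = element_symbol(z), atomic_numbers = z,
         positions = positions, proatoms = proatoms,
         density = density, true_coefficients = coefficients,
         n_electrons = sum(coefficients * vapply(proatoms, proatom_population,
                                                 numeric(1))),
         mode = "promolecule"),
    class = "synthetic_system"
  )
}

.collect_shells <- function(proatoms, positions, coefficients) {
  centers <- list(); amp <- list(); expn <- list()
  for (a in seq_along(proatoms)) {
    p <- proatoms[[a]]
    k <- length(p$amplitudes)
    centers[[a]] <- matrix(rep(positions[a, ], each = k), k, 3L)
    amp[[a]] <- coefficients[a] * p$amplitudes
    expn[[a]] <- p$exponents
  }
  list(centers = do.call(rbind, centers), amplitudes = unlist(amp),
       exponents = unlist(expn))
}

#' Synthetic density with inter-atomic charge transfer
#'
#' Starts from the neutral promolecule and moves `transfer` electrons from
#' the donor atom to the acceptor atom by subtracting / adding a normalized
#' Gaussian monopole of exponent `width` on each, producing a density that
#' is not a promolecule (so stockholder coefficients become nontrivial)
#' while the total electron count is unchanged in closed form.
#' Nonnegativity of the perturbed density is verified on a molecular grid
#' plus fine radial probes along every interatomic axis.
#'
#' @param elements,positions As in [make_promolecular_system()].
#' @param donor,acceptor Atom indices (1-based) losing / gaining electrons.
#' @param transfer Electrons moved (> 0, less than the donor population).
#' @param width Exponent of the transfer Gaussians, bohr^-2. The default
#'   (`NULL`) uses 1.5 times the donor proatom's most diffuse shell
#'   exponent, so the removed density decays faster than the donor's own
#'   tail and the perturbed density stays positive.
#' @param n_shells Shells per proatom (default 3).
#' @return A `synthetic_system` with `mode = "charge_transfer"`,
#'   `true_coefficients = NULL`, and fields `donor`, `acceptor`, `transfer`.
#' @export
make_charge_transfer_system <- function(elements, positions, donor = 1L,
                                        acceptor = 2L, transfer = 0.2,
                                        width = NULL, n_shells = 3L) {
  base <- make_promolecular_system(elements, positions, n_shells = n_shells)
  m <- length(base$atomic_numbers)
  donor <- as.integer(donor); acceptor <- as.integer(acceptor)
  if (donor < 1L || donor > m || acceptor < 1L || acceptor > m ||
      donor == acceptor) {
    stop("donor and acceptor must be distinct atom indices")
  }
  if (!is.finite(transfer) || transfer <= 0 ||
      transfer >= base$proatoms[[donor]]$population) {
    stop("transfer must be positive and smaller than the donor population")
  }
  if (is.null(width)) width <- 1.5 * min(base$proatoms[[donor]]$exponents)
  if (!is.finite(width) || width <= 0) stop("width must be positive")
  amp <- transfer * (width / pi)^1.5
  d <- base$density
  density <- density_from_shells(
    rbind(d$centers, base$positions[donor, ], base$positions[acceptor, ]),
    c(d$amplitudes, -amp, amp),
    c(d$exponents, width, width)
  )
  .check_nonnegative(density, base$positions, base$atomic_numbers)
  out <- base
  out$density <- density
  out$true_coefficients <- NULL
  out$mode <- "charge_transfer"
  out$donor <- donor
  out$acceptor <- acceptor
  out$transfer <- transfer
  structure(out, class = "synthetic_system")
}

# probe a modest molecular grid plus dense segments along each pair axis
.check_nonnegative <- function(density, positions, atomic_numbers) {
  grid <- build_molecular_grid(positions, atomic_numbers,
                               n_radial = 40L, angular_order = 8L)
  vals <- eval_density(density, grid$points)
  m <- nrow(positions)
  if (m > 1L) {
    for (a in seq_len(m - 1L)) {
      for (b in seq((a + 1L), m)) {
        tt <- seq(-0.5, 1.5, length.out = 2000L)
        seg <- positions[a, ] + outer(tt, positions[b, ] - positions[a, ])
        vals <- c(vals, eval_density(density, seg))
      }
    }
  }
  if (min(vals) < -1e-12) {
    stop("perturbation too large: the perturbed density is negative ",
         "(minimum ", signif(min(vals), 3), " e/bohr^3)")
  }
  invisible(TRUE)
}

#' Seeded random synthetic fixture
#'
#' Reproducible random geometry (atoms placed at bonded-range distances
#' 1.8-3.2 bohr from an existing atom, minimum pair separation 1.2 bohr)
#' with either promolecular or charge-transfer density.
#'
#' @param seed Integer seed (required; the fixture is a pure function of it).
#' @param n_atoms Range (length-2) or fixed count of atoms (default 2 to 4).
#' @param elements Pool of element symbols to draw from.
#' @param coef_range Range of the true coefficients in promolecular mode.
#' @param mode `"promolecule"` (default) or `"charge_transfer"`.
#' @return A `synthetic_system`.
#' @export
random_fixture <- function(seed, n_atoms = c(2L, 4L),
                           elements = c("H", "C", "N", "O", "F"),
                           coef_range = c(0.7, 1.3),
                           mode = c("promolecule", "charge_transfer")) {
  mode <- match.arg(mode)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n_atoms <- as.integer(n_atoms)
  n <- if (length(n_atoms) == 1L) n_atoms else
    sample(seq(n_atoms[1], n_atoms[2]), 1L)
  if (n < 2L) stop("fixtures need at least 2 atoms")
  elems <- sample(elements, n, replace = TRUE)
  pos <- matrix(0, n, 3L)
  for (a in seq(2L, n)) {
    repeat {
      anchor <- pos[sample.int(a - 1L, 1L), ]
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- anchor + stats::runif(1, 1.8, 3.2) * dir
      dmin <- min(sqrt(rowSums(sweep(pos[seq_len(a - 1L), , drop = FALSE],
                                     2L, cand)^2)))
      if (dmin >= 1.2) break
    }
    pos[a, ] <- cand
  }
  if (mode == "promolecule") {
    cc <- stats::runif(n, coef_range[1], coef_range[2])
    make_promolecular_system(elems, pos, cc)
  } else {
    da <- sample.int(n, 2L)
    donor_z <- atomic_number(elems[da[1]])
    alpha_min <- min(build_neutral_proatom(donor_z)$exponents)
    make_charge_transfer_system(elems, pos, donor = da[1], acceptor = da[2],
                                transfer = stats::runif(1, 0.05, 0.15),
                                width = stats::runif(1, 1.2, 2.0) * alpha_min)
  }
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat(sprintf("<synthetic %s: %s; %.6g electrons>\n", x$mode,
              paste(x$elements, collapse = " "), x$n_electrons))
  if (!is.null(x$true_coefficients)) {
    cat("  true coefficients:",
        paste(signif(x$true_coefficients, 6), collapse = ", "), "\n")
  }
  if (identical(x$mode, "charge_transfer")) {
    cat(sprintf("  transfer: %.4g e from atom %d to atom %d\n",
                x$transfer, x$donor, x$acceptor))
  }
  invisible(x)
}

#' Serialize a synthetic system to JSON
#'
#' Writes elements, positions (bohr), all Gaussian shells, the mode and any
#' ground-truth coefficients, so a fixture can be reloaded (or fed to the
#' command-line tool) without regeneration.
#'
#' @param system A `synthetic_system`.
#' @param path Output path.
#' @export
write_system_json <- function(system, path) {
  stopifnot(inherits(system, "synthetic_system"))
  obj <- list(
    elements = system$elements,
    positions_bohr = unname(apply(system$positions, 1L, as.numeric,
                                  simplify = FALSE)),
    shells = list(
      centers_bohr = unname(apply(system$density$centers, 1L, as.numeric,
                                  simplify = FALSE)),
      amplitudes = system$density$amplitudes,
      exponents = system$density$exponents
    ),
    mode = system$mode,
    true_coefficients = system$true_coefficients,
    n_electrons = system$n_electrons
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a synthetic system from JSON
#'
#' @param path Path written by [write_system_json()].
#' @return A `synthetic_system` (proatoms rebuilt from the element list).
#' @export
read_system_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  z <- atomic_number(obj$elements)
  rows_to_matrix <- function(x) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = 3L, byrow = TRUE)
  }
  positions <- rows_to_matrix(obj$positions_bohr)
  density <- density_from_shells(
    rows_to_matrix(obj$shells$centers_bohr),
    obj$shells$amplitudes, obj$shells$exponents)
  structure(
    list(elements = obj$elements, atomic_numbers = z, positions = positions,
         proatoms = lapply(z, build_neutral_proatom),
         density = density,
         true_coefficients = obj$true_coefficients,
         n_electrons = obj$n_electrons,
         mode = obj$mode),
    class = "synthetic_system"
  )
}
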