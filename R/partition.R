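# Stockholder partitioning.
#
# The molecular density rho_mol is divided among atoms by fuzzy weights
#   w_A(r) = c_A rho0_A(r) / sum_B c_B rho0_B(r),
# built from neutral reference proatoms rho0_A scaled by positive
# coefficients c_A. Classic Hirshfeld fixes all c_A = 1; scaled Hirshfeld
# (SH) determines the c_A self-consistently so each proatom population
# c_A n0_A matches the atomic population N_A = int rho_mol w_A dr. The
# fixed-point iteration alternates population integration with the update
# c_A = N_A / n0_A until the coefficients stop changing; this is equivalent
# to minimizing the extended Kullback-Leibler divergence between molecule
# and promolecule over the scaling coefficients (see solve_variational).

# promolecule density floor: grid points where sum_B c_B rho0_B falls below
# tau carry no physical density either; they are excluded from all sums so
# that conservation sum_A N_A = int rho_mol holds exactly over retained
# points.
.DENSITY_FLOOR <- 1e-100

# proatom value matrix: n_points x n_atoms
.proatom_matrix <- function(proatoms, centers, points) {
  centers <- as_point_matrix(centers)
  if (length(proatoms) != nrow(centers)) {
    stop("need one proatom per center")
  }
  vapply(seq_along(proatoms), function(a) {
    evaluate_proatom(proatoms[[a]], .dist_to_center(points, centers[a, ]))
  }, numeric(nrow(as_point_matrix(points))))
}

#' Stockholder weights from proatom values
#'
#' Computes `w_A = c_A g_A / sum_B c_B g_B` at each point, where `g_A` are
#' the proatom densities. Points where the promolecular density falls below
#' the floor `tau` are excluded: all their weights are set to 0 and they are
#' flagged in the `retained` component.
#'
#' @param proatom_values n x m matrix of proatom densities at the points.
#' @param coefficients Positive scaling coefficients, length m.
#' @param tau Promolecule density floor (default 1e-100).
#' @return List with `weights` (n x m, rows summing to 1 where retained),
#'   `retained` (logical n), and `promolecule` (n, the scaled promolecular
#'   density).
#' @export
stockholder_weights <- function(proatom_values, coefficients,
                                tau = .DENSITY_FLOOR) {
  g <- as.matrix(proatom_values)
  coefficients <- as.numeric(coefficients)
  if (ncol(g) != length(coefficients)) {
    stop("one coefficient per proatom column is required")
  }
  if (any(!is.finite(coefficients)) || any(coefficients <= 0)) {
    stop("invalid coefficient: all c_A must be positive and finite")
  }
  if (any(g < 0)) stop("proatom values must be nonnegative")
  promol <- drop(g %*% coefficients)
  retained <- promol > tau
  w <- matrix(0, nrow(g), ncol(g))
  if (any(retained)) {
    w[retained, ] <- sweep(g[retained, , drop = FALSE], 2L, coefficients, "*") /
      promol[retained]
  }
  list(weights = w, retained = retained, promolecule = promol)
}

#' Atomic populations by weighted integration
#'
#' `N_A = sum_i w_grid_i rho_mol_i w_A_i` -- the grid analogue of
#' integrating the atomic density rho_mol w_A. Because the weights of
#' retained points sum to one, `sum_A N_A` equals the grid integral of
#' rho_mol over retained points by construction.
#'
#' @param rho_mol Density values at the grid points (nonnegative).
#' @param weights Result of [stockholder_weights()] (or a bare n x m matrix).
#' @param grid A `molecular_grid`.
#' @return Numeric vector of populations N_A, electrons.
#' @export
atomic_populations <- function(rho_mol, weights, grid) {
  w <- if (is.list(weights)) weights$weights else as.matrix(weights)
  rho_mol <- as.numeric(rho_mol)
  if (length(rho_mol) != nrow(w) || length(rho_mol) != nrow(grid$points)) {
    stop("rho_mol, weights and grid must describe the same points")
  }
  if (any(rho_mol < -1e-12)) stop("rho_mol must be nonnegative")
  drop(crossprod(w, grid$weights * rho_mol))
}

#' Coefficient update of the fixed-point iteration
#'
#' `c_A = N_A / n0_A`: each proatom is rescaled so its population matches
#' the atomic population from the current weights.
#'
#' @param populations Atomic populations N_A (electrons), all > 0.
#' @param reference_populations Reference proatom populations n0_A.
#' @return Updated coefficients.
#' @export
update_coefficients <- function(populations, reference_populations) {
  populations <- as.numeric(populations)
  n0 <- as.numeric(reference_populations)
  if (length(populations) != length(n0)) stop("length mismatch")
  if (any(n0 <= 0)) stop("reference populations must be positive")
  if (any(populations <= 0)) {
    stop("degenerate partition: an atomic population vanished, the ",
         "scaling coefficient would leave the c_A > 0 domain")
  }
  populations / n0
}

#' Scaled Hirshfeld partitioning by fixed-point iteration
#'
#' Starting from `init` (all 1 by default, i.e. the classic Hirshfeld
#' promolecule), alternately (i) builds stockholder weights from the current
#' coefficients, (ii) integrates atomic populations, and (iii) rescales each
#' proatom so its population matches, until
#' `max_A |c_A^(k+1) - c_A^(k)| < epsilon` or `k_max` updates have been
#' performed. The underlying objective is convex, so the converged
#' coefficients are unique and independent of the start.
#'
#' @param density A density field or a numeric vector of values at
#'   `grid$points` (electron bohr^-3).
#' @param proatoms List of `radial_proatom` (one per atom).
#' @param centers m x 3 nuclear positions, bohr.
#' @param grid A `molecular_grid` built on the same centers.
#' @param epsilon Convergence threshold on `max_A |delta c_A|` (default 1e-6).
#' @param k_max Maximum number of coefficient updates (default 500); with
#'   `k_max = 0` the routine performs a single population pass at `init`,
#'   which is exactly the classic Hirshfeld scheme.
#' @param init Initial coefficients (default all 1).
#' @param tau Promolecule density floor passed to [stockholder_weights()].
#' @return An object of class `sh_partition`: `coefficients`, `populations`,
#'   `charges` (Z_A - N_A), `reference_populations`, `iterations`,
#'   `converged`, `history` (per-update max |delta c|), `objective` (final
#'   extended-KL divergence), `objective_history`, `excluded_points`,
#'   `elements`, `centers`, `settings`.
#' @export
run_scaled_hirshfeld <- function(density, proatoms, centers, grid,
                                 epsilon = 1e-6, k_max = 500L, init = NULL,
                                 tau = .DENSITY_FLOOR) {
  if (epsilon <= 0) stop("epsilon must be positive")
  k_max <- as.integer(k_max)
  if (k_max < 0L) stop("k_max must be >= 0")
  centers <- as_point_matrix(centers)
  g <- .proatom_matrix(proatoms, centers, grid$points)
  rho <- .density_values(density, grid)
  n0 <- vapply(proatoms, proatom_population, numeric(1))
  z <- vapply(proatoms, function(p) as.numeric(p$atomic_number), numeric(1))
  m <- length(proatoms)
  cc <- if (is.null(init)) rep(1, m) else as.numeric(init)
  if (length(cc) != m || any(cc <= 0)) {
    stop("init must supply one positive coefficient per atom")
  }

  history <- numeric(0)
  obj_history <- numeric(0)
  converged <- (k_max == 0L)
  k <- 0L
  repeat {
    sw <- stockholder_weights(g, cc, tau = tau)
    N <- atomic_populations(rho, sw, grid)
    obj_history <- c(obj_history, .ext_kl_value(rho, sw$promolecule,
                                                grid$weights, sw$retained))
    if (k >= k_max) break
    c_new <- update_coefficients(N, n0)
    delta <- max(abs(c_new - cc))
    history <- c(history, delta)
    cc <- c_new
    k <- k + 1L
    if (delta < epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "scaled Hirshfeld did not converge in %d iterations (last max |delta c| = %.3g)",
      k_max, history[length(history)]))
  }
  promol_final <- drop(g %*% cc)
  retained_final <- promol_final > tau
  objective <- .ext_kl_value(rho, promol_final, grid$weights, retained_final)
  structure(
    list(coefficients = cc, populations = N, charges = z - N,
         reference_populations = n0,
         iterations = k, converged = converged, history = history,
         objective = objective, objective_history = obj_history,
         excluded_points = sum(!sw$retained),
         elements = element_symbol(z), centers = centers,
         settings = list(epsilon = epsilon, k_max = k_max, tau = tau,
                         grid = grid$settings)),
    class = "sh_partition"
  )
}

#' Classic Hirshfeld partitioning
#'
#' Single stockholder pass with all scaling coefficients fixed at 1 (the
#' neutral promolecule). Identical, bit for bit, to
#' `run_scaled_hirshfeld(..., k_max = 0)`.
#'
#' @inheritParams run_scaled_hirshfeld
#' @return An `sh_partition` (with `iterations = 0`).
#' @export
run_hirshfeld <- function(density, proatoms, centers, grid,
                          tau = .DENSITY_FLOOR) {
  run_scaled_hirshfeld(density, proatoms, centers, grid,
                       epsilon = 1e-6, k_max = 0L, init = NULL, tau = tau)
}

# extended-KL divergence value on retained points (rho clamped to avoid
# 0 * log(0))
.ext_kl_value <- function(rho, promol, wq, retained) {
  r <- pmax(rho[retained], 1e-300)
  p <- promol[retained]
  sum(wq[retained] * (rho[retained] * log(r / p) + p - rho[retained]))
}

#' @export
print.sh_partition <- function(x, digits = 6, ...) {
  cat(sprintf("Stockholder partition: %d atoms, %d update(s), %s\n",
              length(x$coefficients), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  df <- data.frame(element = x$elements,
                   c = signif(x$coefficients, digits),
                   N = signif(x$populations, digits),
                   q = signif(x$charges, digits))
  print(df, row.names = FALSE)
  cat(sprintf("ext-KL objective: %.*g\n", digits, x$objective))
  invisible(x)
}

# ---- f-divergences ----------------------------------------------------------

#' Built-in f-divergence generators
#'
#' Returns a generator object for the named convex function f. The extended
#' Kullback-Leibler generator `f(x) = -ln x + x - 1` is the one whose
#' minimization defines the scaled-Hirshfeld promolecule (it satisfies
#' f(1) = f'(1) = 0, so it applies to unnormalized densities); the classic
#' KL generator `-ln x` and the squared-Hellinger generator `0.5 (x-1)^2`
#' are provided as diagnostics.
#'
#' @param name One of `"extkl"`, `"kl"`, `"hellinger"`.
#' @return An object of class `f_generator` with components `name`, `f`,
#'   `f_prime`.
#' @export
divergence_generator <- function(name = c("extkl", "kl", "hellinger")) {
  name <- match.arg(name)
  gen <- switch(name,
    extkl = list(f = function(x) -log(x) + x - 1,
                 f_prime = function(x) 1 - 1 / x),
    kl = list(f = function(x) -log(x),
              f_prime = function(x) -1 / x),
    hellinger = list(f = function(x) 0.5 * (x - 1)^2,
                     f_prime = function(x) x - 1)
  )
  structure(c(list(name = name), gen), class = "f_generator")
}

#' Check f-divergence generator admissibility
#'
#' An admissible generator for stockholder partitioning of unnormalized
#' densities must be convex with `f(1) = 0` and `f'(1) = 0`. This checks
#' `|f(1)| <= 1e-12`, `|f'(1)| <= 1e-12` and nonnegativity (to -1e-10) of
#' second differences of f on a sample of x in [0.05, 20].
#'
#' @param gen An `f_generator` (or any list with `f` and `f_prime`).
#' @return `TRUE` if admissible, else `FALSE`.
#' @export
check_generator <- function(gen) {
  f1 <- gen$f(1)
  fp1 <- gen$f_prime(1)
  if (!is.finite(f1) || abs(f1) > 1e-12) return(FALSE)
  if (!is.finite(fp1) || abs(fp1) > 1e-12) return(FALSE)
  x <- seq(0.05, 20, length.out = 400L)
  fx <- gen$f(x)
  d2 <- diff(fx, differences = 2L)
  all(is.finite(fx)) && all(d2 >= -1e-10)
}

#' f-divergence between molecule and promolecule on a grid
#'
#' `D_f = sum_i w_i rho_mol_i f(rho_promol_i / rho_mol_i)` over retained
#' points. Points where the molecular density is positive but the
#' promolecule is not are excluded and counted in the `excluded` attribute.
#'
#' @param rho_mol,rho_promol Density values at the grid points.
#' @param grid A `molecular_grid`.
#' @param gen An `f_generator` or a generator name.
#' @return The divergence (scalar, >= 0 up to quadrature noise), with
#'   attribute `excluded` (number of skipped points).
#' @export
f_divergence <- function(rho_mol, rho_promol, grid, gen = "extkl") {
  if (is.character(gen)) gen <- divergence_generator(gen)
  rho_mol <- as.numeric(rho_mol)
  rho_promol <- as.numeric(rho_promol)
  if (length(rho_mol) != length(rho_promol) ||
      length(rho_mol) != nrow(grid$points)) {
    stop("rho_mol, rho_promol and grid must describe the same points")
  }
  bad <- rho_mol > .DENSITY_FLOOR & rho_promol <= 0
  keep <- rho_mol > .DENSITY_FLOOR & rho_promol > 0
  r <- rho_mol[keep]
  val <- sum(grid$weights[keep] * r * gen$f(rho_promol[keep] / r))
  structure(val, excluded = sum(bad))
}

# ---- variational formulation ------------------------------------------------

#' Variational (extended-KL) determination of the scaling coefficients
#'
#' Minimizes the extended Kullback-Leibler divergence between the molecular
#' density and the scaled promolecule `sum_A c_A rho0_A` over the positive
#' coefficients, by a damped Newton iteration with the analytic gradient
#' `n0_A - int rho_mol rho0_A / rho0_mol dr` and Hessian
#' `int rho_mol rho0_A rho0_B / (rho0_mol)^2 dr` (positive semidefinite, so
#' the problem is convex and the solution unique). With
#' `with_constraint = TRUE` the electron-number constraint
#' `sum_A c_A n0_A = N_mol` is enforced through an explicit Lagrange
#' multiplier lambda (bordered Newton system); at the solution lambda
#' vanishes, which is what makes the unconstrained stationarity identical to
#' the fixed-point condition `c_A = N_A / n0_A`.
#'
#' @inheritParams run_scaled_hirshfeld
#' @param with_constraint Enforce `sum_A c_A n0_A = N_mol` explicitly and
#'   report the multiplier (default `TRUE`).
#' @param tol Stationarity tolerance: `max_A |gradient_A| / n0_A <= tol`
#'   (default 1e-10).
#' @param max_iter Newton iteration cap (default 200).
#' @return List with `coefficients`, `lambda` (`NA` when unconstrained),
#'   `residual` (max scaled stationarity residual), `iterations`,
#'   `converged`, `objective`.
#' @export
solve_variational <- function(density, proatoms, centers, grid,
                              with_constraint = TRUE, tol = 1e-10,
                              max_iter = 200L, tau = .DENSITY_FLOOR) {
  centers <- as_point_matrix(centers)
  g <- .proatom_matrix(proatoms, centers, grid$points)
  rho <- .density_values(density, grid)
  n0 <- vapply(proatoms, proatom_population, numeric(1))
  m <- length(proatoms)
  wq <- grid$weights
  n_mol <- sum(wq * rho)

  moments <- function(cc) {
    promol <- drop(g %*% cc)
    keep <- promol > tau
    t1 <- wq[keep] * rho[keep] / promol[keep]
    gk <- g[keep, , drop = FALSE]
    mom <- drop(crossprod(gk, t1))
    hess <- crossprod(gk * sqrt(t1 / promol[keep]))
    list(m = mom, H = hess)
  }

  cc <- rep(1, m)
  lambda <- 0
  converged <- FALSE
  it <- 0L
  resid <- Inf
  for (it in seq_len(as.integer(max_iter))) {
    mo <- moments(cc)
    if (with_constraint) {
      res <- c(n0 - mo$m + lambda * n0, sum(cc * n0) - n_mol)
      resid <- max(abs(res[seq_len(m)]) / n0, abs(res[m + 1L]) / max(n_mol, 1))
      if (resid <= tol) { converged <- TRUE; break }
      J <- rbind(cbind(mo$H, n0), c(n0, 0))
      step <- tryCatch(solve(J, -res), error = function(e) {
        stop("variational optimizer failure (singular KKT system); ",
             "stationarity residuals: ",
             paste(signif(res, 4), collapse = ", "))
      })
      dc <- step[seq_len(m)]
      dl <- step[m + 1L]
      damp <- 1
      while (any(cc + damp * dc <= 0) && damp > 1e-8) damp <- damp / 2
      cc <- cc + damp * dc
      lambda <- lambda + damp * dl
    } else {
      res <- n0 - mo$m
      resid <- max(abs(res) / n0)
      if (resid <= tol) { converged <- TRUE; break }
      dc <- tryCatch(solve(mo$H, -res), error = function(e) {
        stop("variational optimizer failure (singular Hessian); ",
             "stationarity residuals: ",
             paste(signif(res, 4), collapse = ", "))
      })
      damp <- 1
      while (any(cc + damp * dc <= 0) && damp > 1e-8) damp <- damp / 2
      cc <- cc + damp * dc
    }
  }
  if (!converged) {
    stop("variational optimizer failure: residual ", signif(resid, 4),
         " after ", max_iter, " Newton steps")
  }
  promol <- drop(g %*% cc)
  keep <- promol > tau
  list(coefficients = cc,
       lambda = if (with_constraint) lambda else NA_real_,
       residual = resid, iterations = it, converged = converged,
       objective = .ext_kl_value(rho, promol, wq, keep))
}
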