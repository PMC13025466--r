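test_that("stockholder weights follow the scaled-promolecule arithmetic", {
  g <- rbind(c(0.2, 0.2), c(0.4, 0.1), c(0, 0))
  sw <- stockholder_weights(g, c(1, 1))
  expect_equal(sw$weights[1, ], c(0.5, 0.5))
  sw2 <- stockholder_weights(g, c(2, 1))
  expect_equal(sw2$weights[1, ], c(2 / 3, 1 / 3), tolerance = 1e-15)
  # all-zero proatom point is excluded with zero weights
  expect_false(sw$retained[3])
  expect_equal(sw$weights[3, ], c(0, 0))
  expect_error(stockholder_weights(g, c(1, 0)), "invalid coefficient")
  expect_error(stockholder_weights(g, c(1, -2)), "invalid coefficient")
})

test_that("atomic populations integrate the weighted density", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.4))
  sys <- make_promolecular_system(c("H", "H"), pos)
  grid <- quick_grid(pos, c(1, 1))
  gmat <- .proatom_matrix(sys$proatoms, pos, grid$points)
  rho <- eval_density(sys$density, grid$points)
  sw <- stockholder_weights(gmat, c(1, 1))
  N <- atomic_populations(rho, sw, grid)
  expect_equal(N[1], N[2], tolerance = 1e-12)

  # single atom: partition of unity makes N the full integral
  g1 <- quick_grid(rbind(c(0, 0, 0)), 6)
  p6 <- build_neutral_proatom(6)
  gmat1 <- .proatom_matrix(list(p6), rbind(c(0, 0, 0)), g1$points)
  rho1 <- 1.3 * gmat1[, 1]
  N1 <- atomic_populations(rho1, stockholder_weights(gmat1, 1), g1)
  expect_equal(N1, grid_integrate(g1, rho1), tolerance = 1e-12)
  expect_error(atomic_populations(rho1[-1], stockholder_weights(gmat1, 1), g1),
               "same points")
})

test_that("far-separated atoms keep their own electrons", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 20))
  sys <- make_promolecular_system(c("H", "H"), pos, c(0.9, 1.1))
  grid <- quick_grid(pos, c(1, 1), 60L, 10L)
  res <- run_hirshfeld(sys$density, sys$proatoms, pos, grid)
  expect_lt(abs(res$populations[1] - 0.9), 5e-4)
  expect_lt(abs(res$populations[2] - 1.1), 5e-4)
})

test_that("the coefficient update is the population ratio", {
  expect_equal(update_coefficients(6.2, 6), 31 / 30)
  expect_equal(update_coefficients(c(1, 8), c(1, 8)), c(1, 1))
  expect_equal(update_coefficients(c(0.9, 7.1), c(1, 8)), c(0.9, 0.8875))
  expect_error(update_coefficients(c(0, 1), c(1, 1)), "degenerate")
})

test_that("a uniformly scaled single atom converges in one update", {
  g1 <- quick_grid(rbind(c(0, 0, 0)), 8)
  p <- build_neutral_proatom(8)
  rho <- 1.3 * evaluate_proatom(p, .dist_to_center(g1$points, c(0, 0, 0)))
  res <- run_scaled_hirshfeld(rho, list(p), rbind(c(0, 0, 0)), g1,
                              epsilon = 1e-6)
  expect_true(res$converged)
  expect_equal(res$coefficients, 1.3, tolerance = 1e-7)
})

test_that("an exact neutral promolecule is already the fixed point", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 2.0))
  sys <- make_promolecular_system(c("C", "O"), pos)
  grid <- build_molecular_grid(pos, c(6, 8))  # default accuracy
  res <- run_scaled_hirshfeld(sys$density, sys$proatoms, pos, grid,
                              epsilon = 1e-6)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_lt(res$history[1], 1e-6)
  expect_equal(res$coefficients, c(1, 1), tolerance = 1e-6)
})

test_that("bonded-distance promolecule coefficients are recovered", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.6))
  sys <- make_promolecular_system(c("H", "H"), pos, c(0.9, 1.1))
  grid <- quick_grid(pos, c(1, 1), 60L, 12L)
  eps <- 1e-9
  res <- run_scaled_hirshfeld(sys$density, sys$proatoms, pos, grid,
                              epsilon = eps)
  # solver distance plus the grid's population bias
  tol <- 10 * eps + grid_selfcheck(grid, lapply(1:2, function(a) {
    scaled_proatom(sys$proatoms[[a]], pos[a, ], sys$true_coefficients[a])
  }))
  expect_lt(max(abs(res$coefficients - c(0.9, 1.1))), tol)
  # c_A = N_A / n0_A holds exactly at the returned state
  expect_equal(res$coefficients,
               res$populations / res$reference_populations, tolerance = 1e-15)
})

test_that("classic Hirshfeld is the zero-update limit", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.5))
  sys <- make_charge_transfer_system(c("H", "H"), pos, transfer = 0.1)
  grid <- quick_grid(pos, c(1, 1))
  h <- run_hirshfeld(sys$density, sys$proatoms, pos, grid)
  s0 <- run_scaled_hirshfeld(sys$density, sys$proatoms, pos, grid, k_max = 0)
  expect_identical(h$coefficients, s0$coefficients)
  expect_identical(h$populations, s0$populations)
  expect_identical(h$charges, s0$charges)
  expect_identical(h$iterations, 0L)
  # charge transfer conserves electrons, so the charges balance to grid noise
  expect_lt(abs(sum(h$charges)), 5e-4)
  sysn <- make_promolecular_system(c("H", "H"), pos)
  hn <- run_hirshfeld(sysn$density, sysn$proatoms, pos, grid)
  expect_lt(max(abs(hn$charges)), 5e-4)
})

test_that("weights sum to one and electrons are conserved at every iteration", {
  sys <- random_fixture(BASE_SEED + 30, n_atoms = 3)
  grid <- quick_grid(sys$positions, sys$atomic_numbers)
  gmat <- .proatom_matrix(sys$proatoms, sys$positions, grid$points)
  rho <- eval_density(sys$density, grid$points)
  n0 <- vapply(sys$proatoms, proatom_population, numeric(1))
  cc <- rep(1, 3)
  for (k in 1:6) {
    sw <- stockholder_weights(gmat, cc)
    sums <- rowSums(sw$weights[sw$retained, , drop = FALSE])
    expect_lt(max(abs(sums - 1)), 1e-12)
    N <- atomic_populations(rho, sw, grid)
    lhs <- sum(N)
    rhs <- sum(grid$weights[sw$retained] * rho[sw$retained])
    expect_lt(abs(lhs - rhs) / rhs, 1e-12)
    cc <- update_coefficients(N, n0)
  }
})

test_that("the fixed point is independent of the initialization", {
  sys <- random_fixture(BASE_SEED + 31, n_atoms = 3)
  grid <- quick_grid(sys$positions, sys$atomic_numbers)
  eps <- 1e-8
  set.seed(BASE_SEED + 32)
  sols <- lapply(1:5, function(i) {
    init <- exp(runif(3, log(0.2), log(5)))
    run_scaled_hirshfeld(sys$density, sys$proatoms, sys$positions, grid,
                         epsilon = eps, init = init)$coefficients
  })
  ref <- sols[[1]]
  for (s in sols[-1]) expect_lt(max(abs(s - ref)), 10 * eps)
})

test_that("atom permutation permutes the result and symmetry is exact", {
  sys <- random_fixture(BASE_SEED + 33, n_atoms = 3)
  grid <- quick_grid(sys$positions, sys$atomic_numbers)
  res <- run_scaled_hirshfeld(sys$density, sys$proatoms, sys$positions, grid,
                              epsilon = 1e-9)
  perm <- c(3, 1, 2)
  gridp <- quick_grid(sys$positions[perm, ], sys$atomic_numbers[perm])
  resp <- run_scaled_hirshfeld(sys$density, sys$proatoms[perm],
                               sys$positions[perm, ], gridp, epsilon = 1e-9)
  expect_equal(resp$coefficients, res$coefficients[perm], tolerance = 1e-8)

  pos <- rbind(c(0, 0, -0.7), c(0, 0, 0.7))
  sysh <- make_promolecular_system(c("N", "N"), pos, c(1.08, 1.08))
  gh <- quick_grid(pos, c(7, 7))
  rh <- run_scaled_hirshfeld(sysh$density, sysh$proatoms, pos, gh,
                             epsilon = 1e-10)
  expect_lt(abs(rh$coefficients[1] - rh$coefficients[2]), 1e-10)
})

test_that("non-convergence is reported, not hidden", {
  sys <- random_fixture(BASE_SEED + 34, n_atoms = 2,
                        mode = "charge_transfer")
  grid <- quick_grid(sys$positions, sys$atomic_numbers)
  expect_warning(
    res <- run_scaled_hirshfeld(sys$density, sys$proatoms, sys$positions,
                                grid, epsilon = 1e-12, k_max = 2),
    "did not converge")
  expect_false(res$converged)
  expect_length(res$history, 2L)
})

test_that("f-divergences vanish at equality and obey closed forms", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.4))
  sys <- make_promolecular_system(c("H", "H"), pos)
  grid <- quick_grid(pos, c(1, 1))
  rho <- eval_density(sys$density, grid$points)
  for (gname in c("extkl", "kl", "hellinger")) {
    expect_lt(abs(f_divergence(rho, rho, grid, gname)), 1e-12)
  }
  # promolecule exactly 3x the molecule: Hellinger integrand is 2 rho
  hel <- f_divergence(rho, 3 * rho, grid, "hellinger")
  expect_equal(as.numeric(hel), 2 * grid_integrate(grid, rho),
               tolerance = 1e-12)
  gen <- divergence_generator("hellinger")
  expect_equal(gen$f(3), 2.0)
  expect_error(divergence_generator("nope"))
})

test_that("generator admissibility implements the f(1) = f'(1) = 0 contract", {
  expect_true(check_generator(divergence_generator("extkl")))
  gen <- divergence_generator("extkl")
  expect_identical(gen$f(1), 0)
  expect_identical(gen$f_prime(1), 0)
  # plain KL fails the normalized contract: f'(1) = -1
  expect_false(check_generator(divergence_generator("kl")))
  expect_false(check_generator(list(f = function(x) x - 1,
                                    f_prime = function(x) rep(1, length(x)))))
  # concave function fails convexity
  expect_false(check_generator(list(f = function(x) -(x - 1)^2,
                                    f_prime = function(x) -2 * (x - 1))))
})

test_that("variational and fixed-point solutions coincide", {
  for (seed in BASE_SEED + 40:42) {
    sys <- random_fixture(seed, n_atoms = c(2, 4), mode = "charge_transfer")
    grid <- quick_grid(sys$positions, sys$atomic_numbers)
    fp <- run_scaled_hirshfeld(sys$density, sys$proatoms, sys$positions, grid,
                               epsilon = 1e-10, k_max = 2000)
    va <- solve_variational(sys$density, sys$proatoms, sys$positions, grid,
                            with_constraint = TRUE)
    expect_lt(max(abs(fp$coefficients - va$coefficients)), 1e-8)
    expect_lt(abs(va$lambda), 1e-6)
    vu <- solve_variational(sys$density, sys$proatoms, sys$positions, grid,
                            with_constraint = FALSE)
    expect_lt(max(abs(vu$coefficients - va$coefficients)), 1e-8)
    expect_true(is.na(vu$lambda))
    # the minimum is at least as good as the fixed point's objective
    expect_lte(va$objective, fp$objective + 1e-10)
  }
})

test_that("the variational solver recovers exact promolecule coefficients", {
  sys <- random_fixture(BASE_SEED + 43, n_atoms = 3)
  grid <- quick_grid(sys$positions, sys$atomic_numbers, 60L, 12L)
  va <- solve_variational(sys$density, sys$proatoms, sys$positions, grid)
  expect_lt(max(abs(va$coefficients - sys$true_coefficients)), 1e-5)
  expect_gte(va$objective, -1e-10)
})

test_that("partitioning two fragments jointly equals partitioning them apart", {
  sysA <- make_promolecular_system(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 1.7)),
                                   c(0.9, 1.1))
  sysB <- make_promolecular_system(c("C", "O"), rbind(c(28, 0, 0), c(28, 0, 2.1)),
                                   c(1.05, 0.95))
  joint_pos <- rbind(sysA$positions, sysB$positions)
  joint_z <- c(sysA$atomic_numbers, sysB$atomic_numbers)
  joint_density <- density_from_shells(
    rbind(sysA$density$centers, sysB$density$centers),
    c(sysA$density$amplitudes, sysB$density$amplitudes),
    c(sysA$density$exponents, sysB$density$exponents))
  eps <- 1e-9
  gj <- quick_grid(joint_pos, joint_z, 60L, 12L)
  rj <- run_scaled_hirshfeld(joint_density, c(sysA$proatoms, sysB$proatoms),
                             joint_pos, gj, epsilon = eps)
  sep <- unlist(lapply(list(sysA, sysB), function(s) {
    g <- quick_grid(s$positions, s$atomic_numbers, 60L, 12L)
    run_scaled_hirshfeld(s$density, s$proatoms, s$positions, g,
                         epsilon = eps)$coefficients
  }))
  expect_lt(max(abs(rj$coefficients - sep)), 1e-5)
})
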