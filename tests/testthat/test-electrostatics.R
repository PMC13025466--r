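test_that("point-charge dipoles follow the defining sum", {
  expect_equal(point_charge_dipole(c(0.5, -0.5),
                                   rbind(c(1, 0, 0), c(-1, 0, 0))),
               c(1, 0, 0))
  expect_equal(point_charge_dipole(c(0, 0), rbind(c(1, 2, 3), c(-4, 0, 1))),
               c(0, 0, 0))
  # translation shifts the dipole by t * sum(q); invariant for neutral sets
  pos <- rbind(c(0.3, 1, -2), c(2, 0, 0.5))
  q <- c(0.31, -0.31)
  shifted <- sweep(pos, 2, c(5, -3, 2), "+")
  expect_equal(point_charge_dipole(q, pos), point_charge_dipole(q, shifted),
               tolerance = 1e-12)
})

test_that("dipole errors are norms in debye", {
  pos <- rbind(c(1, 0, 0), c(-1, 0, 0))
  q <- c(0.5, -0.5)
  mu <- point_charge_dipole(q, pos)
  expect_equal(dipole_error(mu, q, pos), 0)
  expect_equal(dipole_error(c(1, 0, 0), c(0, 0), pos), 2.5417464519,
               tolerance = 1e-10)
})

test_that("spherical-atom densities have the dipole of their populations", {
  # single neutral spherical atom anywhere: zero dipole
  pos1 <- rbind(c(0.7, -1.2, 2.0))
  sys1 <- make_promolecular_system("O", pos1)
  g1 <- quick_grid(pos1, 8, 60L, 12L)
  mu1 <- reference_dipole(sys1$density, g1, 8, pos1)
  expect_lt(sqrt(sum(as.numeric(mu1)^2)), 1e-6)

  # heteronuclear scaled pair: shell theorem gives mu = sum (Z - c n0) R
  pos <- rbind(c(1, 0, 0), c(-1, 0, 0))
  sys <- make_promolecular_system(c("H", "H"), pos, c(0.9, 1.1))
  g <- quick_grid(pos, c(1, 1), 60L, 12L)
  mu <- reference_dipole(sys$density, g, c(1, 1), pos)
  exact <- drop(crossprod(pos, c(1 - 0.9, 1 - 1.1)))
  expect_equal(as.numeric(mu), exact, tolerance = 1e-5)

  # neutral promolecule: zero dipole
  w <- water_like()
  sysw <- make_promolecular_system(w$elements, w$positions)
  gw <- quick_grid(w$positions, w$z, 60L, 12L)
  muw <- reference_dipole(sysw$density, gw, w$z, w$positions)
  expect_lt(sqrt(sum(as.numeric(muw)^2)), 1e-5)
})

test_that("the scaled vdW surface keeps only exterior points", {
  s1 <- sample_vdw_surface("C", rbind(c(0, 0, 0)), points_per_atom = 100)
  expect_equal(nrow(s1$points), 100L)
  r <- sqrt(rowSums(s1$points^2))
  expect_lt(max(abs(r - 2.5 * vdw_radius("C"))), 1e-10)

  far <- sample_vdw_surface(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 50)),
                            points_per_atom = 80)
  expect_equal(nrow(far$points), 160L)

  near <- sample_vdw_surface(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                             points_per_atom = 80)
  expect_lt(nrow(near$points), 160L)
  # every retained point is outside every scaled sphere
  for (a in 1:2) {
    d <- .dist_to_center(near$points, rbind(c(0, 0, 0), c(0, 0, 1.4))[a, ])
    expect_true(all(d >= 2.5 * vdw_radius("H") - 1e-10))
  }
  expect_error(vdw_radius(99), "radius")
  # seeded rotation is reproducible and seed-dependent
  sa <- sample_vdw_surface("C", rbind(c(0, 0, 0)), points_per_atom = 50, seed = 4)
  sb <- sample_vdw_surface("C", rbind(c(0, 0, 0)), points_per_atom = 50, seed = 4)
  sc <- sample_vdw_surface("C", rbind(c(0, 0, 0)), points_per_atom = 50, seed = 5)
  expect_identical(sa$points, sb$points)
  expect_false(isTRUE(all.equal(sa$points, sc$points)))
})

test_that("exterior potentials obey the shell theorem", {
  pos <- rbind(c(0, 0, 0))
  sys <- make_promolecular_system("N", pos)
  pts <- rbind(c(4, 0, 0), c(0, -6, 1), c(3, 3, 3))
  v <- esp_reference(sys$density, 7, pos, pts)
  expect_lt(max(abs(v)), 1e-8)  # neutral atom: Z/r cancels the shells

  sysc <- make_promolecular_system("N", pos, 0.9)
  vc <- esp_reference(sysc$density, 7, pos, pts)
  d <- sqrt(rowSums(pts^2))
  expect_equal(vc, (7 - 0.9 * 7) / d, tolerance = 1e-6)

  # a bare 1-electron Gaussian shell at 10 sigma behaves as -1/r
  shell <- density_from_shells(rbind(c(0, 0, 0)), (2 / pi)^1.5, 2)
  far <- rbind(c(10 * 0.5, 0, 0))  # sigma = 1/sqrt(2 alpha) = 0.5
  vfar <- esp_reference(shell, numeric(0), matrix(numeric(0), 0, 3), far)
  expect_equal(vfar, -1 / far[1, 1], tolerance = 1e-10)

  expect_error(esp_reference(sys$density, 7, pos, rbind(c(0, 0, 0))),
               "coincident")
})

test_that("surface ESP errors vanish for a partition of spherical atoms", {
  sys <- random_fixture(BASE_SEED + 50, n_atoms = 3)
  grid <- quick_grid(sys$positions, sys$atomic_numbers, 60L, 12L)
  res <- run_scaled_hirshfeld(sys$density, sys$proatoms, sys$positions, grid,
                              epsilon = 1e-9)
  surf <- sample_vdw_surface(sys$elements, sys$positions, seed = 11)
  surf <- esp_reference(sys$density, sys$atomic_numbers, sys$positions, surf)
  expect_lt(esp_mae(surf, res$charges, sys$positions), 1e-3)
  mu <- reference_dipole(sys$density, grid, sys$atomic_numbers, sys$positions)
  expect_lt(dipole_error(mu, res$charges, sys$positions), 1e-3)
})

test_that("the MAE of simple charge models has a closed form", {
  pos <- rbind(c(0, 0, 0))
  sysc <- make_promolecular_system("H", pos, 0.8)  # q = +0.2
  surf <- sample_vdw_surface("H", pos, points_per_atom = 60)
  surf <- esp_reference(sysc$density, 1, pos, surf)
  mae <- esp_mae(surf, 0, pos)
  # q/r up to the ~0.5% of the model H density not enclosed by the surface
  expect_equal(mae, 0.2 / (2.5 * vdw_radius("H")) * 627.5094740631,
               tolerance = 0.01)
  surf0 <- surf
  surf0$reference_potential <- numeric(nrow(surf$points))
  expect_equal(esp_mae(surf0, 0, pos), 0)
})

test_that("neutral point-charge ESP errors decay at least quadratically", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 1.8))
  sys <- make_charge_transfer_system(c("H", "F"), pos, transfer = 0.2)
  grid <- quick_grid(pos, c(1, 9), 60L, 12L)
  res <- run_hirshfeld(sys$density, sys$proatoms, pos, grid)
  mae <- vapply(c(2.5, 5, 10), function(sc) {
    s <- sample_vdw_surface(c("H", "F"), pos, scale = sc)
    s <- esp_reference(sys$density, c(1, 9), pos, s)
    esp_mae(s, res$charges, pos)
  }, numeric(1))
  expect_lt(mae[2], mae[1] / 4 * 1.5)
  expect_lt(mae[3], mae[2] / 4 * 1.5)
})

test_that("charge-set comparison reports R^2 and the regression slope", {
  set.seed(BASE_SEED + 51)
  b <- rnorm(40)
  expect_equal(compare_charge_sets(b, b)[c("r_squared", "slope")],
               list(r_squared = 1, slope = 1), tolerance = 1e-12)
  half <- compare_charge_sets(0.5 * b, b)
  expect_equal(half$r_squared, 1, tolerance = 1e-12)
  expect_equal(half$slope, 0.5, tolerance = 1e-12)
  noise <- compare_charge_sets(rnorm(1000), rnorm(1000))
  expect_lt(noise$r_squared, 0.02)
  expect_error(compare_charge_sets(1:2, 1:2), "insufficient")
})

test_that("surface comparisons export as CSV", {
  pos <- rbind(c(0, 0, 0))
  sys <- make_promolecular_system("H", pos, 0.8)
  surf <- sample_vdw_surface("H", pos, points_per_atom = 20)
  surf <- esp_reference(sys$density, 1, pos, surf)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_esp_csv(surf, 0.2, pos, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 20L)
  expect_equal(back$abs_error, df$abs_error, tolerance = 1e-10)
})
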