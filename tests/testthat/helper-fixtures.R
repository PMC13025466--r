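# Shared helpers: compact grids keep the unit tests fast; the acceptance
# tests use the package defaults where the check demands them.

BASE_SEED <- 20260323L

quick_grid <- function(positions, z, n_radial = 40L, angular_order = 10L) {
  build_molecular_grid(positions, z, n_radial = n_radial,
                       angular_order = angular_order)
}

# independent radial-quadrature oracle for proatom populations:
# 4 pi int r^2 rho(r) dr on n Gauss-Legendre nodes mapped by r = rm (1+x)/(1-x)
radial_population_oracle <- function(p, n = 200L, rm = 1.0) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  r <- rm * (1 + gl$x) / (1 - gl$x)
  jac <- 2 * rm / (1 - gl$x)^2
  sum(gl$w * jac * 4 * pi * r^2 * evaluate_proatom(p, r))
}

# H2O-like bent 3-center toy geometry (bohr)
water_like <- function() {
  list(
    elements = c("O", "H", "H"),
    z = c(8L, 1L, 1L),
    positions = rbind(c(0, 0, 0),
                      c(1.43, 0, 1.11),
                      c(-1.43, 0, 1.11))
  )
}
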