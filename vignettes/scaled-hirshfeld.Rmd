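---
title: "Scaled Hirshfeld partitioning: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaled Hirshfeld partitioning: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shpart)
```

## The model

Stockholder partitioning divides a molecular electron density
$\rho_{\mathrm{mol}}(\mathbf r)$ among atoms with fuzzy weights
$w_A(\mathbf r) \ge 0$, $\sum_A w_A = 1$, so that the atomic densities
$\rho_A = w_A \rho_{\mathrm{mol}}$ reconstruct the molecule exactly. In
Hirshfeld-family schemes the weights come from spherical reference
proatom densities $\rho^0_A(r)$:
$$ w_A(\mathbf r) = \frac{c_A\,\rho^0_A(|\mathbf r - \mathbf R_A|)}
                         {\sum_B c_B\,\rho^0_B(|\mathbf r - \mathbf R_B|)}. $$
Classic Hirshfeld fixes every scaling coefficient $c_A = 1$. The scaled
Hirshfeld (SH) scheme implemented here instead determines the $c_A > 0$
self-consistently by demanding that each scaled proatom hold exactly the
population its atom receives:
$$ N_A = \int \rho_{\mathrm{mol}}\, w_A \,\mathrm d\mathbf r,
   \qquad c_A = N_A / n^0_A, $$
with $n^0_A = \int \rho^0_A\,\mathrm d\mathbf r$ the neutral reference
population. `run_scaled_hirshfeld()` iterates these two steps from
$c_A = 1$ until $\max_A |\Delta c_A| < \varepsilon$; charges are
$q_A = Z_A - N_A$ (the universal convention).

The same coefficients are the unique minimizer of the extended
Kullback–Leibler (ext-KL) divergence between molecule and promolecule,
$$ D(\{c_A\}) = \int \rho_{\mathrm{mol}}
   \ln\frac{\rho_{\mathrm{mol}}}{\rho^0_{\mathrm{mol}}}
   + \rho^0_{\mathrm{mol}} - \rho_{\mathrm{mol}} \,\mathrm d\mathbf r, $$
whose generator $f(x) = -\ln x + x - 1$ satisfies the admissibility
contract $f(1) = f'(1) = 0$ required for unnormalized densities
(`check_generator()`); the linear extension terms make the
electron-number constraint $\sum_A c_A n^0_A = N_{\mathrm{mol}}$
*inactive*: its Lagrange multiplier vanishes at the stationary point,
which is exactly why the unconstrained stationarity condition collapses to
the fixed-point update. `solve_variational()` exposes both variants — a
damped Newton iteration on the analytic gradient
$n^0_A - \int \rho_{\mathrm{mol}} \rho^0_A / \rho^0_{\mathrm{mol}}\,
\mathrm d\mathbf r$ and Hessian
$\int \rho_{\mathrm{mol}} \rho^0_A \rho^0_B / (\rho^0_{\mathrm{mol}})^2\,
\mathrm d\mathbf r$ (positive semidefinite, hence convexity and a unique,
initialization-independent solution), and a bordered-Newton KKT solve with
one explicit multiplier $\lambda$, reported so the $\lambda = 0$ property
can be verified numerically. Because both solvers and the fixed point use
the same analytic $n^0_A$, their discrete stationary conditions are
identical and the two routes agree to solver tolerance, not merely to grid
accuracy.

Convexity also yields size consistency: for fragments with vanishing
density overlap the objective separates, so partitioning them jointly or
separately gives the same coefficients (tested at 26 bohr separation).

```{r example}
sys <- random_fixture(20260323, n_atoms = 3)
grid <- build_molecular_grid(sys$positions, sys$atomic_numbers,
                             n_radial = 50, angular_order = 12)
res <- run_scaled_hirshfeld(sys$density, sys$proatoms, sys$positions, grid,
                            epsilon = 1e-8)
res$coefficients - sys$true_coefficients  # exact promolecule: recovered
```

## Proatom models

The built-in library (`build_neutral_proatom()`, Z = 1–36) represents each
element as three s-type Gaussian shells with exponents in geometric
progression, $\alpha_j = 2\,Z^{4/3}\,4^{-(j-1)}$ bohr$^{-2}$, each shell
carrying $Z/3$ electrons. These are deliberately *model* proatoms: the
functional form was chosen because populations, dipoles and exterior
electrostatic potentials of Gaussian shells have closed forms
(erf-potentials), which supplies exact oracles for every downstream
quantity; the shapes are not fitted to real atomic densities and should
not be read as such. Users who need realistic proatoms supply radial
tables (`proatom_from_table()`, `read_proatom_table()`): the density is a
cubic spline of $\log\rho$ inside the tabulated range (positivity for
free; `fmm` boundary handling, since a natural spline would flatten the
log-density at the nucleus) with an exponential tail
$\rho(r_{\max})\,e^{-\beta (r - r_{\max})}$ beyond it. How a production
proatom should be spherically averaged (grids, multiplets) is out of this
package's hands — the table interface is the contract.

## Quadrature

`build_molecular_grid()` builds one product grid per atom and glues them
with Becke's smooth partition of space:

* radial: Gauss–Chebyshev (second kind) nodes under the rational map
  $r = R_m (1+x)/(1-x)$, with per-element midpoint $R_m$ = half the
  Bragg–Slater radius (1 bohr fallback). Default `n_radial = 75`.
* angular: Gauss–Legendre in $\cos\theta$ times a uniform trapezoid in
  $\phi$ — $(L+1) \times (2L+2)$ points for `angular_order` $L$, exact for
  band-limited spherical harmonics and self-contained (no Lebedev weight
  tables). Default $L = 17$.
* cells: Becke's iterated polynomial switching function with $k = 3$
  smoothing passes; atomic-size adjustment is available
  (`size_adjust = TRUE`) but off by default. No pruning — node economy is
  not worth the complexity at the problem sizes targeted here.

`grid_selfcheck()` integrates every proatom and reports the worst absolute
population error; at default settings the 3-center test systems stay below
$5 \times 10^{-4}$ electrons, the accuracy class production molecular
grids are usually held to, and single Gaussian atoms integrate to
$\sim 10^{-13}$.

## Numerical choices

* **Promolecule floor.** Grid points where
  $\rho^0_{\mathrm{mol}} \le \tau = 10^{-100}$ get zero weights and are
  excluded from every integral. Any physically meaningful molecular
  density is also negligible there, and exclusion keeps
  $\sum_A N_A = \int \rho_{\mathrm{mol}}$ *exact* over retained points
  (to rounding), not just to quadrature accuracy.
* **Convergence.** Defaults $\varepsilon = 10^{-6}$ on
  $\max_A|\Delta c_A|$ and `k_max = 500`; the per-iteration history and
  the equivalent population change are stored in the result. The ext-KL
  objective is logged per iteration but no monotonicity is asserted — the
  fixed-point map is not a descent method step by step, only its limit is
  the minimizer.
* **Degeneracies.** A vanishing atomic population would push a
  coefficient out of the $c_A > 0$ domain and raises an error, as do
  coincident nuclei (which would make the proatom profiles linearly
  dependent and the minimizer non-unique). Non-convergence at `k_max`
  returns the partial result flagged `converged = FALSE` with a warning.
* **Electrostatics conventions.** 1 bohr = 0.529177210903 Å, 1 a.u.
  dipole = 2.5417464519 D, 1 hartree = 627.5094740631 kcal/mol. Dipoles
  are evaluated about the center of nuclear charge, which only matters
  for net ions; `dipole_error()` reuses the reference origin so ionic
  comparisons stay well defined. The ESP surface is the union of
  2.5-scaled Bondi spheres, sampled with a Fibonacci lattice
  (170 points/atom before exclusion by default, equal weight per retained
  point — no area weighting) and an optional seeded rotation; the MAE is
  converted to kcal/mol per unit charge.

## The synthetic-data generator

`make_promolecular_system()` produces densities that are *exactly* scaled
promolecules with recorded coefficients — the partitioner must return them
to grid accuracy, which is the strongest end-to-end oracle available.
`make_charge_transfer_system()` perturbs the neutral promolecule by moving
electrons from a donor to an acceptor atom via opposite Gaussian
monopoles; the density is no longer promolecular, so the recovered
coefficients depart from 1 and the donor/acceptor acquire charges of known
sign while the total electron count is conserved in closed form. The
transfer Gaussian's default exponent is 1.5× the donor's most diffuse
shell exponent so the removed density decays faster than the donor's own
tail; nonnegativity is still verified on a molecular grid plus dense
probes along every interatomic axis, and too-aggressive perturbations are
refused. Monopoles sit on atoms, not bond midpoints — bond-centered
deformations would break the atom-centered closed-form ESP and are left as
an extension point. `random_fixture()` makes both kinds reproducibly from
a single seed (bonded-range geometries, minimum separation 1.2 bohr,
coefficients in [0.7, 1.3]) without disturbing the caller's RNG stream.

What these fixtures do *not* emulate: real deformation densities
(anisotropic bonding features, lone pairs, basis-set ripple), nuclear cusp
behaviour, or heavy-element shell structure. Passing tests therefore
demonstrate the correctness of the partitioning machinery and its
analytic properties — recovery, uniqueness, conservation, size
consistency, shell-theorem electrostatics — not chemical accuracy of
charges on real molecules, which depends on real densities and real
proatoms supplied by the user.

## Problem sizes used in the tests

The test-suite fixtures use 2–4 atoms; unit tests run on 40×10-order
grids (≈12,000 points/atom), while the end-to-end recovery and
electrostatics checks use the default 75×17 grid (48,600 points/atom) —
sizes at which every check is a desk-scale computation. Recovery of exact
promolecule coefficients holds to $10^{-4}$ at the default grid
($\sim 10^{-7}$ typical), fixed-point/variational agreement to
$10^{-5}$, and the constraint multiplier to $|\lambda| \le 10^{-6}$
($\sim 10^{-13}$ typical).

## Known limitations

* Built-in proatoms are Gaussian models with exact populations but
  unvalidated shapes; element coverage stops at Z = 36.
* Cube densities are interpolated trilinearly; integration and ESP
  accuracy are then limited by the voxel resolution of the input, and the
  quadrature Coulomb sum used for cube ESPs is slow for large surfaces.
* Only neutral-reference scaling is implemented — schemes requiring
  charged proatom references or larger proatom basis expansions are out
  of scope, as are ESP-fitted or empirically corrected charge models.
* The f-divergence generators other than ext-KL are diagnostics: the
  solvers minimize the ext-KL objective only. The classic KL generator
  $-\ln x$ fails the literal $f'(1) = 0$ contract used here
  (`check_generator()` reports `FALSE`); it is admissible only within the
  normalized-density formulation, a discrepancy this package documents
  rather than resolves.
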