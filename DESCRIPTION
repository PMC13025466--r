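Package: shpart
Title: Scaled Hirshfeld Stockholder Partitioning of Molecular Electron Densities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Atoms-in-molecules analysis by stockholder partitioning with
    scaled neutral proatoms. Implements the scaled Hirshfeld fixed-point
    iteration and the equivalent constrained variational formulation based
    on the extended Kullback-Leibler divergence, on Becke-style multicenter
    quadrature grids, together with dipole and electrostatic-potential
    error metrics for the resulting atomic point charges, synthetic
    Gaussian-shell test densities with known ground truth, and readers and
    writers for XYZ, extended XYZ and Gaussian cube files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
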