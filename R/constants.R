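# Unit conversions pinned to CODATA-2018 values so that file I/O (angstrom),
# internal math (bohr/hartree) and reported metrics (debye, kcal/mol) stay
# reproducible across platforms.
BOHR_TO_ANGSTROM <- 0.529177210903
ANGSTROM_TO_BOHR <- 1 / 0.529177210903
AU_TO_DEBYE <- 2.5417464519
HARTREE_TO_KCALMOL <- 627.5094740631

# Elements supported by the built-in proatom library (Z = 1..36).
ELEMENT_SYMBOLS <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

# Bragg-Slater covalent radii (angstrom), used only to place the midpoint of
# the radial quadrature map. Values without a tabulated entry (He, Ne) reuse
# the nearest light-element estimates; the grid is insensitive to them.
BRAGG_SLATER_ANGSTROM <- c(
  0.25, 0.25,
  1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.45,
  1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 1.00,
  2.20, 1.80, 1.60, 1.40, 1.35, 1.40, 1.40, 1.40, 1.35, 1.35, 1.35, 1.35,
  1.30, 1.25, 1.15, 1.15, 1.15, 1.10
)

# Bondi-style van der Waals radii (angstrom). Transition-metal entries fall
# back to consensus crystallographic estimates; all values can be overridden
# per call via the `radii` argument of sample_vdw_surface().
BONDI_VDW_ANGSTROM <- c(
  1.20, 1.40,
  1.81, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
  2.27, 1.73, 1.84, 2.10, 1.80, 1.80, 1.75, 1.88,
  2.75, 2.31, 2.15, 2.11, 2.07, 2.06, 2.05, 2.04, 2.00, 1.97, 1.96, 2.01,
  1.87, 2.11, 1.85, 1.90, 1.85, 2.02
)

#' Atomic number from an element symbol
#'
#' @param symbol Character vector of element symbols (case sensitive, "H".."Kr")
#'   or strings holding integer atomic numbers.
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(symbol) {
  z <- match(symbol, ELEMENT_SYMBOLS)
  num <- suppressWarnings(as.integer(symbol))
  z[is.na(z)] <- num[is.na(z)]
  if (anyNA(z) || any(z < 1L) || any(z > length(ELEMENT_SYMBOLS))) {
    bad <- symbol[is.na(z) | z < 1L | z > length(ELEMENT_SYMBOLS)]
    stop("unsupported element(s): ", paste(unique(bad), collapse = ", "),
         " (supported: Z = 1..", length(ELEMENT_SYMBOLS), ")")
  }
  z
}

#' Element symbol from an atomic number
#'
#' @param z Integer vector of atomic numbers in 1..36.
#' @return Character vector of symbols.
#' @export
element_symbol <- function(z) {
  z <- as.integer(z)
  if (anyNA(z) || any(z < 1L) || any(z > length(ELEMENT_SYMBOLS))) {
    stop("atomic number outside the supported range 1..",
         length(ELEMENT_SYMBOLS))
  }
  ELEMENT_SYMBOLS[z]
}

#' Van der Waals radius of an element
#'
#' Bondi-style radii used to construct the scaled van der Waals surface on
#' which electrostatic-potential errors are judged.
#'
#' @param element Element symbols or atomic numbers.
#' @param units `"bohr"` (default) or `"angstrom"`.
#' @return Numeric vector of radii.
#' @export
vdw_radius <- function(element, units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  z <- if (is.character(element)) atomic_number(element) else as.integer(element)
  if (any(z < 1L) || any(z > length(BONDI_VDW_ANGSTROM))) {
    stop("no tabulated van der Waals radius for Z = ",
         paste(z[z < 1L | z > length(BONDI_VDW_ANGSTROM)], collapse = ", "))
  }
  r <- BONDI_VDW_ANGSTROM[z]
  if (units == "bohr") r * ANGSTROM_TO_BOHR else r
}

# Radial-map midpoint (bohr) for the quadrature of one atom: half the
# Bragg-Slater radius, with a 1-bohr fallback outside the table.
radial_midpoint <- function(z) {
  z <- as.integer(z)
  out <- rep(1.0, length(z))
  ok <- z >= 1L & z <= length(BRAGG_SLATER_ANGSTROM)
  out[ok] <- 0.5 * BRAGG_SLATER_ANGSTROM[z[ok]] * ANGSTROM_TO_BOHR
  out
}

# rows of `points` (n x 3) to distances from `center` (length-3)
.dist_to_center <- function(points, center) {
  points <- as_point_matrix(points)
  sqrt((points[, 1] - center[1])^2 +
       (points[, 2] - center[2])^2 +
       (points[, 3] - center[3])^2)
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("points must be a length-3 vector or an n x 3 matrix")
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns")
  storage.mode(points) <- "double"
  points
}
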