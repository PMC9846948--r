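# Physical constants and small element tables used across the package.

#' @keywords internal
.avogadro <- 6.02214076e23

# 1 amu expressed in grams
#' @keywords internal
.amu_g <- 1.66053907e-24

# Coulomb prefactor in kcal*Angstrom/(mol*e^2)
#' @keywords internal
.coulomb_kcal <- 332.0637

# Standard atomic weights (amu) for the elements the builders and readers need.
#' @keywords internal
.atomic_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.90,
  # generic sites used by the synthetic builders
  A = 22.990, B2 = 35.45, X = 18.015
)

# Van der Waals radii (Angstrom, Bondi-style) for probe-accessible surfaces.
#' @keywords internal
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Ca = 2.31, Na = 2.27, Ar = 1.88, K = 2.75, X = 1.70,
  A = 2.27, B2 = 1.75
)

#' Look up a standard atomic mass
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    stop("no tabulated mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
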