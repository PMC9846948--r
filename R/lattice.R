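# Unit-cell geometry: direct/reciprocal bases, volumes, d-spacings, normals,
# crystallographic density and the ionic/covalent contact rule.

#' Construct a unit cell
#'
#' Defines a crystallographic unit cell from its six lattice parameters plus
#' optional symmetry information. The cell is stored with the standard
#' crystallographic Cartesian convention: \eqn{a} along x, \eqn{b} in the xy
#' plane. All derived geometry (volume, reciprocal basis, d-spacings) is
#' computed for the general triclinic case; higher-symmetry cells are just
#' special parameter values.
#'
#' @param a,b,c lattice lengths in Angstrom, all positive.
#' @param alpha,beta,gamma lattice angles in degrees, each in (0, 180).
#' @param space_group optional Hermann-Mauguin space-group symbol
#'   (e.g. \code{"C2/c"}); used to derive the Laue class when
#'   \code{laue_class} is not given.
#' @param laue_class optional Laue class, one of \code{"-1"}, \code{"2/m"},
#'   \code{"mmm"}, \code{"4/mmm"}, \code{"m-3m"}.
#' @return an object of class \code{unit_cell}.
#' @examples
#' # optimized Ca(Min)2 cell
#' uc <- unit_cell(19.27, 9.74, 17.05, beta = 107.99, space_group = "C2/c")
#' cell_volume(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      space_group = NULL, laue_class = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("lattice lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) {
    stop("lattice angles must lie strictly between 0 and 180 degrees")
  }
  basis <- .cell_basis(a, b, c, alpha, beta, gamma)
  if (!all(is.finite(basis)) || det(basis) <= 0) {
    stop("invalid cell: metric tensor is not positive definite")
  }
  if (is.null(laue_class) && !is.null(space_group)) {
    laue_class <- laue_from_spacegroup(space_group)
  }
  if (!is.null(laue_class)) laue_class <- match.arg(laue_class, .laue_classes)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 space_group = space_group, laue_class = laue_class),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4g b=%.4g c=%.4g Angstrom, alpha=%.4g beta=%.4g gamma=%.4g deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  if (!is.null(x$space_group)) cat("space group:", x$space_group, "\n")
  if (!is.null(x$laue_class)) cat("Laue class:", x$laue_class, "\n")
  cat(sprintf("volume: %.4f Angstrom^3\n", cell_volume(x)))
  invisible(x)
}

# direct basis as a 3x3 matrix with cell vectors in COLUMNS
#' @keywords internal
.cell_basis <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  av <- c(a, 0, 0)
  bv <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) return(matrix(NA_real_, 3, 3))
  m <- cbind(av, bv, c(cx, cy, sqrt(cz2)))
  dimnames(m) <- NULL
  m
}

#' Direct lattice basis of a cell
#'
#' @param cell a \code{unit_cell}.
#' @return 3x3 matrix whose columns are the cell vectors a, b, c (Angstrom).
#' @export
cell_basis <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  .cell_basis(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
}

#' Reciprocal lattice basis (no 2*pi factor)
#'
#' @param cell a \code{unit_cell}.
#' @return 3x3 matrix whose columns are a*, b*, c* in 1/Angstrom.
#' @export
reciprocal_basis <- function(cell) {
  A <- cell_basis(cell)
  t(solve(A))
}

#' Unit-cell volume
#'
#' Volume of the parallelepiped spanned by the cell vectors,
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#' +2\cos\alpha\cos\beta\cos\gamma}}; for a monoclinic cell this reduces to
#' \eqn{abc\sin\beta}.
#'
#' @param cell a \code{unit_cell}.
#' @return volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  v <- det(cell_basis(cell))
  if (!is.finite(v) || v <= 0) stop("invalid cell: non-positive volume")
  v
}

#' Validate a Miller index
#' @keywords internal
.check_hkl <- function(hkl) {
  hkl <- as.numeric(hkl)
  if (length(hkl) != 3 || anyNA(hkl)) stop("a Miller index needs three integers")
  if (any(hkl != round(hkl))) stop("Miller indices must be integers")
  if (all(hkl == 0)) stop("Miller index (0 0 0) is not a lattice plane")
  as.integer(hkl)
}

#' Interplanar spacing d_hkl
#'
#' Perpendicular distance between adjacent (h k l) lattice planes, computed
#' from the reciprocal metric: \eqn{d = 1/|h a^* + k b^* + l c^*|}. Valid for
#' any triclinic cell; for a b-unique monoclinic cell it is equivalent to
#' \eqn{1/d^2 = (h^2/a^2 + l^2/c^2 - 2hl\cos\beta/(ac))/\sin^2\beta + k^2/b^2}.
#'
#' @param cell a \code{unit_cell}.
#' @param hkl integer 3-vector, or an n x 3 matrix of indices.
#' @return spacing(s) in Angstrom.
#' @examples
#' uc <- unit_cell(19.27, 9.74, 17.05, beta = 107.99)
#' d_spacing(uc, c(2, 0, 0))   # 9.16
#' @export
d_spacing <- function(cell, hkl) {
  B <- reciprocal_basis(cell)
  if (is.matrix(hkl)) {
    apply(hkl, 1, function(h) 1 / sqrt(sum((B %*% .check_hkl(h))^2)))
  } else {
    1 / sqrt(sum((B %*% .check_hkl(hkl))^2))
  }
}

#' Unit normal of a lattice plane
#'
#' Direction of the reciprocal-lattice vector \eqn{h a^* + k b^* + l c^*},
#' which is perpendicular to the (h k l) plane.
#'
#' @param cell a \code{unit_cell}.
#' @param hkl integer 3-vector.
#' @return Cartesian unit 3-vector.
#' @export
plane_unit_normal <- function(cell, hkl) {
  g <- reciprocal_basis(cell) %*% .check_hkl(hkl)
  as.numeric(g / sqrt(sum(g^2)))
}

#' Crystallographic density
#'
#' \eqn{\rho = Z M / (N_A V)} with V in cubic Angstrom converted to
#' \eqn{\mathrm{cm}^3}.
#'
#' @param cell a \code{unit_cell}.
#' @param z formula units per cell (integer, >= 1).
#' @param molar_mass molar mass of one formula unit, g/mol.
#' @return density in g/cm^3.
#' @examples
#' rep_cell <- unit_cell(19.40, 9.78, 17.05, beta = 106.44)
#' crystal_density(rep_cell, z = 4, molar_mass = 772.44)  # ~1.65
#' @export
crystal_density <- function(cell, z, molar_mass) {
  if (z < 1 || z != round(z)) stop("z must be a positive integer")
  if (molar_mass <= 0) stop("molar_mass must be positive")
  z * molar_mass / (.avogadro * cell_volume(cell) * 1e-24)
}

#' Molar mass of a composition given as element counts
#'
#' @param counts named integer vector, e.g. \code{c(Ca = 1, C = 18, ...)}.
#' @return molar mass in g/mol.
#' @export
formula_mass <- function(counts) {
  sum(atomic_mass(names(counts)) * counts)
}

#' Classify a metal--ligand contact as ionic or covalent/coordinate
#'
#' Applies the radius-sum rule: a contact longer than the sum of the two
#' ionic radii is classified as ionic; at or below the sum it is treated as
#' covalent/coordinate. The boundary itself (distance equal to the radius
#' sum) is not "above" the sum and therefore falls on the covalent side.
#'
#' @param distance contact distance, Angstrom (> 0).
#' @param radius_1,radius_2 ionic radii of the two atoms, Angstrom.
#' @return character vector, \code{"ionic"} or \code{"covalent/coordinate"}.
#' @examples
#' classify_contact(2.35, 1.21, 1.00)  # "ionic" (Ca--O beyond 2.21)
#' @export
classify_contact <- function(distance, radius_1, radius_2) {
  if (any(distance <= 0)) stop("contact distance must be positive")
  if (any(c(radius_1, radius_2) <= 0)) stop("radii must be positive")
  ifelse(distance > radius_1 + radius_2, "ionic", "covalent/coordinate")
}

.laue_classes <- c("-1", "2/m", "mmm", "4/mmm", "m-3m")

#' Laue class from a space-group symbol
#'
#' Maps a Hermann-Mauguin space-group symbol to the Laue class (point group
#' plus inversion) used for form expansion. Coverage is limited to the
#' crystal systems the habit machinery supports: triclinic, monoclinic,
#' orthorhombic, tetragonal (4/mmm type) and cubic (m-3m type).
#'
#' @param symbol space-group symbol, e.g. \code{"C2/c"} or \code{"P 21/c"}.
#' @return one of \code{"-1"}, \code{"2/m"}, \code{"mmm"}, \code{"4/mmm"},
#'   \code{"m-3m"}.
#' @export
laue_from_spacegroup <- function(symbol) {
  s <- gsub("[ _]", "", symbol)
  # strip the lattice centering letter
  body <- sub("^[PABCIFR]", "", s, ignore.case = FALSE)
  if (body == "" ) stop("cannot parse space-group symbol: ", symbol)
  if (grepl("^-?1$", body)) return("-1")
  # a 3 beyond the first position marks a cubic group (m-3m, 23, Fd-3m, -43m)
  if (grepl("3", substr(body, 2, nchar(body)))) return("m-3m")
  if (grepl("^-?4", body)) return("4/mmm")
  if (grepl("^-?3", body)) stop("trigonal/hexagonal Laue classes are not supported")
  # monoclinic: a single-position symbol built from 2, m, c-like glides
  if (grepl("^(2|21|m|[abcden])(/([mabcden]|21|2))?$", body)) return("2/m")
  # orthorhombic: three positions of 2/21/m/glides
  if (grepl("^([2m]|21|[abcden]){3}$", gsub("/", "", body))) return("mmm")
  stop("unsupported space-group symbol for Laue-class derivation: ", symbol)
}
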