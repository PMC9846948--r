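# Non-bonded energy evaluation (12-6 Lennard-Jones + point-charge Coulomb)
# and the attachment-energy algebra:
#   E_att  = E_latt - E_slice
#   E_int  = E_tot - (E_cry + E_sol)
#   E_att' = E_att - E_int

#' Force-field parameters for the non-bonded evaluator
#'
#' Per-element 12-6 Lennard-Jones well depths and sizes plus the evaluation
#' settings. The van der Waals sum is atom-based with a plain distance
#' cutoff (default 15.5 Angstrom); electrostatics are either a direct sum
#' over all pairs (finite clusters) or a minimum-image cutoff sum (periodic
#' systems).
#'
#' @param elements data.frame with columns \code{element}, \code{epsilon}
#'   (kcal/mol, >= 0) and \code{sigma} (Angstrom, > 0).
#' @param mixing combination rule for unlike pairs: \code{"geometric"}
#'   (both epsilon and sigma geometric means, the Dreiding convention) or
#'   \code{"lorentz-berthelot"}.
#' @param vdw_cutoff Lennard-Jones cutoff, Angstrom.
#' @param coulomb_method \code{"direct_sum"} or \code{"minimum_image_cutoff"};
#'   \code{NULL} picks by periodicity at evaluation time.
#' @param coulomb_constant prefactor in kcal Angstrom / (mol e^2).
#' @return object of class \code{ff_params}.
#' @export
ff_params <- function(elements, mixing = c("geometric", "lorentz-berthelot"),
                      vdw_cutoff = 15.5, coulomb_method = NULL,
                      coulomb_constant = .coulomb_kcal) {
  mixing <- match.arg(mixing)
  stopifnot(all(c("element", "epsilon", "sigma") %in% names(elements)))
  if (any(elements$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(elements$sigma <= 0)) stop("sigma must be > 0")
  if (vdw_cutoff <= 0) stop("cutoff must be positive")
  if (!is.null(coulomb_method)) {
    coulomb_method <- match.arg(coulomb_method,
                                c("direct_sum", "minimum_image_cutoff"))
  }
  structure(list(elements = elements, mixing = mixing,
                 vdw_cutoff = vdw_cutoff, coulomb_method = coulomb_method,
                 coulomb_constant = coulomb_constant),
            class = "ff_params")
}

# all i<j index pairs
#' @keywords internal
.pair_indices <- function(n) {
  if (n < 2) return(list(i = integer(0), j = integer(0)))
  list(i = rep.int(seq_len(n - 1L), rev(seq_len(n - 1L))),
       j = sequence(rev(seq_len(n - 1L)), from = 2:n))
}

#' Non-bonded energy of a molecular system
#'
#' Pairwise sum of 12-6 Lennard-Jones,
#' \eqn{4\epsilon_{ij}[(\sigma_{ij}/r)^{12}-(\sigma_{ij}/r)^6]}, over pairs
#' within the cutoff, plus point-charge Coulomb
#' \eqn{k q_i q_j / r}. For periodic systems distances use the minimum-image
#' convention in the periodic directions (the cutoff must not exceed half
#' the smallest periodic box extent). Intramolecular pairs (same
#' \code{molecule_id}) are excluded by default: molecules are treated rigid
#' and carry no internal terms.
#'
#' @param system a \code{molecular_system}.
#' @param params a \code{ff_params} covering every element present.
#' @param exclude_intramolecular drop pairs within one molecule (default TRUE).
#' @return energy in kcal/mol (scalar).
#' @export
nonbonded_energy <- function(system, params, exclude_intramolecular = TRUE) {
  stopifnot(inherits(system, "molecular_system"), inherits(params, "ff_params"))
  at <- system$atoms
  n <- nrow(at)
  if (n < 2) return(0)
  missing_el <- setdiff(unique(at$element), params$elements$element)
  if (length(missing_el)) {
    stop("no force-field parameters for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  pos <- as.matrix(at[, c("x", "y", "z")])
  pr <- .pair_indices(n)
  i <- pr$i; j <- pr$j
  if (exclude_intramolecular) {
    keep <- at$molecule_id[i] != at$molecule_id[j]
    i <- i[keep]; j <- j[keep]
    if (length(i) == 0) return(0)
  }
  d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]

  periodic <- !is.null(system$box) && any(system$pbc)
  if (periodic) {
    box <- system$box
    # minimum-image validity
    per <- which(system$pbc)
    h <- .box_heights(box)[per]
    if (params$vdw_cutoff > min(h) / 2 + 1e-9) {
      stop(sprintf(
        "cutoff %.3g exceeds half the smallest periodic box height (%.3g): minimum-image violation",
        params$vdw_cutoff, min(h)))
    }
    frac <- d %*% solve(box)
    for (k in per) frac[, k] <- frac[, k] - round(frac[, k])
    d <- frac %*% box
  }
  r2 <- rowSums(d * d)
  if (any(r2 < 1e-12)) stop("overlapping atoms (distance < 1e-6 Angstrom)")
  r <- sqrt(r2)

  idx <- match(at$element, params$elements$element)
  eps <- params$elements$epsilon[idx]
  sig <- params$elements$sigma[idx]
  if (params$mixing == "geometric") {
    eij <- sqrt(eps[i] * eps[j]); sij <- sqrt(sig[i] * sig[j])
  } else {
    eij <- sqrt(eps[i] * eps[j]); sij <- (sig[i] + sig[j]) / 2
  }
  within <- r <= params$vdw_cutoff
  sr6 <- (sij[within] / r[within])^6
  e_lj <- sum(4 * eij[within] * (sr6 * sr6 - sr6))

  method <- params$coulomb_method
  if (is.null(method)) method <- if (periodic) "minimum_image_cutoff" else "direct_sum"
  q <- at$charge
  qq <- q[i] * q[j]
  e_coul <- if (method == "direct_sum") {
    sum(params$coulomb_constant * qq / r)
  } else {
    sum(params$coulomb_constant * qq[within] / r[within])
  }
  e_lj + e_coul
}

# perpendicular heights of a (possibly triclinic) box
#' @keywords internal
.box_heights <- function(box) {
  v <- abs(det(box))
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  c(v / sqrt(sum(cross(box[2, ], box[3, ])^2)),
    v / sqrt(sum(cross(box[3, ], box[1, ])^2)),
    v / sqrt(sum(cross(box[1, ], box[2, ])^2)))
}

#' Energy breakdown container
#' @keywords internal
energy_breakdown <- function(...) {
  structure(list(...), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  for (nm in names(x)) {
    if (is.numeric(x[[nm]])) cat(sprintf("%-12s %12.6f kcal/mol\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Crystal--solvent interaction energy of an interface model
#'
#' Evaluates the full crystal + solvent system, the crystal subset alone and
#' the solvent (organic + water) subset alone under identical settings and
#' returns the adhesion energy
#' \eqn{E_{int} = E_{tot} - (E_{cry} + E_{sol})}. A negative value means the
#' crystal face and the solvent layer attract (spontaneous adsorption).
#'
#' @param interface a \code{molecular_system} whose atoms carry roles
#'   \code{"crystal"} and \code{"organic"}/\code{"water"}.
#' @param params a \code{ff_params}.
#' @param exclude_intramolecular passed through.
#' @return an \code{energy_breakdown} with \code{e_tot}, \code{e_cry},
#'   \code{e_sol}, \code{e_int}.
#' @export
interaction_energy <- function(interface, params, exclude_intramolecular = TRUE) {
  roles <- unique(interface$atoms$role)
  if (!"crystal" %in% roles) stop("interface has no atoms with role 'crystal'")
  if (!any(c("organic", "water") %in% roles)) {
    stop("interface has no solvent atoms (role 'organic' or 'water')")
  }
  e_tot <- nonbonded_energy(interface, params, exclude_intramolecular)
  e_cry <- nonbonded_energy(subset_roles(interface, "crystal"), params,
                            exclude_intramolecular)
  e_sol <- nonbonded_energy(subset_roles(interface, c("organic", "water")),
                            params, exclude_intramolecular)
  energy_breakdown(e_tot = e_tot, e_cry = e_cry, e_sol = e_sol,
                   e_int = e_tot - (e_cry + e_sol))
}

#' Solvent-modified attachment energy
#'
#' \eqn{E'_{att} = E_{att} - s\,E_{int}} where \eqn{s} rescales a box-level
#' interaction energy to the per-cell reference of the attachment energy
#' (default 1: energies already on a common footing, e.g.
#' \eqn{s = A_{cell}/A_{box}} computed by the caller). Since adsorption makes
#' \eqn{E_{int} < 0} while \eqn{E_{att} < 0}, subtracting it shrinks
#' \eqn{|E'_{att}|}: the solvent slows face growth.
#'
#' @param e_att attachment energy, kcal/mol (<= 0 by convention).
#' @param e_int crystal--solvent interaction energy, kcal/mol.
#' @param area_scale dimensionless rescaling of \code{e_int} (default 1).
#' @return modified attachment energy, kcal/mol.
#' @export
modified_attachment_energy <- function(e_att, e_int, area_scale = 1) {
  if (any(e_att > 0)) stop("attachment energies are expected to be <= 0")
  e_att - area_scale * e_int
}

#' Attachment energy of a toy periodic crystal
#'
#' Computes, for a toy crystal, the per-cell lattice energy (fully periodic,
#' minimum image), the per-cell energy of an isolated slice of thickness
#' \eqn{d_{hkl}} (periodic in-plane only), and their difference
#' \eqn{E_{att} = E_{latt} - E_{slice}} -- the energy released when a growth
#' slice attaches onto the face. The toy path supports faces whose normal is
#' aligned with a Cartesian axis of the supercell (e.g. (1 0 0) or (0 0 1)
#' of an orthogonal cell).
#'
#' @param crystal a \code{toy_crystal} (see \code{\link{toy_crystal}}).
#' @param hkl Miller index of the face.
#' @param params a \code{ff_params}.
#' @param slice_thickness slice depth; defaults to \eqn{d_{hkl}}.
#' @return an \code{energy_breakdown} with \code{e_latt}, \code{e_slice},
#'   \code{e_att} (all per unit cell).
#' @export
attachment_energy_toy <- function(crystal, hkl, params, slice_thickness = NULL) {
  stopifnot(inherits(crystal, "toy_crystal"))
  cell <- crystal$cell
  hkl <- .check_hkl(hkl)
  if (is.null(slice_thickness)) slice_thickness <- d_spacing(cell, hkl)
  n <- plane_unit_normal(cell, hkl)
  axis <- which(abs(abs(n) - 1) < 1e-8)
  if (length(axis) != 1) {
    stop("toy attachment energies need a face normal aligned with a box axis")
  }
  sys <- crystal$system
  n_cells <- prod(crystal$repeats)
  e_latt <- nonbonded_energy(sys, params) / n_cells

  coord <- sys$atoms[[c("x", "y", "z")[axis]]]
  sel <- coord < min(coord) + slice_thickness - 1e-9 * slice_thickness
  if (!any(sel)) stop("slice selects no atoms")
  slice_atoms <- sys$atoms[sel, , drop = FALSE]
  pbc <- c(TRUE, TRUE, TRUE); pbc[axis] <- FALSE
  slice_sys <- molecular_system(slice_atoms, box = sys$box, pbc = pbc)
  # per-cell normalization: cells contained in the slice
  atoms_per_cell <- nrow(sys$atoms) / n_cells
  n_slice_cells <- nrow(slice_atoms) / atoms_per_cell
  e_slice <- nonbonded_energy(slice_sys, params) / n_slice_cells
  energy_breakdown(e_latt = e_latt, e_slice = e_slice,
                   e_att = e_latt - e_slice)
}
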