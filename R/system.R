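# MolecularSystem container shared by the energetics, interface-builder and
# density-profile stages, plus the rigid molecule templates.

#' Construct a molecular system
#'
#' A flat atom table (element, mass, partial charge, Cartesian position,
#' molecule id, role) with an optional periodic box. Roles distinguish the
#' crystal slab from the solvent (\code{"organic"} + \code{"water"}) in
#' interface models.
#'
#' @param atoms data.frame with columns \code{element}, \code{mass} (amu),
#'   \code{charge} (e), \code{x}, \code{y}, \code{z} (Angstrom); optional
#'   \code{molecule_id} (integer) and \code{role} (character). Missing
#'   molecule ids default to one molecule per atom; missing roles to
#'   \code{"crystal"}.
#' @param box optional 3x3 matrix whose rows are the periodic cell vectors,
#'   or a length-3 vector for an orthorhombic box.
#' @param pbc logical 3-vector: which box directions are periodic.
#' @param tags free-text annotation.
#' @return object of class \code{molecular_system}.
#' @export
molecular_system <- function(atoms, box = NULL, pbc = c(TRUE, TRUE, TRUE),
                             tags = NULL) {
  req <- c("element", "mass", "charge", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (is.null(atoms$molecule_id)) atoms$molecule_id <- seq_len(nrow(atoms))
  if (is.null(atoms$role)) atoms$role <- "crystal"
  if (!is.null(box)) {
    if (!is.matrix(box)) box <- diag(as.numeric(box), 3)
    stopifnot(all(dim(box) == c(3, 3)))
    if (abs(det(box)) <= 0) stop("periodic box must have positive volume")
  }
  structure(list(atoms = atoms, box = box, pbc = pbc, tags = tags),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular system:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$molecule_id)), "molecules\n")
  cat("roles:", paste(sprintf("%s=%d", names(table(x$atoms$role)),
                              table(x$atoms$role)), collapse = " "), "\n")
  if (!is.null(x$box)) {
    cat(sprintf("box: %.2f x %.2f x %.2f (pbc %s)\n",
                x$box[1, 1], x$box[2, 2], x$box[3, 3],
                paste(ifelse(x$pbc, "T", "F"), collapse = "")))
  }
  invisible(x)
}

#' Subset a molecular system by role
#'
#' @param system a \code{molecular_system}.
#' @param roles character vector of roles to keep.
#' @return a \code{molecular_system} with the same box.
#' @export
subset_roles <- function(system, roles) {
  keep <- system$atoms$role %in% roles
  if (!any(keep)) stop("no atoms with role(s): ", paste(roles, collapse = ", "))
  molecular_system(system$atoms[keep, , drop = FALSE], box = system$box,
                   pbc = system$pbc, tags = system$tags)
}

#' Rigid molecule templates
#'
#' Small bundled coordinate templates used by the packing and synthetic
#' builders. \code{"water"} is a rigid 3-site model (O-H 0.957 Angstrom,
#' H-O-H 104.5 degrees) carrying the partial charges q(O) = -0.72 e,
#' q(H) = +0.36 e. \code{"mecn"} is a 3-site united-atom acetonitrile
#' (CH3-C-N) and \code{"lj"} a single neutral site of argon mass.
#'
#' @param name template name: \code{"water"}, \code{"mecn"} or \code{"lj"}.
#' @return data.frame of template atoms centered on their centroid.
#' @export
molecule_template <- function(name = c("water", "mecn", "lj")) {
  name <- match.arg(name)
  tpl <- switch(name,
    water = {
      ang <- 104.5 * pi / 180
      d <- 0.957
      data.frame(
        element = c("O", "H", "H"),
        mass = atomic_mass(c("O", "H", "H")),
        charge = c(-0.72, 0.36, 0.36),
        x = c(0, d * sin(ang / 2), -d * sin(ang / 2)),
        y = c(0, d * cos(ang / 2), d * cos(ang / 2)),
        z = c(0, 0, 0))
    },
    mecn = data.frame(   # CH3 - C - N united-atom chain along x
      element = c("C", "C", "N"),
      mass = c(15.035, 12.011, 14.007),
      charge = c(0.15, 0.28, -0.43),
      x = c(0, 1.46, 2.62), y = 0, z = 0),
    lj = data.frame(element = "Ar", mass = atomic_mass("Ar"), charge = 0,
                    x = 0, y = 0, z = 0)
  )
  ctr <- colMeans(tpl[, c("x", "y", "z")])
  tpl$x <- tpl$x - ctr[1]; tpl$y <- tpl$y - ctr[2]; tpl$z <- tpl$z - ctr[3]
  tpl
}

#' Molar mass of a template molecule
#' @param template data.frame as returned by \code{\link{molecule_template}}.
#' @return g/mol.
#' @export
template_molar_mass <- function(template) sum(template$mass)
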