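# Seeded synthetic generators: toy periodic crystals, layered interface
# trajectories with known density peaks, side-ratio tables with planted
# slopes, and adsorption fixtures with controlled separation. Every
# generator records its ground truth so downstream analyses can be checked
# round-trip.

#' Build a toy periodic crystal
#'
#' Desk-scale periodic structures for exercising the lattice-energy and
#' slab machinery: a single Lennard-Jones atom per cell (\code{"lj"} basis)
#' or a two-site charged basis with opposite unit charges at (0,0,0) and
#' (1/2,1/2,1/2) (\code{"ionic"} basis, net cell charge zero). Cubic or
#' b-unique monoclinic lattices are supported; the supercell box follows
#' the cell vectors exactly.
#'
#' @param lattice \code{"cubic"} or \code{"monoclinic"}.
#' @param a,b,c,beta lattice parameters (Angstrom / degrees); for cubic
#'   lattices b and c default to a.
#' @param basis \code{"lj"} or \code{"ionic"}.
#' @param repeats integer 3-vector: supercell repeats along a, b, c.
#' @param vacuum extra empty box height added along z, Angstrom.
#' @param element element symbol for the LJ basis atom.
#' @return object of class \code{toy_crystal}: \code{system}
#'   (\code{molecular_system}, fully periodic), \code{cell}
#'   (\code{unit_cell}), \code{repeats}, \code{vacuum}.
#' @examples
#' xt <- toy_crystal("cubic", a = 5, repeats = c(3, 3, 3))
#' nrow(xt$system$atoms)  # 27
#' @export
toy_crystal <- function(lattice = c("cubic", "monoclinic"), a = 5, b = NULL,
                        c = NULL, beta = 90, basis = c("lj", "ionic"),
                        repeats = c(3, 3, 3), vacuum = 0, element = "Ar") {
  lattice <- match.arg(lattice)
  basis <- match.arg(basis)
  if (lattice == "cubic") { b <- a; c <- a; beta <- 90 }
  if (is.null(b)) b <- a
  if (is.null(c)) c <- a
  cell <- unit_cell(a, b, c, beta = beta,
                    space_group = if (lattice == "cubic") "Pm-3m" else "P2/m")
  A <- cell_basis(cell)    # columns a, b, c
  frac_basis <- switch(basis,
    lj = matrix(c(0, 0, 0), 1, 3),
    ionic = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)))
  site <- switch(basis,
    lj = data.frame(element = element, mass = atomic_mass(element), charge = 0),
    ionic = data.frame(element = c("A", "B2"),
                       mass = atomic_mass(c("A", "B2")),
                       charge = c(1, -1)))
  reps <- as.integer(repeats)
  grid <- expand.grid(i = 0:(reps[1] - 1), j = 0:(reps[2] - 1), k = 0:(reps[3] - 1))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    frac <- sweep(frac_basis, 2, as.numeric(grid[g, ]), "+")
    xyz <- frac %*% t(A)
    rows[[g]] <- data.frame(element = site$element, mass = site$mass,
                            charge = site$charge,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            molecule_id = NA_integer_, role = "crystal")
  }
  at <- do.call(rbind, rows)
  at$molecule_id <- seq_len(nrow(at))    # atomic crystal: one atom per molecule
  box <- t(A %*% diag(reps))             # rows are supercell vectors
  if (vacuum > 0) {
    nrm <- box[3, ] / sqrt(sum(box[3, ]^2))
    box[3, ] <- box[3, ] + vacuum * nrm
  }
  sys <- molecular_system(at, box = box, pbc = c(TRUE, TRUE, TRUE))
  structure(list(system = sys, cell = cell, repeats = reps, vacuum = vacuum),
            class = "toy_crystal")
}

#' Generate layered interface trajectory frames
#'
#' Emulates an equilibrated interface trajectory: each layer places atoms
#' with Gaussian-distributed z about a prescribed center and uniform
#' in-plane positions; frames add seeded Gaussian jitter to the base
#' configuration (zero jitter gives identical frames). The generating
#' parameters and the realized per-layer statistics are stored as metadata
#' ground truth.
#'
#' @param layers data.frame with columns \code{center} (Angstrom),
#'   \code{width} (Gaussian sigma, Angstrom, > 0), \code{role},
#'   \code{mass} (amu per atom), \code{n_atoms}.
#' @param n_frames number of frames.
#' @param lx,ly in-plane box edges, Angstrom.
#' @param box_height box height, Angstrom; default covers the layers.
#' @param noise per-frame z jitter sigma, Angstrom.
#' @param frame_interval ps between frames.
#' @param seed RNG seed.
#' @return a \code{frame_set} whose \code{metadata} attribute records the
#'   layer table and realized base-z per layer.
#' @export
layered_frames <- function(layers, n_frames = 20, lx = 30, ly = 30,
                           box_height = NULL, noise = 0, frame_interval = 0.5,
                           seed = 1) {
  stopifnot(all(c("center", "width", "role", "mass", "n_atoms") %in% names(layers)))
  if (any(layers$width <= 0)) stop("layer widths must be positive")
  set.seed(as.integer(seed))
  if (is.null(box_height)) box_height <- max(layers$center + 6 * layers$width)
  base <- vector("list", nrow(layers))
  rows <- vector("list", nrow(layers))
  mol0 <- 0
  for (i in seq_len(nrow(layers))) {
    n <- layers$n_atoms[i]
    z <- stats::rnorm(n, layers$center[i], layers$width[i])
    base[[i]] <- z
    rows[[i]] <- data.frame(element = "X", mass = layers$mass[i],
                            charge = 0,
                            x = stats::runif(n, 0, lx),
                            y = stats::runif(n, 0, ly), z = z,
                            molecule_id = mol0 + seq_len(n),
                            role = layers$role[i])
    mol0 <- mol0 + n
  }
  at0 <- do.call(rbind, rows)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    at <- at0
    if (noise > 0) at$z <- at$z + stats::rnorm(nrow(at), 0, noise)
    frames[[f]] <- molecular_system(at, box = diag(c(lx, ly, box_height)),
                                    pbc = c(TRUE, TRUE, FALSE))
  }
  fs <- frame_set(frames, frame_interval = frame_interval,
                  window = c(1, n_frames))
  attr(fs, "metadata") <- list(
    layers = layers, seed = as.integer(seed), noise = noise,
    base_z = base,
    overlap_fraction = function(role, edge) {
      sel <- which(layers$role == role)
      zz <- unlist(base[sel])
      ww <- rep(layers$mass[sel], layers$n_atoms[sel])
      sum(ww * (zz < edge)) / sum(ww)
    })
  fs
}

#' Generate side-ratio tables with planted linear trends
#'
#' One series per solvent: \code{ratio = intercept + slope * volume} plus
#' i.i.d. Gaussian noise. The planted coefficients are stored as the
#' ground-truth attribute.
#'
#' @param slopes named numeric vector of slopes (per microliter).
#' @param intercepts single value or named vector of intercepts.
#' @param sigma noise standard deviation (0 for exact lines).
#' @param volumes organic-solvent volumes, microliter.
#' @param seed RNG seed.
#' @return named list of data.frames (\code{volume}, \code{side_ratio});
#'   attribute \code{"truth"} holds the planted slopes/intercepts.
#' @export
sideratio_table <- function(slopes, intercepts = 0.1, sigma = 0,
                            volumes = seq(50, 250, by = 50), seed = 1) {
  if (length(unique(volumes)) < 2) stop("volumes are degenerate")
  if (is.null(names(slopes))) stop("slopes must be named by solvent")
  if (length(intercepts) == 1) {
    intercepts <- stats::setNames(rep(intercepts, length(slopes)), names(slopes))
  }
  set.seed(as.integer(seed))
  out <- lapply(names(slopes), function(nm) {
    r <- intercepts[[nm]] + slopes[[nm]] * volumes
    if (sigma > 0) r <- r + stats::rnorm(length(volumes), 0, sigma)
    data.frame(volume = volumes, side_ratio = r)
  })
  names(out) <- names(slopes)
  attr(out, "truth") <- list(slopes = slopes, intercepts = intercepts,
                             sigma = sigma, seed = as.integer(seed))
  out
}

#' Build a slab + adsorbate fixture with controlled separation
#'
#' A rectangular crystal slab of Lennard-Jones atoms (role \code{"crystal"})
#' with a layer of adsorbate atoms (role \code{"water"}) placed a prescribed
#' distance above the top crystal layer. With the separation beyond the
#' van der Waals cutoff the crystal--solvent interaction energy is exactly
#' zero; at contact distances it is negative.
#'
#' @param nx,ny in-plane atoms per layer; \code{layers} stacked along z.
#' @param spacing lattice spacing of the slab, Angstrom.
#' @param layers number of crystal layers.
#' @param adsorbate_count number of adsorbate atoms (0 allowed).
#' @param separation gap between the top crystal layer and the adsorbate
#'   plane, Angstrom (>= 0).
#' @param element,ads_element element symbols for slab and adsorbate.
#' @param seed RNG seed for the in-plane adsorbate positions.
#' @return a \code{molecular_system} (non-periodic) with roles set.
#' @export
adsorption_config <- function(nx = 5, ny = 5, spacing = 3.5, layers = 2,
                              adsorbate_count = 5, separation = 3.8,
                              element = "Ar", ads_element = "Ar", seed = 1) {
  if (separation < 0) stop("separation must be >= 0")
  set.seed(as.integer(seed))
  g <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(layers - 1))
  slab <- data.frame(element = element, mass = atomic_mass(element), charge = 0,
                     x = g$i * spacing, y = g$j * spacing,
                     z = -g$k * spacing, role = "crystal")
  ztop <- 0
  ads <- if (adsorbate_count > 0) {
    if (adsorbate_count > nx * ny) stop("too many adsorbates for the slab grid")
    # jittered grid keeps adsorbates from overlapping each other
    k <- seq_len(adsorbate_count) - 1L
    data.frame(element = ads_element, mass = atomic_mass(ads_element),
               charge = 0,
               x = (k %% nx) * spacing +
                 stats::runif(adsorbate_count, -0.25, 0.25) * spacing,
               y = (k %/% nx) * spacing +
                 stats::runif(adsorbate_count, -0.25, 0.25) * spacing,
               z = ztop + separation, role = "water")
  } else NULL
  at <- rbind(slab, ads)
  at$molecule_id <- seq_len(nrow(at))
  molecular_system(at, box = NULL, tags = sprintf("adsorption fixture, sep=%.3g", separation))
}
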