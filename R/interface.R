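# Layered crystal/organic/water/vacuum interface models and
# solvent-accessible surface measures.

#' Pack a solvent box at a target density
#'
#' Random sequential insertion of rigid molecule copies into a rectangular
#' box whose thickness is fixed by the target density:
#' \eqn{t = n M / (N_A \rho A)} (with A the cross-section). Each inserted
#' copy gets a uniform random position and orientation; a trial is rejected
#' if any of its atoms falls closer than \code{min_dist} to an already
#' placed atom. The construction is geometric, not an equilibrated liquid.
#'
#' @param template molecule template (data.frame) or a name accepted by
#'   \code{\link{molecule_template}}.
#' @param count number of molecules (>= 1).
#' @param target_density g/cm^3.
#' @param cross_section box cross-sectional area, Angstrom^2. The box is
#'   square in-plane unless \code{lx} is given.
#' @param seed integer RNG seed; identical seeds give identical coordinates.
#' @param role role label for the packed atoms (default \code{"water"} for
#'   the water template, else \code{"organic"}).
#' @param min_dist minimum intermolecular atom-atom distance, Angstrom.
#' @param z_margin clearance kept between atoms and the box z faces.
#' @param lx optional in-plane box edge (ly = cross_section / lx).
#' @param max_attempts insertion attempts per molecule before giving up.
#' @return a \code{molecular_system} with an orthorhombic box; the box
#'   z-height is the density-determined thickness.
#' @examples
#' w <- pack_solvent_box("water", count = 50, target_density = 1.0,
#'                       cross_section = 400, seed = 1)
#' @export
pack_solvent_box <- function(template, count, target_density, cross_section,
                             seed, role = NULL, min_dist = 1.5,
                             z_margin = 0.75, lx = NULL, max_attempts = 2000) {
  if (is.character(template)) {
    if (is.null(role)) role <- if (template == "water") "water" else "organic"
    template <- molecule_template(template)
  }
  if (is.null(role)) role <- "organic"
  if (count < 1 || count != round(count)) stop("count must be a positive integer")
  if (target_density <= 0) stop("target density must be positive")
  M <- template_molar_mass(template)
  thickness <- count * M * .amu_g * 1e24 / (target_density * cross_section)
  if (is.null(lx)) lx <- sqrt(cross_section)
  ly <- cross_section / lx
  if (thickness <= 2 * z_margin && nrow(template) > 0) {
    stop("box too thin for the requested margin; lower the density or count")
  }
  # crude packing-fraction sanity bound
  vol_per_mol <- lx * ly * thickness / count
  if (vol_per_mol < nrow(template) * (4 / 3) * pi * 0.5^3) {
    stop("requested density is not achievable for this template")
  }

  set.seed(as.integer(seed))
  tpl <- as.matrix(template[, c("x", "y", "z")])
  placed <- matrix(0, 0, 3)
  rows <- vector("list", count)
  for (m in seq_len(count)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      R <- .random_rotation()
      ctr <- c(stats::runif(1, 0, lx), stats::runif(1, 0, ly),
               stats::runif(1, z_margin, thickness - z_margin))
      xyz <- tpl %*% t(R)
      xyz <- sweep(xyz, 2, ctr, "+")
      # keep whole molecule inside z slab; wrap in-plane
      if (min(xyz[, 3]) < z_margin || max(xyz[, 3]) > thickness - z_margin) next
      xyz[, 1] <- xyz[, 1] %% lx
      xyz[, 2] <- xyz[, 2] %% ly
      if (nrow(placed) > 0) {
        dmin <- min(.min_image_dist2(xyz, placed, lx, ly))
        if (dmin < min_dist^2) next
      }
      placed <- rbind(placed, xyz)
      rows[[m]] <- data.frame(element = template$element, mass = template$mass,
                              charge = template$charge,
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              molecule_id = m, role = role)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("failed to insert molecule ", m, " after ", max_attempts,
           " attempts; lower the density or min_dist")
    }
  }
  molecular_system(do.call(rbind, rows),
                   box = diag(c(lx, ly, thickness)),
                   pbc = c(TRUE, TRUE, FALSE),
                   tags = sprintf("packed %d x %s, rho=%.4g g/cm3, seed=%d",
                                  count, role, target_density, as.integer(seed)))
}

# squared minimum-image (in-plane periodic) distances between two point sets
#' @keywords internal
.min_image_dist2 <- function(a, b, lx, ly) {
  dx <- outer(a[, 1], b[, 1], "-"); dx <- dx - lx * round(dx / lx)
  dy <- outer(a[, 2], b[, 2], "-"); dy <- dy - ly * round(dy / ly)
  dz <- outer(a[, 3], b[, 3], "-")
  dx^2 + dy^2 + dz^2
}

# uniform random rotation matrix (quaternion method)
#' @keywords internal
.random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Cut a slab from a toy crystal
#'
#' Keeps the molecules whose centroid lies within \code{depth} of the bottom
#' of the crystal along +z (whole molecules are kept so no intramolecular
#' contact is severed). The surface normal is +z and the slab bottom sits at
#' z = 0; \code{surface_edge_z} records the top of the crystal material.
#'
#' @param crystal a \code{toy_crystal} whose normal axis is z.
#' @param depth slab depth, Angstrom; default twice the (0 0 1) d-spacing.
#' @return object of class \code{slab}: the crystal subset (role
#'   \code{"crystal"}) plus bookkeeping (cell, repeats, cross-section,
#'   \code{surface_edge_z}).
#' @export
cleave_slab <- function(crystal, depth = NULL) {
  stopifnot(inherits(crystal, "toy_crystal"))
  if (is.null(depth)) depth <- 2 * d_spacing(crystal$cell, c(0, 0, 1))
  at <- crystal$system$atoms
  at$z <- at$z - min(at$z)
  cen <- tapply(at$z, at$molecule_id, mean)
  keep_mol <- names(cen)[cen <= depth]
  at <- at[as.character(at$molecule_id) %in% keep_mol, , drop = FALSE]
  at$role <- "crystal"
  box <- crystal$system$box
  lx <- box[1, 1]; ly <- box[2, 2]
  sys <- molecular_system(at, box = diag(c(lx, ly, max(at$z) + depth)),
                          pbc = c(TRUE, TRUE, FALSE))
  structure(list(system = sys, cell = crystal$cell, hkl = c(0, 0, 1),
                 depth = depth, u_repeat = crystal$repeats[1],
                 v_repeat = crystal$repeats[2],
                 lx = lx, ly = ly, cross_section = lx * ly,
                 surface_edge_z = max(at$z)),
            class = "slab")
}

#' Assemble a crystal/organic/water/vacuum interface model
#'
#' Stacks the layers along +z in the order slab, organic, water, vacuum.
#' Each solvent layer keeps its packed thickness, so at equal cross-section
#' the organic/water thickness ratio equals their volume ratio. Atom counts
#' are conserved and roles are preserved.
#'
#' @param slab a \code{slab} (or any \code{molecular_system} with role
#'   \code{"crystal"} and an orthorhombic box).
#' @param organic packed organic layer (\code{molecular_system}) or NULL for
#'   a water-only interface.
#' @param water packed water layer (\code{molecular_system}).
#' @param vacuum vacuum thickness added above the solvent, Angstrom
#'   (default 100, suppressing spurious periodic-image interactions).
#' @param tol cross-section matching tolerance, Angstrom.
#' @return object of class \code{interface_model}: composite
#'   \code{molecular_system} plus layer bounds.
#' @export
assemble_interface <- function(slab, organic = NULL, water, vacuum = 100,
                               tol = 1e-6) {
  sl_sys <- if (inherits(slab, "slab")) slab$system else slab
  lx <- sl_sys$box[1, 1]; ly <- sl_sys$box[2, 2]
  layers <- Filter(Negate(is.null), list(organic = organic, water = water))
  for (nm in names(layers)) {
    b <- layers[[nm]]$box
    if (abs(b[1, 1] - lx) > tol || abs(b[2, 2] - ly) > tol) {
      stop(sprintf("cross-section mismatch: %s layer is %.6f x %.6f, slab is %.6f x %.6f",
                   nm, b[1, 1], b[2, 2], lx, ly))
    }
  }
  sl_at <- sl_sys$atoms
  sl_at$z <- sl_at$z - min(sl_at$z)
  slab_depth <- if (inherits(slab, "slab")) slab$depth else max(sl_at$z)
  ztop <- max(max(sl_at$z), slab_depth)
  parts <- list(sl_at)
  bounds <- list(crystal = c(0, ztop))
  next_id <- max(sl_at$molecule_id)
  for (nm in names(layers)) {
    at <- layers[[nm]]$atoms
    th <- layers[[nm]]$box[3, 3]
    at$z <- at$z + ztop
    at$molecule_id <- at$molecule_id + next_id
    next_id <- max(at$molecule_id)
    parts[[length(parts) + 1]] <- at
    bounds[[nm]] <- c(ztop, ztop + th)
    ztop <- ztop + th
  }
  height <- ztop + vacuum
  comp <- molecular_system(do.call(rbind, parts),
                           box = diag(c(lx, ly, height)),
                           pbc = c(TRUE, TRUE, FALSE))
  structure(list(system = comp, layer_bounds = bounds, vacuum = vacuum,
                 height = height, lx = lx, ly = ly,
                 surface_edge_z = if (inherits(slab, "slab")) slab$surface_edge_z else max(sl_at$z)),
            class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  cat("interface model:", nrow(x$system$atoms), "atoms, height",
      sprintf("%.2f", x$height), "Angstrom (vacuum", x$vacuum, ")\n")
  for (nm in names(x$layer_bounds)) {
    b <- x$layer_bounds[[nm]]
    cat(sprintf("  %-8s z = %7.2f .. %7.2f\n", nm, b[1], b[2]))
  }
  invisible(x)
}

#' Solvent-accessible area ratio of a slab surface
#'
#' Measures surface roughness as \eqn{S = A_{acc}/A_{hkl}}: the area of the
#' upper envelope of the probe-inflated atom spheres (grid-marched over the
#' periodic cross-section, triangulated) divided by the planar face area.
#' A perfectly flat surface gives S near 1; cavities and protrusions raise
#' it, signalling more solvent adsorption sites.
#'
#' @param slab a \code{slab} or \code{molecular_system} with an orthorhombic
#'   box (periodic in-plane).
#' @param probe_radius probe sphere radius, Angstrom (default 1.0).
#' @param grid_resolution lateral grid spacing, Angstrom.
#' @param radii named per-element van der Waals radii; defaults to a bundled
#'   Bondi-style table.
#' @return list with \code{a_acc}, \code{a_hkl} (Angstrom^2) and
#'   \code{s_ratio}.
#' @export
solvent_accessible_ratio <- function(slab, probe_radius = 1.0,
                                     grid_resolution = 0.25, radii = NULL) {
  sys <- if (inherits(slab, "slab")) slab$system else slab
  at <- sys$atoms
  if (nrow(at) == 0) stop("empty slab")
  if (probe_radius < 0) stop("probe radius must be >= 0")
  if (is.null(radii)) radii <- .vdw_radii
  rr <- radii[at$element]
  if (anyNA(rr)) stop("no radius for element(s): ",
                      paste(unique(at$element[is.na(rr)]), collapse = ", "))
  R <- unname(rr) + probe_radius
  lx <- sys$box[1, 1]; ly <- sys$box[2, 2]
  nx <- max(4L, as.integer(round(lx / grid_resolution)))
  ny <- max(4L, as.integer(round(ly / grid_resolution)))
  dx <- lx / nx; dy <- ly / ny
  zfloor <- min(at$z)
  h <- matrix(zfloor, nx, ny)
  gx <- (seq_len(nx) - 1) * dx
  gy <- (seq_len(ny) - 1) * dy
  for (a in seq_len(nrow(at))) {
    Ra <- R[a]
    ix <- which(pmin(abs(gx - at$x[a] %% lx), lx - abs(gx - at$x[a] %% lx)) <= Ra)
    iy <- which(pmin(abs(gy - at$y[a] %% ly), ly - abs(gy - at$y[a] %% ly)) <= Ra)
    if (!length(ix) || !length(iy)) next
    ddx <- abs(gx[ix] - at$x[a] %% lx); ddx <- pmin(ddx, lx - ddx)
    ddy <- abs(gy[iy] - at$y[a] %% ly); ddy <- pmin(ddy, ly - ddy)
    d2 <- outer(ddx^2, ddy^2, "+")
    inside <- d2 <= Ra^2
    if (!any(inside)) next
    zc <- matrix(-Inf, length(ix), length(iy))
    zc[inside] <- at$z[a] + sqrt(Ra^2 - d2[inside])
    h[ix, iy] <- pmax(h[ix, iy], zc)
  }
  # triangulated area with periodic wrap
  hx1 <- h[c(2:nx, 1), , drop = FALSE]
  hy1 <- h[, c(2:ny, 1), drop = FALSE]
  hxy <- h[c(2:nx, 1), c(2:ny, 1), drop = FALSE]
  # triangle 1: (0,0,h), (dx,0,hx1), (0,dy,hy1); triangle 2: (dx,0,hx1),
  # (dx,dy,hxy), (0,dy,hy1)
  a1 <- 0.5 * sqrt((dy * (h - hx1))^2 + (dx * (h - hy1))^2 + (dx * dy)^2)
  a2 <- 0.5 * sqrt((dy * (hxy - hy1))^2 + (dx * (hxy - hx1))^2 + (dx * dy)^2)
  a_acc <- sum(a1) + sum(a2)
  a_hkl <- lx * ly
  list(a_acc = a_acc, a_hkl = a_hkl, s_ratio = a_acc / a_hkl)
}

#' Probe-accessible sphere area of a finite system
#'
#' Shrake--Rupley style accessible surface area: each atom sphere is
#' inflated by the probe radius and sampled with a deterministic Fibonacci
#' point set; points buried inside any other inflated sphere are discarded.
#' For an isolated atom this returns \eqn{4\pi(r+p)^2}.
#'
#' @param system a \code{molecular_system} (treated as non-periodic).
#' @param probe_radius probe radius, Angstrom.
#' @param n_points sample points per atom sphere.
#' @param radii named per-element radii (default bundled table).
#' @return accessible area, Angstrom^2.
#' @export
probe_accessible_area <- function(system, probe_radius = 1.0, n_points = 960,
                                  radii = NULL) {
  at <- system$atoms
  if (is.null(radii)) radii <- .vdw_radii
  R <- unname(radii[at$element]) + probe_radius
  if (anyNA(R)) stop("missing radius for some element")
  # Fibonacci sphere
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  pos <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(at)
  area <- 0
  for (a in seq_len(n)) {
    sp <- sweep(pts * R[a], 2, pos[a, ], "+")
    free <- rep(TRUE, n_points)
    for (b in seq_len(n)) {
      if (b == a) next
      d2 <- rowSums(sweep(sp, 2, pos[b, ])^2)
      free <- free & d2 > R[b]^2
      if (!any(free)) break
    }
    area <- area + 4 * pi * R[a]^2 * mean(free)
  }
  area
}

#' Default simulation protocol block
#'
#' The fixed NVT protocol emitted alongside interface models for external
#' molecular-dynamics engines: 298.15 K, Nose-Hoover-Langevin thermostat,
#' 15.5 Angstrom atom-based van der Waals cutoff, 500 ps at 1 fs with
#' configurations dumped every 500 steps, the first half discarded as
#' equilibration and the final quarter analyzed.
#'
#' @return named list of protocol values.
#' @export
md_protocol <- function() {
  list(temperature_K = 298.15, ensemble = "NVT", thermostat = "NHL",
       vdw_cutoff_A = 15.5, electrostatics = "Ewald",
       timestep_fs = 1, duration_ps = 500, dump_interval_steps = 500,
       equilibration_ps = 250, analysis_window_ps = 125,
       vacuum_A = 100, organic_water_volume_ratio = 1 / 3)
}
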