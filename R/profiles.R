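# Mass density profiles along the surface normal, peak finding and
# surface-overlap diagnostics.

#' Bundle trajectory frames for analysis
#'
#' @param frames list of \code{molecular_system} objects with identical atom
#'   rosters (same count, ordering, elements).
#' @param frame_interval time between stored frames, ps.
#' @param window analysis window as frame indices \code{c(start, end)};
#'   default the final quarter of the trajectory (production window after
#'   equilibration).
#' @return object of class \code{frame_set}.
#' @export
frame_set <- function(frames, frame_interval = 0.5, window = NULL) {
  if (length(frames) == 0) stop("no frames")
  n0 <- nrow(frames[[1]]$atoms)
  el0 <- frames[[1]]$atoms$element
  for (f in frames) {
    if (nrow(f$atoms) != n0 || !identical(f$atoms$element, el0)) {
      stop("all frames must share one atom roster (count and ordering)")
    }
  }
  nf <- length(frames)
  if (is.null(window)) window <- c(max(1L, floor(0.75 * nf) + 1L), nf)
  if (window[1] > window[2] || window[2] > nf) stop("empty or invalid analysis window")
  structure(list(frames = frames, frame_interval = frame_interval,
                 window = window),
            class = "frame_set")
}

#' Mass density profile along z
#'
#' Time-averaged histogram of atomic mass over z bins, one curve per role,
#' converted to g/cm^3 using the in-plane cross-section. Atoms are binned at
#' their centers (no smearing), so integrating the profile over z recovers
#' each role's total mass exactly.
#'
#' @param frames a \code{frame_set} (or single \code{molecular_system}).
#' @param bin_width bin width along z, Angstrom (default 0.5).
#' @param roles roles to profile; default all present.
#' @param cross_section in-plane area, Angstrom^2; default from the frame box.
#' @param zlim optional profile range \code{c(zmin, zmax)}; default spans
#'   the data (expanded to whole bins).
#' @return object of class \code{density_profile}: \code{bin_edges} (Angstrom),
#'   \code{density} matrix (bins x roles, g/cm^3), \code{cross_section}.
#' @export
mass_density_profile <- function(frames, bin_width = 0.5, roles = NULL,
                                 cross_section = NULL, zlim = NULL) {
  if (inherits(frames, "molecular_system")) frames <- frame_set(list(frames), window = c(1, 1))
  stopifnot(inherits(frames, "frame_set"))
  if (bin_width <= 0) stop("bin width must be positive")
  idx <- seq(frames$window[1], frames$window[2])
  use <- frames$frames[idx]
  if (is.null(cross_section)) {
    b <- use[[1]]$box
    if (is.null(b)) stop("no box on frames: supply cross_section")
    cross_section <- b[1, 1] * b[2, 2]
  }
  if (is.null(roles)) roles <- sort(unique(use[[1]]$atoms$role))
  allz <- unlist(lapply(use, function(f) f$atoms$z))
  if (is.null(zlim)) {
    zlim <- c(floor(min(allz) / bin_width) * bin_width,
              ceiling(max(allz) / bin_width + 1e-9) * bin_width)
  }
  edges <- seq(zlim[1], zlim[2], by = bin_width)
  if (utils::tail(edges, 1) < zlim[2] - 1e-9) edges <- c(edges, utils::tail(edges, 1) + bin_width)
  nb <- length(edges) - 1
  dens <- matrix(0, nb, length(roles), dimnames = list(NULL, roles))
  for (f in use) {
    at <- f$atoms
    for (r in roles) {
      sel <- at$role == r
      if (!any(sel)) next
      bin <- findInterval(at$z[sel], edges, rightmost.closed = TRUE)
      ok <- bin >= 1 & bin <= nb
      dens[, r] <- dens[, r] + tabulate_mass(bin[ok], at$mass[sel][ok], nb)
    }
  }
  dens <- dens / length(use)                       # mean mass per bin, amu
  dens <- dens * .amu_g * 1e24 / (cross_section * bin_width)   # -> g/cm^3
  structure(list(bin_edges = edges, density = dens,
                 cross_section = cross_section, bin_width = bin_width),
            class = "density_profile")
}

#' @keywords internal
tabulate_mass <- function(bin, mass, nbins) {
  out <- numeric(nbins)
  if (length(bin)) {
    agg <- tapply(mass, bin, sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density profile:", nrow(x$density), "bins of", x$bin_width,
      "Angstrom, roles:", paste(colnames(x$density), collapse = ", "), "\n")
  invisible(x)
}

#' Bin centers of a density profile
#' @param profile a \code{density_profile}.
#' @return numeric vector, Angstrom.
#' @export
profile_bin_centers <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Density peaks of one role
#'
#' Local maxima of the role's density curve above a noise floor (a fraction
#' of the global maximum), returned tallest first.
#'
#' @param profile a \code{density_profile}.
#' @param role column to analyze.
#' @param floor_frac noise floor as a fraction of the global maximum
#'   (default 0.10).
#' @return data.frame with columns \code{z} (bin center, Angstrom) and
#'   \code{density} (g/cm^3), ordered by decreasing density; zero rows if
#'   the curve is flat or empty.
#' @export
peak_positions <- function(profile, role, floor_frac = 0.10) {
  stopifnot(inherits(profile, "density_profile"))
  if (!role %in% colnames(profile$density)) stop("no such role: ", role)
  d <- profile$density[, role]
  z <- profile_bin_centers(profile)
  if (all(d == 0)) return(data.frame(z = numeric(0), density = numeric(0)))
  floor_v <- floor_frac * max(d)
  n <- length(d)
  left <- c(-Inf, d[-n]); right <- c(d[-1], -Inf)
  is_peak <- d > left & d >= right & d > floor_v
  out <- data.frame(z = z[is_peak], density = d[is_peak])
  out[order(-out$density), , drop = FALSE]
}

#' Mass fraction of a role below the crystal surface edge
#'
#' Fraction of a role's mass found at z below \code{surface_edge_z} -- the
#' overlap of a solvent layer with the (rough) crystal surface. A bin
#' straddling the edge contributes the linear fraction of its width below
#' the edge.
#'
#' @param profile a \code{density_profile}.
#' @param role column to analyze.
#' @param surface_edge_z edge position, Angstrom (within the profile range).
#' @return scalar in [0, 1].
#' @export
surface_overlap <- function(profile, role, surface_edge_z) {
  stopifnot(inherits(profile, "density_profile"))
  d <- profile$density[, role]
  e <- profile$bin_edges
  if (surface_edge_z < e[1] || surface_edge_z > e[length(e)]) {
    stop("surface_edge_z lies outside the profile range")
  }
  tot <- sum(d)
  if (tot == 0) return(0)
  lo <- e[-length(e)]; hi <- e[-1]
  w <- pmin(pmax((surface_edge_z - lo) / (hi - lo), 0), 1)
  sum(d * w) / tot
}
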