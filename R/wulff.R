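# Crystal habit: Laue-class form expansion, growth rates from attachment
# energies, Wulff (halfspace-intersection) construction, facet areas and
# side ratios.

# Integer point-group generators per Laue class, acting on Miller indices.
#' @keywords internal
.laue_ops <- function(laue_class) {
  I3 <- diag(3)
  switch(laue_class,
    "-1" = list(I3, -I3),
    "2/m" = {           # b-unique: 2-fold along b, mirror normal to b, inversion
      two <- diag(c(-1, 1, -1))
      list(I3, two, -I3, -two)
    },
    "mmm" = {
      signs <- expand.grid(c(1, -1), c(1, -1), c(1, -1))
      lapply(seq_len(nrow(signs)), function(i) diag(as.numeric(signs[i, ])))
    },
    "4/mmm" = {
      base <- .laue_ops("mmm")
      swap <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
      c(base, lapply(base, function(o) o %*% swap))
    },
    "m-3m" = {
      perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      signs <- expand.grid(c(1, -1), c(1, -1), c(1, -1))
      ops <- list()
      for (p in perms) {
        P <- diag(3)[p, ]
        for (i in seq_len(nrow(signs))) {
          ops[[length(ops) + 1L]] <- diag(as.numeric(signs[i, ])) %*% P
        }
      }
      ops
    },
    stop("unsupported Laue class: ", laue_class)
  )
}

#' Expand a crystal form under its Laue class
#'
#' Returns the orbit of (h k l) under the Laue point group (point group plus
#' inversion), i.e. the complete form \{h k l\}. The orbit size is the
#' crystallographic multiplicity of the form.
#'
#' @param hkl integer 3-vector.
#' @param laue_class one of \code{"-1"}, \code{"2/m"}, \code{"mmm"},
#'   \code{"4/mmm"}, \code{"m-3m"}; defaults to the class stored on
#'   \code{cell} when given.
#' @param cell optional \code{unit_cell} carrying a \code{laue_class}.
#' @return integer matrix, one equivalent index per row.
#' @examples
#' expand_form(c(1, 1, 0), "2/m")   # multiplicity 4
#' expand_form(c(2, 0, 0), "2/m")   # multiplicity 2
#' @export
expand_form <- function(hkl, laue_class = NULL, cell = NULL) {
  hkl <- .check_hkl(hkl)
  if (is.null(laue_class)) {
    if (is.null(cell) || is.null(cell$laue_class)) {
      stop("no Laue class given and none stored on the cell")
    }
    laue_class <- cell$laue_class
  }
  ops <- .laue_ops(laue_class)
  orbit <- t(vapply(ops, function(o) as.integer(round(o %*% hkl)), integer(3)))
  unique(orbit)
}

#' Build a face table
#'
#' Assembles the per-form record used by the habit machinery: one row per
#' crystallographic form with its attachment energy and, optionally, the
#' crystal--solvent interaction energy.
#'
#' @param hkl n x 3 integer matrix (or list of 3-vectors) of form indices.
#' @param e_att attachment energies, kcal/mol (conventionally <= 0).
#' @param e_int optional crystal--solvent interaction energies, kcal/mol.
#' @param cell optional \code{unit_cell}; when given, \code{d_hkl} and
#'   multiplicities are filled in.
#' @return data.frame of class \code{face_table}.
#' @export
face_table <- function(hkl, e_att = NULL, e_int = NULL, cell = NULL) {
  if (is.list(hkl)) hkl <- do.call(rbind, hkl)
  hkl <- matrix(as.integer(hkl), ncol = 3)
  n <- nrow(hkl)
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3])
  out$label <- apply(hkl, 1, function(v) sprintf("(%d %d %d)", v[1], v[2], v[3]))
  if (!is.null(cell)) {
    out$multiplicity <- vapply(seq_len(n), function(i)
      nrow(expand_form(hkl[i, ], cell = cell)), integer(1))
    out$d_hkl <- d_spacing(cell, hkl)
  }
  if (!is.null(e_att)) {
    stopifnot(length(e_att) == n)
    out$e_att <- as.numeric(e_att)
  }
  if (!is.null(e_int)) {
    stopifnot(length(e_int) == n)
    out$e_int <- as.numeric(e_int)
  }
  class(out) <- c("face_table", "data.frame")
  out
}

#' Relative growth rates from attachment energies
#'
#' Under the attachment-energy habit model the relative growth rate of a
#' face is proportional to the magnitude of its attachment energy,
#' \eqn{R_{hkl} \propto |E_{att}|}; in solution the solvent-modified rate is
#' \eqn{R'_{hkl} \propto |E'_{att}|} with \eqn{E'_{att} = E_{att} - E_{int}}.
#' Rates are normalized so the slowest face has rate 1.
#'
#' @param faces a \code{face_table} with an \code{e_att} column (and
#'   \code{e_int} for \code{mode = "solvent"}).
#' @param mode \code{"vacuum"} (use \eqn{|E_{att}|}) or \code{"solvent"}
#'   (use \eqn{|E_{att} - E_{int}|}).
#' @param area_scale scaling applied to \code{e_int} before subtraction (see
#'   \code{\link{modified_attachment_energy}}).
#' @return the face table with \code{e_att_prime} (solvent mode) and
#'   \code{growth_rate} columns added.
#' @export
growth_rates_from_energies <- function(faces, mode = c("vacuum", "solvent"),
                                       area_scale = 1) {
  mode <- match.arg(mode)
  if (is.null(faces$e_att)) stop("face table has no e_att column")
  if (mode == "vacuum") {
    raw <- abs(faces$e_att)
  } else {
    if (is.null(faces$e_int) || anyNA(faces$e_int)) {
      stop("solvent mode needs an e_int value for every face")
    }
    faces$e_att_prime <- modified_attachment_energy(faces$e_att, faces$e_int,
                                                    area_scale = area_scale)
    raw <- abs(faces$e_att_prime)
  }
  if (any(raw <= 0)) stop("cannot derive a growth rate from a zero energy")
  faces$growth_rate <- raw / min(raw)
  faces
}

# Clip a convex 2D polygon by the halfplane a*x + b*y <= c (Sutherland-Hodgman).
#' @keywords internal
.clip_halfplane <- function(poly, a, b, c) {
  m <- nrow(poly)
  if (m == 0) return(poly)
  f <- a * poly[, 1] + b * poly[, 2] - c
  nxt <- c(2:m, 1)
  out <- matrix(0, 0, 2)
  for (k in seq_len(m)) {
    P <- poly[k, ]; fP <- f[k]
    Q <- poly[nxt[k], ]; fQ <- f[nxt[k]]
    if (fP <= 0) out <- rbind(out, P)
    if ((fP < 0 && fQ > 0) || (fP > 0 && fQ < 0)) {
      t <- fP / (fP - fQ)
      out <- rbind(out, P + t * (Q - P))
    }
  }
  if (nrow(out) < 3) out <- matrix(0, 0, 2)
  out
}

# Core halfspace-intersection engine: for each plane {x . n_i = d_i}, clip
# the supporting plane by every other halfspace (Sutherland-Hodgman in the
# plane's 2D frame) to get the facet polygon and its area. Planes falling
# outside the intersection get empty polygons and zero area.
#' @keywords internal
.halfspace_facet_polygons <- function(normals, dists) {
  np <- nrow(normals)
  L <- 100 * max(dists)
  areas <- numeric(np)
  polys <- vector("list", np)
  for (i in seq_len(np)) {
    ni <- normals[i, ]; di <- dists[i]
    seed <- if (abs(ni[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- seed - sum(seed * ni) * ni; u <- u / sqrt(sum(u^2))
    v <- c(ni[2] * u[3] - ni[3] * u[2],
           ni[3] * u[1] - ni[1] * u[3],
           ni[1] * u[2] - ni[2] * u[1])
    p0 <- di * ni
    poly <- rbind(c(-L, -L), c(L, -L), c(L, L), c(-L, L))
    for (j in seq_len(np)) {
      if (j == i) next
      aj <- sum(u * normals[j, ]); bj <- sum(v * normals[j, ])
      cj <- dists[j] - sum(p0 * normals[j, ])
      poly <- .clip_halfplane(poly, aj, bj, cj)
      if (nrow(poly) == 0) break
    }
    if (nrow(poly) >= 3) {
      if (max(abs(poly)) > 0.45 * L) {
        stop("unbounded habit: halfspace intersection is not a closed polyhedron")
      }
      m <- nrow(poly)
      x <- poly[, 1]; y <- poly[, 2]
      areas[i] <- abs(sum(x * y[c(2:m, 1)] - x[c(2:m, 1)] * y)) / 2
      polys[[i]] <- sweep(poly[, 1, drop = FALSE] %*% rbind(u) +
                          poly[, 2, drop = FALSE] %*% rbind(v), 2, -p0)
    }
  }
  list(areas = areas, polygons = polys)
}

#' @keywords internal
.halfspace_facet_areas <- function(normals, dists) {
  .halfspace_facet_polygons(normals, dists)$areas
}

#' Wulff construction from face normals and center-to-face distances
#'
#' Intersects the halfspaces \eqn{\{x : x \cdot n_f \le d_f\}} over all
#' symmetry-expanded faces and returns the resulting convex polyhedron with
#' every facet attributed to its generating form. Each facet polygon is
#' obtained by clipping its supporting plane by all other halfspaces; a form
#' whose plane lies entirely outside the intersection gets zero area
#' ("absent" face).
#'
#' @param cell a \code{unit_cell} supplying the plane normals.
#' @param hkl n x 3 integer matrix of form indices (one row per form).
#' @param distances center-to-face distances, one per form, all positive.
#'   Under the habit rule these are proportional to relative growth rates.
#' @param laue_class Laue class used for form expansion; defaults to the
#'   cell's stored class.
#' @return object of class \code{wulff_shape}: facet polygons, areas, form
#'   attribution, merged vertex list.
#' @examples
#' cub <- unit_cell(10, 10, 10, space_group = "Pm-3m")
#' sh <- wulff_construct(cub, rbind(c(1, 0, 0)), 1)
#' facet_area_fractions(sh)   # a cube, 100% on {1 0 0}
#' @export
wulff_construct <- function(cell, hkl, distances, laue_class = NULL) {
  if (is.list(hkl)) hkl <- do.call(rbind, hkl)
  hkl <- matrix(as.integer(hkl), ncol = 3)
  nf <- nrow(hkl)
  stopifnot(length(distances) == nf)
  if (any(distances <= 0)) stop("all center-to-face distances must be positive")

  # expand forms into concrete planes
  normals <- matrix(0, 0, 3); plane_d <- numeric(0)
  form_of <- integer(0); plane_hkl <- matrix(0L, 0, 3)
  for (i in seq_len(nf)) {
    orbit <- expand_form(hkl[i, ], laue_class = laue_class, cell = cell)
    for (r in seq_len(nrow(orbit))) {
      n <- plane_unit_normal(cell, orbit[r, ])
      normals <- rbind(normals, n)
      plane_d <- c(plane_d, distances[i])
      form_of <- c(form_of, i)
      plane_hkl <- rbind(plane_hkl, orbit[r, ])
    }
  }
  np <- nrow(normals)
  if (np < 4) stop("fewer than 4 halfspaces: intersection cannot be bounded")
  if (qr(normals)$rank < 3) stop("face normals do not span 3D: unbounded habit")

  # drop duplicate planes (same normal): keep the tightest distance
  keep <- rep(TRUE, np)
  for (i in seq_len(np - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):np) {
      if (!keep[j]) next
      if (sum(normals[i, ] * normals[j, ]) > 1 - 1e-12) {
        if (plane_d[j] < plane_d[i]) keep[i] <- FALSE else keep[j] <- FALSE
      }
    }
  }
  normals <- normals[keep, , drop = FALSE]; plane_d <- plane_d[keep]
  form_of <- form_of[keep]; plane_hkl <- plane_hkl[keep, , drop = FALSE]
  np <- nrow(normals)

  clipped <- .halfspace_facet_polygons(normals, plane_d)
  facets <- vector("list", np)
  for (i in seq_len(np)) {
    facets[[i]] <- list(form = form_of[i], hkl = plane_hkl[i, ],
                        normal = normals[i, ], distance = plane_d[i],
                        vertices = clipped$polygons[[i]],
                        area = clipped$areas[i])
  }

  # merged vertex list (watertight bookkeeping + OBJ export)
  tol <- 1e-8 * max(plane_d)
  allv <- do.call(rbind, lapply(facets, function(f) f$vertices))
  verts <- matrix(0, 0, 3)
  facet_index <- vector("list", np)
  if (!is.null(allv)) {
    key <- function(p) paste(round(p / tol), collapse = ",")
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(np)) {
      fv <- facets[[i]]$vertices
      if (is.null(fv)) { facet_index[[i]] <- integer(0); next }
      idx <- integer(nrow(fv))
      for (r in seq_len(nrow(fv))) {
        k <- key(fv[r, ])
        if (is.null(seen[[k]])) {
          verts <- rbind(verts, fv[r, ])
          seen[[k]] <- nrow(verts)
        }
        idx[r] <- seen[[k]]
      }
      facet_index[[i]] <- idx[!duplicated(idx)]
    }
  }

  labels <- apply(hkl, 1, function(v) sprintf("(%d %d %d)", v[1], v[2], v[3]))
  structure(list(facets = facets, forms = hkl, form_labels = labels,
                 distances = distances, vertices = verts,
                 facet_index = facet_index, cell = cell),
            class = "wulff_shape")
}

#' @export
print.wulff_shape <- function(x, ...) {
  fr <- facet_area_fractions(x)
  cat("Wulff shape:", length(x$facets), "candidate facets,",
      sum(vapply(x$facets, function(f) f$area > 0, logical(1))), "present\n")
  cat("facet-area fractions (%):\n")
  print(round(fr, 2))
  invisible(x)
}

#' Facet-area fractions per form
#'
#' Sums facet areas over each form family and expresses them as a percent of
#' the total surface area. Absent forms report 0; fractions sum to 100.
#'
#' @param shape a \code{wulff_shape}.
#' @return named numeric vector (percent), one entry per input form.
#' @export
facet_area_fractions <- function(shape) {
  stopifnot(inherits(shape, "wulff_shape"))
  areas <- vapply(shape$facets, function(f) f$area, numeric(1))
  forms <- vapply(shape$facets, function(f) f$form, numeric(1))
  tot <- sum(areas)
  if (tot <= 0) stop("shape has no surface area")
  out <- numeric(nrow(shape$forms))
  agg <- tapply(areas, forms, sum)
  out[as.integer(names(agg))] <- agg
  stats::setNames(100 * out / tot, shape$form_labels)
}

#' Total surface area and volume of a Wulff shape
#'
#' @param shape a \code{wulff_shape}.
#' @return list with \code{area} and \code{volume} (in the distance unit
#'   squared and cubed). Volume uses the cone decomposition
#'   \eqn{V = \sum_f d_f A_f / 3} valid for star-shaped polyhedra about the
#'   origin.
#' @export
shape_measures <- function(shape) {
  areas <- vapply(shape$facets, function(f) f$area, numeric(1))
  dists <- vapply(shape$facets, function(f) f$distance, numeric(1))
  list(area = sum(areas), volume = sum(areas * dists) / 3)
}

#' Side ratio of two crystal forms
#'
#' Scale-invariant morphology descriptor comparing the facet sizes of two
#' forms: the default is the ratio of the square roots of the mean
#' single-facet areas, an analogue of the edge-length ratio measured on
#' optical photographs of crystals. An alternative based on the longest
#' in-plane facet edge is available.
#'
#' @param shape a \code{wulff_shape}.
#' @param form_a,form_b integer 3-vectors naming two of the shape's forms.
#' @param method \code{"sqrt_area"} (default) or \code{"max_edge"}.
#' @return positive scalar; \code{side_ratio(a, b) * side_ratio(b, a) == 1}.
#' @export
side_ratio <- function(shape, form_a, form_b, method = c("sqrt_area", "max_edge")) {
  method <- match.arg(method)
  find_form <- function(hkl) {
    hkl <- .check_hkl(hkl)
    for (i in seq_len(nrow(shape$forms))) {
      if (all(shape$forms[i, ] == hkl)) return(i)
    }
    stop(sprintf("form (%d %d %d) is not part of this shape", hkl[1], hkl[2], hkl[3]))
  }
  ia <- find_form(form_a); ib <- find_form(form_b)
  scale_of <- function(fi) {
    fac <- Filter(function(f) f$form == fi && f$area > 0, shape$facets)
    if (length(fac) == 0) {
      stop("undefined side ratio: form ", shape$form_labels[fi],
           " is absent from the habit")
    }
    if (method == "sqrt_area") {
      sqrt(mean(vapply(fac, function(f) f$area, numeric(1))))
    } else {
      max(vapply(fac, function(f) {
        v <- f$vertices; m <- nrow(v)
        max(sqrt(rowSums((v[c(2:m, 1), , drop = FALSE] - v)^2)))
      }, numeric(1)))
    }
  }
  scale_of(ia) / scale_of(ib)
}

#' Predict a crystal habit from a face table
#'
#' Convenience wrapper: derives growth rates from attachment energies
#' (vacuum) or solvent-modified attachment energies, uses them as Wulff
#' distances, and builds the shape.
#'
#' @param cell a \code{unit_cell}.
#' @param faces a \code{face_table} with \code{e_att} (and \code{e_int} for
#'   solvent mode).
#' @param mode \code{"vacuum"} or \code{"solvent"}.
#' @param distances optional explicit distances overriding the energy rule.
#' @param area_scale passed to \code{\link{growth_rates_from_energies}}.
#' @return a \code{wulff_shape}.
#' @export
predict_habit <- function(cell, faces, mode = c("vacuum", "solvent"),
                          distances = NULL, area_scale = 1) {
  mode <- match.arg(mode)
  hkl <- as.matrix(faces[, c("h", "k", "l")])
  if (is.null(distances)) {
    faces <- growth_rates_from_energies(faces, mode = mode, area_scale = area_scale)
    distances <- faces$growth_rate
  }
  wulff_construct(cell, hkl, distances)
}
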