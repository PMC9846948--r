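# Format readers and writers shared by all stages: face-table CSV, XYZ /
# extended XYZ (single- and multi-frame), minimal CIF, atom sidecar CSV,
# OBJ polyhedron export, and YAML run configuration.

#' Read a face table from CSV
#'
#' Expected columns: \code{hkl} (the three indices space-separated in one
#' field, e.g. \code{"2 0 -2"}), \code{e_att}; optional \code{multiplicity},
#' \code{d_hkl}, \code{e_int}. Negative components are plain integers.
#'
#' @param path CSV file path.
#' @return a \code{face_table} data.frame.
#' @export
read_face_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"hkl" %in% names(df)) stop("face CSV needs an 'hkl' column")
  idx <- t(vapply(strsplit(trimws(df$hkl), "\\s+"),
                  function(v) as.integer(v), integer(3)))
  out <- face_table(idx,
                    e_att = if ("e_att" %in% names(df)) df$e_att,
                    e_int = if ("e_int" %in% names(df)) df$e_int)
  for (cn in c("multiplicity", "d_hkl")) {
    if (cn %in% names(df)) out[[cn]] <- df[[cn]]
  }
  out
}

#' Write a face table to CSV
#'
#' @param faces a \code{face_table}.
#' @param path output path.
#' @export
write_face_table <- function(faces, path) {
  df <- as.data.frame(faces)
  df$hkl <- sprintf("%d %d %d", df$h, df$k, df$l)
  df <- df[, c("hkl", setdiff(names(df), c("hkl", "h", "k", "l", "label")))]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read (possibly multi-frame) XYZ coordinates
#'
#' Standard XYZ: atom count line, comment line, then element/x/y/z rows;
#' frames may be concatenated. An extended-XYZ \code{Lattice="..."} entry in
#' the comment line is parsed into a box matrix.
#'
#' @param path file path.
#' @return list of frames, each a list with \code{atoms} (data.frame:
#'   element, x, y, z), \code{comment}, and \code{box} (3x3 matrix or NULL).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ at line ", i)
    comment <- lines[i + 1]
    rows <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    at <- data.frame(
      element = vapply(parts, `[`, character(1), 1),
      x = as.numeric(vapply(parts, `[`, character(1), 2)),
      y = as.numeric(vapply(parts, `[`, character(1), 3)),
      z = as.numeric(vapply(parts, `[`, character(1), 4)))
    box <- NULL
    m <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
    if (length(m) == 1 && nzchar(m)) {
      v <- as.numeric(strsplit(sub('Lattice="([^"]+)"', "\\1", m), "\\s+")[[1]])
      box <- matrix(v, 3, 3, byrow = TRUE)
    }
    frames[[length(frames) + 1]] <- list(atoms = at, comment = comment, box = box)
    i <- i + 2 + n
  }
  frames
}

#' Write systems as (extended) XYZ
#'
#' @param systems a \code{molecular_system} or list of them (frames).
#' @param path output path.
#' @param comment optional comment line; a \code{Lattice="..."} entry is
#'   appended automatically when the system has a box.
#' @export
write_xyz <- function(systems, path, comment = "") {
  if (inherits(systems, "molecular_system")) systems <- list(systems)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in systems) {
    at <- s$atoms
    cm <- comment
    if (!is.null(s$box)) {
      cm <- paste0(cm, if (nzchar(cm)) " " else "",
                   sprintf('Lattice="%s"', paste(signif(t(s$box), 12), collapse = " ")))
    }
    writeLines(as.character(nrow(at)), con)
    writeLines(cm, con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f", at$element, at$x, at$y, at$z), con)
  }
  invisible(path)
}

#' Read a molecular system from XYZ plus an atom sidecar CSV
#'
#' The sidecar carries per-atom metadata the XYZ cannot: columns
#' \code{index}, \code{mass}, \code{charge}, \code{role},
#' \code{molecule_id}; missing sidecar values fall back to tabulated masses,
#' zero charges and one molecule per atom.
#'
#' @param xyz_path XYZ file (first frame used).
#' @param sidecar_path optional CSV path.
#' @return a \code{molecular_system}.
#' @export
read_system <- function(xyz_path, sidecar_path = NULL) {
  fr <- read_xyz(xyz_path)[[1]]
  at <- fr$atoms
  at$mass <- atomic_mass(at$element)
  at$charge <- 0
  if (!is.null(sidecar_path)) {
    sc <- utils::read.csv(sidecar_path, stringsAsFactors = FALSE)
    if (!"index" %in% names(sc)) stop("sidecar needs an 'index' column")
    ord <- match(seq_len(nrow(at)), sc$index)
    for (cn in intersect(c("mass", "charge", "role", "molecule_id"), names(sc))) {
      at[[cn]] <- sc[[cn]][ord]
    }
  }
  molecular_system(at, box = fr$box)
}

#' Write a molecular system as XYZ plus sidecar CSV
#'
#' @param system a \code{molecular_system}.
#' @param xyz_path XYZ output path.
#' @param sidecar_path CSV output path (optional).
#' @export
write_system <- function(system, xyz_path, sidecar_path = NULL) {
  write_xyz(system, xyz_path)
  if (!is.null(sidecar_path)) {
    at <- system$atoms
    utils::write.csv(data.frame(index = seq_len(nrow(at)), mass = at$mass,
                                charge = at$charge, role = at$role,
                                molecule_id = at$molecule_id),
                     sidecar_path, row.names = FALSE)
  }
  invisible(xyz_path)
}

#' Minimal CIF reader
#'
#' Parses the subset of CIF needed here: cell parameters, the space-group
#' symbol, symmetry operation strings, and fractional atom sites. Not a
#' general CIF parser.
#'
#' @param path CIF file path.
#' @return list with \code{cell} (a \code{unit_cell}), \code{atoms}
#'   (data.frame: label, element, fx, fy, fz) and \code{symmetry_ops}
#'   (character vector, possibly empty).
#' @export
read_cif_minimal <- function(path) {
  lines <- readLines(path)
  val <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA)
    v <- sub(paste0("^\\s*", tag, "\\s+"), "", ln[1])
    v
  }
  num <- function(tag) {
    v <- val(tag)
    if (is.na(v)) return(NA_real_)
    as.numeric(sub("\\(.*\\)", "", v))   # strip esd parentheses
  }
  a <- num("_cell_length_a"); b <- num("_cell_length_b"); c <- num("_cell_length_c")
  al <- num("_cell_angle_alpha"); be <- num("_cell_angle_beta"); ga <- num("_cell_angle_gamma")
  if (anyNA(c(a, b, c))) stop("CIF lacks cell lengths")
  if (is.na(al)) al <- 90; if (is.na(be)) be <- 90; if (is.na(ga)) ga <- 90
  sg <- val("_symmetry_space_group_name_H-M")
  if (is.na(sg)) sg <- val("_space_group_name_H-M_alt")
  if (!is.na(sg)) sg <- gsub("['\"]", "", sg)
  cell <- unit_cell(a, b, c, al, be, ga,
                    space_group = if (is.na(sg)) NULL else trimws(sg))

  # loops
  ops <- character(0)
  atoms <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_", lines[i])) {
      j <- i + 1
      tags <- character(0)
      while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1
      }
      body <- character(0)
      while (j <= length(lines) && nzchar(trimws(lines[j])) &&
             !grepl("^\\s*(_|loop_|data_|#)", lines[j])) {
        body <- c(body, trimws(lines[j])); j <- j + 1
      }
      if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz", tags))) {
        ops <- gsub("^['\"]|['\"]$", "", sub("^\\d+\\s+", "", body))
      }
      if (any(grepl("_atom_site_fract_x", tags))) {
        fields <- strsplit(body, "\\s+")
        col <- function(tag) {
          k <- grep(tag, tags)[1]
          vapply(fields, `[`, character(1), k)
        }
        strip <- function(x) as.numeric(sub("\\(.*\\)", "", x))
        lab <- if (any(grepl("_atom_site_label", tags))) col("_atom_site_label") else NA
        el <- if (any(grepl("_atom_site_type_symbol", tags))) col("_atom_site_type_symbol") else lab
        atoms <- data.frame(label = lab, element = gsub("[0-9+-]+$", "", el),
                            fx = strip(col("_atom_site_fract_x")),
                            fy = strip(col("_atom_site_fract_y")),
                            fz = strip(col("_atom_site_fract_z")),
                            stringsAsFactors = FALSE)
      }
      i <- j
    } else i <- i + 1
  }
  list(cell = cell, atoms = atoms, symmetry_ops = ops)
}

#' Export a Wulff shape as Wavefront OBJ
#'
#' @param shape a \code{wulff_shape}.
#' @param path output path.
#' @export
write_obj <- function(shape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Wulff habit polyhedron", con)
  v <- shape$vertices
  for (r in seq_len(nrow(v))) {
    writeLines(sprintf("v %.8f %.8f %.8f", v[r, 1], v[r, 2], v[r, 3]), con)
  }
  for (i in seq_along(shape$facet_index)) {
    idx <- shape$facet_index[[i]]
    if (length(idx) < 3) next
    writeLines(sprintf("g form_%s", gsub("[ ()]", "", shape$form_labels[shape$facets[[i]]$form])), con)
    writeLines(paste("f", paste(idx, collapse = " ")), con)
  }
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return named list; a missing \code{protocol} block is filled from
#'   \code{\link{md_protocol}}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$protocol)) cfg$protocol <- md_protocol()
  cfg
}

#' Bundled vacuum-habit face table of the calcium minodronate crystal
#'
#' The five morphologically important forms of the Ca(Min)2 crystal with
#' their multiplicities, d-spacings and vacuum attachment energies.
#'
#' @return a \code{face_table}.
#' @export
camin2_face_table <- function() {
  read_face_table(system.file("extdata", "camin2_faces.csv",
                              package = "crysmorph", mustWork = TRUE))
}

#' Reported and optimized unit cells of calcium minodronate
#'
#' @param which \code{"reported"} (single-crystal determination) or
#'   \code{"optimized"} (force-field optimized cell used for the habit
#'   geometry).
#' @return a \code{unit_cell} (monoclinic C2/c, Laue class 2/m).
#' @export
camin2_cell <- function(which = c("optimized", "reported")) {
  which <- match.arg(which)
  if (which == "optimized") {
    unit_cell(19.27, 9.74, 17.05, beta = 107.99, space_group = "C2/c")
  } else {
    unit_cell(19.40, 9.78, 17.05, beta = 106.44, space_group = "C2/c")
  }
}
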