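# Pipeline driver: executes one named stage from a configuration list and
# writes its artifacts plus a provenance manifest.

#' Run one analysis stage from a configuration
#'
#' Thin driver tying the package's stages together for scripted use. The
#' configuration is a named list (typically from
#' \code{\link{read_run_config}}) with \code{stage}, \code{output_dir},
#' optional \code{seed}, and per-stage parameters under \code{params}.
#' Every run writes a \code{manifest.json} recording the package version,
#' stage, seed, input checksums and output checksums, so a rerun with the
#' same configuration yields an identical numeric-output manifest.
#'
#' Stages: \code{"dspacing"}, \code{"habit"}, \code{"habit-solvent"},
#' \code{"build-interface"}, \code{"s-ratio"}, \code{"profile"},
#' \code{"fit-sideratio"}, \code{"correlate"}, \code{"synth"}.
#' Units are fixed throughout: Angstrom, kcal/mol, g/cm^3, microliter,
#' Debye.
#'
#' @param config named list as described above.
#' @return (invisibly) a list of produced file paths.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$stage)) stop("config is missing the field 'stage'")
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config is missing the field 'output_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  p <- config$params
  if (is.null(p)) p <- list()
  inputs <- character(0)

  get_cell <- function() {
    if (!is.null(p$cif)) {
      inputs <<- c(inputs, p$cif)
      read_cif_minimal(p$cif)$cell
    } else if (!is.null(p$cell)) {
      do.call(unit_cell, p$cell)
    } else camin2_cell()
  }
  get_faces <- function() {
    if (!is.null(p$faces_csv)) {
      inputs <<- c(inputs, p$faces_csv)
      read_face_table(p$faces_csv)
    } else camin2_face_table()
  }

  outputs <- switch(config$stage,
    "dspacing" = {
      cell <- get_cell()
      faces <- get_faces()
      hkl <- as.matrix(faces[, c("h", "k", "l")])
      df <- data.frame(hkl = faces$label, d_hkl = d_spacing(cell, hkl),
                       multiplicity = vapply(seq_len(nrow(hkl)), function(i)
                         nrow(expand_form(hkl[i, ], cell = cell)), integer(1)))
      f <- file.path(out_dir, "dspacings.csv")
      utils::write.csv(df, f, row.names = FALSE)
      f
    },
    "habit" = ,
    "habit-solvent" = {
      cell <- get_cell()
      faces <- get_faces()
      mode <- if (config$stage == "habit") "vacuum" else "solvent"
      shape <- predict_habit(cell, faces, mode = mode,
                             area_scale = if (is.null(p$area_scale)) 1 else p$area_scale)
      fr <- facet_area_fractions(shape)
      csv <- file.path(out_dir, paste0(config$stage, "-areas.csv"))
      utils::write.csv(data.frame(form = names(fr), area_percent = unname(fr)),
                       csv, row.names = FALSE)
      obj <- file.path(out_dir, paste0(config$stage, ".obj"))
      write_obj(shape, obj)
      rep <- file.path(out_dir, paste0(config$stage, "-report.json"))
      jsonlite::write_json(list(mode = mode, area_percent = as.list(fr),
                                distances = shape$distances,
                                measures = shape_measures(shape)),
                           rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(csv, obj, rep)
    },
    "build-interface" = {
      xt <- toy_crystal("cubic", a = if (is.null(p$a)) 5 else p$a,
                        repeats = if (is.null(p$repeats)) c(4, 4, 4) else p$repeats)
      slab <- cleave_slab(xt)
      water <- pack_solvent_box("water",
                                count = if (is.null(p$n_water)) 100 else p$n_water,
                                target_density = 1.0,
                                cross_section = slab$cross_section,
                                lx = slab$lx, seed = seed)
      model <- assemble_interface(slab, water = water,
                                  vacuum = if (is.null(p$vacuum)) 100 else p$vacuum)
      xyz <- file.path(out_dir, "interface.xyz")
      sc <- file.path(out_dir, "interface-atoms.csv")
      write_system(model$system, xyz, sc)
      yml <- file.path(out_dir, "protocol.yaml")
      yaml::write_yaml(md_protocol(), yml)
      c(xyz, sc, yml)
    },
    "s-ratio" = {
      sys <- read_system(p$xyz, p$sidecar)
      inputs <- c(inputs, p$xyz, p$sidecar)
      s <- solvent_accessible_ratio(sys,
             probe_radius = if (is.null(p$probe_radius)) 1 else p$probe_radius,
             grid_resolution = if (is.null(p$grid_resolution)) 0.25 else p$grid_resolution)
      f <- file.path(out_dir, "s-ratio.csv")
      utils::write.csv(data.frame(a_acc = s$a_acc, a_hkl = s$a_hkl,
                                  s_ratio = s$s_ratio), f, row.names = FALSE)
      f
    },
    "profile" = {
      inputs <- c(inputs, p$xyz, p$sidecar)
      raw <- read_xyz(p$xyz)
      sc <- utils::read.csv(p$sidecar, stringsAsFactors = FALSE)
      frames <- lapply(raw, function(fr) {
        at <- fr$atoms
        at$mass <- sc$mass; at$charge <- sc$charge
        at$role <- sc$role; at$molecule_id <- sc$molecule_id
        molecular_system(at, box = fr$box, pbc = c(TRUE, TRUE, FALSE))
      })
      fs <- frame_set(frames)
      prof <- mass_density_profile(fs,
                bin_width = if (is.null(p$bin_width)) 0.5 else p$bin_width)
      csv <- file.path(out_dir, "profile.csv")
      utils::write.csv(data.frame(z = profile_bin_centers(prof), prof$density),
                       csv, row.names = FALSE)
      peaks <- lapply(colnames(prof$density), function(r) peak_positions(prof, r))
      names(peaks) <- colnames(prof$density)
      pj <- file.path(out_dir, "peaks.json")
      jsonlite::write_json(peaks, pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(csv, pj)
    },
    "fit-sideratio" = {
      inputs <- c(inputs, p$series_csv)
      df <- utils::read.csv(p$series_csv, stringsAsFactors = FALSE)
      fits <- lapply(split(df, df$solvent), function(s)
        fit_sideratio(s[, c("volume", "side_ratio")]))
      f <- file.path(out_dir, "sideratio-fits.json")
      jsonlite::write_json(fits, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      f
    },
    "correlate" = {
      inputs <- c(inputs, p$ratios_csv)
      rdf <- utils::read.csv(p$ratios_csv, stringsAsFactors = FALSE)
      ratios <- stats::setNames(rdf$side_ratio, rdf$solvent)
      props <- if (!is.null(p$props_csv)) {
        inputs <- c(inputs, p$props_csv)
        utils::read.csv(p$props_csv, stringsAsFactors = FALSE)
      } else solvent_reference_properties()
      cors <- property_correlations(ratios, props)
      ranking <- rank_solvents(ratios)
      f <- file.path(out_dir, "correlations.json")
      jsonlite::write_json(list(correlations = cors, ranking = ranking),
                           f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      f
    },
    "synth" = {
      layers <- if (is.null(p$layers)) {
        # a tight organic adsorption layer at the surface edge plus a broad
        # water layer above it, sampled densely enough to resolve the peaks
        data.frame(center = c(22.3, 31.0), width = c(0.6, 2.5),
                   role = c("organic", "water"), mass = c(41.05, 18.015),
                   n_atoms = c(1500, 3000))
      } else do.call(data.frame, p$layers)
      fs <- layered_frames(layers, n_frames = if (is.null(p$n_frames)) 20 else p$n_frames,
                           seed = seed)
      xyz <- file.path(out_dir, "synthetic-frames.xyz")
      write_xyz(fs$frames, xyz)
      sc <- file.path(out_dir, "synthetic-atoms.csv")
      at <- fs$frames[[1]]$atoms
      utils::write.csv(data.frame(index = seq_len(nrow(at)), mass = at$mass,
                                  charge = at$charge, role = at$role,
                                  molecule_id = at$molecule_id),
                       sc, row.names = FALSE)
      c(xyz, sc)
    },
    stop("unknown stage: ", config$stage)
  )

  manifest <- list(
    package = "crysmorph",
    version = as.character(utils::packageVersion("crysmorph")),
    stage = config$stage, seed = seed,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(outputs, file.path(out_dir, "manifest.json")))
}
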