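#' @title Model and result input/output
#' @name io
#' @description Voxel models are written as legacy ASCII VTK structured-points
#'   files (cell data: solid fraction and strut id) with a YAML sidecar
#'   carrying the lattice metadata and strut table; curves go to CSV.
NULL

#' Write a voxel model to VTK (plus YAML sidecar)
#'
#' @param model A `voxel_model`.
#' @param path Output path; `.vtk` is appended if missing, and a sidecar
#'   `<path>.yaml` is written next to it.
#' @return The `.vtk` path, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "voxel_model"))
  if (!grepl("\\.vtk$", path)) path <- paste0(path, ".vtk")
  g <- model$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "trabsim voxel model", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g[1] + 1L, g[2] + 1L, g[3] + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g %.9g", model$voxel, model$voxel,
                       model$voxel),
               sprintf("CELL_DATA %d", prod(g)),
               "SCALARS solid_fraction double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(model$frac), digits = 12, trim = TRUE,
                    scientific = FALSE), con)
  writeLines(c("SCALARS strut_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.vector(model$strut_id)), con)
  meta <- list(grid = as.integer(g), voxel = model$voxel,
               lattice = model$lattice[c("type", "thickness", "spacing",
                                         "cells", "requested_voxel")],
               struts = lapply(seq_len(nrow(model$struts)), function(r)
                 as.list(model$struts[r, ])))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a voxel model written by [write_model()]
#'
#' @param path Path to the `.vtk` file (the `.yaml` sidecar must sit next to
#'   it).
#' @return A `voxel_model`.
#' @export
read_model <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  g <- as.integer(meta$grid)
  lines <- readLines(path)
  i_frac <- which(lines == "LOOKUP_TABLE default")[1]
  n <- prod(g)
  frac <- array(as.numeric(lines[(i_frac + 1):(i_frac + n)]), dim = g)
  i_id <- which(lines == "LOOKUP_TABLE default")[2]
  sid <- array(as.integer(lines[(i_id + 1):(i_id + n)]), dim = g)
  struts <- do.call(rbind, lapply(meta$struts, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  lattice <- meta$lattice
  lattice$cells <- as.integer(lattice$cells)
  structure(list(grid = g, voxel = meta$voxel, extent = g * meta$voxel,
                 frac = frac, strut_id = sid, struts = struts,
                 lattice = lattice), class = "voxel_model")
}

#' Write the apparent stress-strain history of a run to CSV
#'
#' @param result A `simulation_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(result, path) {
  utils::write.csv(result$steps, path, row.names = FALSE)
  invisible(path)
}

#' Write per-element damage fields of a finished run to VTK
#'
#' Cell arrays: solid fraction, damage, cracked flag, on the full voxel grid
#' (non-element voxels carry zero).
#'
#' @param result A `simulation_result`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_damage_vtk <- function(result, path) {
  if (!grepl("\\.vtk$", path)) path <- paste0(path, ".vtk")
  model <- result$model
  g <- model$grid
  dmg <- numeric(prod(g)); crk <- integer(prod(g))
  dmg[result$system$elements] <- result$state$d
  crk[result$system$elements] <- as.integer(result$state$cracked)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "trabsim damage field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g[1] + 1L, g[2] + 1L, g[3] + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g %.9g", model$voxel, model$voxel,
                       model$voxel),
               sprintf("CELL_DATA %d", prod(g)),
               "SCALARS solid_fraction double 1", "LOOKUP_TABLE default"),
             con)
  writeLines(format(as.vector(model$frac), digits = 6, trim = TRUE), con)
  writeLines(c("SCALARS damage double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(dmg, digits = 6, trim = TRUE), con)
  writeLines(c("SCALARS cracked int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(crk), con)
  invisible(path)
}
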