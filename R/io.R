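# File interfaces: legacy ASCII VTK (unstructured tissue meshes and
# structured flow snapshots), CSV traces and the JSON run manifest.
# Indices are 0-based in VTK files, 1-based in memory.

#' Write a tissue mesh (+ cell data) as legacy ASCII VTK
#'
#' @param mesh A `tissue_mesh` built from tet/voxel cells is written as a
#'   POLYDATA-free unstructured grid of its cell centroids when no `cells`
#'   geometry is supplied; give `nodes`/`tets` for full tetrahedral
#'   geometry.
#' @param path Output path.
#' @param cell_data Named list of per-cell numeric vectors (e.g. `v`,
#'   `Ta`, activation time).
#' @param nodes,tets Optional tetrahedral geometry (mm).
#' @param title VTK title line; records the unit convention.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, cell_data = list(), nodes = NULL,
                           tets = NULL, title = "cardiosim EP units mm/ms/mV") {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("%s", title)
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  if (!is.null(nodes) && !is.null(tets)) {
    wl("POINTS %d double", nrow(nodes))
    writeLines(apply(nodes, 1, function(r) paste(format(r, digits = 17),
                                                 collapse = " ")), con)
    wl("CELLS %d %d", nrow(tets), 5 * nrow(tets))
    writeLines(apply(tets - 1L, 1, function(r)
      paste(c(4L, r), collapse = " ")), con)
    wl("CELL_TYPES %d", nrow(tets))
    writeLines(rep("10", nrow(tets)), con)
    ncell <- nrow(tets)
  } else {
    wl("POINTS %d double", mesh$n_cells)
    writeLines(apply(mesh$centroids, 1, function(r)
      paste(format(r, digits = 17), collapse = " ")), con)
    wl("CELLS %d %d", mesh$n_cells, 2 * mesh$n_cells)
    writeLines(paste(1L, seq_len(mesh$n_cells) - 1L), con)
    wl("CELL_TYPES %d", mesh$n_cells)
    writeLines(rep("1", mesh$n_cells), con)
    ncell <- mesh$n_cells
  }
  if (length(cell_data)) {
    wl("CELL_DATA %d", ncell)
    for (nm in names(cell_data)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(format(cell_data[[nm]], digits = 17), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid
#'
#' @param path File written by [write_vtk_mesh] (or compatible).
#' @return List with `points`, `cells` (1-based connectivity list),
#'   `cell_types`, `cell_data` (named list).
#' @export
read_vtk_mesh <- function(path) {
  ln <- readLines(path)
  i_pts <- grep("^POINTS", ln)[1]
  npts <- as.integer(strsplit(ln[i_pts], "\\s+")[[1]][2])
  pts <- matrix(as.numeric(unlist(strsplit(trimws(
    ln[(i_pts + 1):(i_pts + npts)]), "\\s+"))), npts, byrow = TRUE)
  i_cells <- grep("^CELLS", ln)[1]
  ncell <- as.integer(strsplit(ln[i_cells], "\\s+")[[1]][2])
  cells <- lapply((i_cells + 1):(i_cells + ncell), function(k) {
    v <- as.integer(strsplit(trimws(ln[k]), "\\s+")[[1]])
    v[-1] + 1L
  })
  i_types <- grep("^CELL_TYPES", ln)[1]
  types <- as.integer(ln[(i_types + 1):(i_types + ncell)])
  cd <- list()
  for (i_sc in grep("^SCALARS", ln)) {
    nm <- strsplit(ln[i_sc], "\\s+")[[1]][2]
    cd[[nm]] <- as.numeric(ln[(i_sc + 2):(i_sc + 1 + ncell)])
  }
  list(points = pts, cells = cells, cell_types = types, cell_data = cd)
}

#' Write a flow snapshot as legacy ASCII VTK structured points
#'
#' Cell-centred pressure and interpolated cell-centred velocity magnitude.
#'
#' @param grid A `flow_grid`.
#' @param state A `flow_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk_flow <- function(grid, state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  uc <- (state$u + shx(state$u, 1)) / 2
  vf <- if (grid$bc_y == "periodic") cbind(state$v, state$v[, 1]) else state$v
  vc <- (vf[, 1:grid$ny] + vf[, 2:(grid$ny + 1)]) / 2
  wl("# vtk DataFile Version 3.0")
  wl("cardiosim flow snapshot SI units t=%.9g", state$t)
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS %d %d 1", grid$nx, grid$ny)
  wl("ORIGIN %.9g %.9g 0", grid$dx / 2, grid$dy / 2)
  wl("SPACING %.9g %.9g 1", grid$dx, grid$dy)
  wl("POINT_DATA %d", grid$nx * grid$ny)
  wl("SCALARS p double 1"); wl("LOOKUP_TABLE default")
  writeLines(format(as.vector(state$p), digits = 17), con)
  wl("SCALARS umag double 1"); wl("LOOKUP_TABLE default")
  writeLines(format(as.vector(sqrt(uc^2 + vc^2)), digits = 17), con)
  invisible(path)
}

#' Write time traces as CSV
#'
#' @param traces data.frame with a `t` column first.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Write the JSON run manifest
#'
#' @param config The run configuration (list).
#' @param path Output path.
#' @param extra Named list appended (e.g. output file inventory).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  man <- c(list(
    package = "cardiosim",
    package_version = as.character(utils::packageVersion("cardiosim")),
    registry_version = REGISTRY_VERSION,
    config = config,
    config_hash = digest_config(config),
    seed = config$seed %||% NA), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-stable hash of a config list (no external digest dependency)
digest_config <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997 + 1)) %% 2147483647
}

#' Read a JSON run configuration
#'
#' @param path JSON file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
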