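#' Write a node or element scalar field as legacy VTK
#'
#' Legacy ASCII `STRUCTURED_POINTS` file viewable in ParaView; node fields
#' are written as point data on the (nx+1) x (ny+1) node lattice, element
#' fields on the nx x ny element lattice.
#'
#' @param grid a `tissue_grid`.
#' @param values numeric matrix/vector of length (nx+1)*(ny+1) (nodes) or
#'   nx*ny (elements).
#' @param path output file.
#' @param name scalar field name.
#' @return the path, invisibly.
#' @export
write_vtk_scalars <- function(grid, values, path, name = "field") {
  v <- as.vector(values)
  h <- grid$h_um / 1000
  np <- (grid$nx + 1L) * (grid$ny + 1L)
  ne <- grid$nx * grid$ny
  if (length(v) == np) {
    dims <- c(grid$nx + 1L, grid$ny + 1L, 1L)
    origin <- c(0, 0, 0)
  } else if (length(v) == ne) {
    dims <- c(grid$nx, grid$ny, 1L)
    origin <- c(h / 2, h / 2, 0)
  } else stop("values must be a node or element field of this grid")
  v[is.na(v)] <- -1e30
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(dims)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(formatC(v, format = "g", digits = 7), con)
  invisible(path)
}

#' Write element labels as CSV
#'
#' @param grid a `tissue_grid`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_labels_csv <- function(grid, path) {
  lab <- as.vector(grid$labels)
  write.csv(data.frame(element = seq_along(lab),
                       label = names(TISSUE_LABELS)[match(lab, TISSUE_LABELS)]),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' Records the configuration (every default printed), the root seed, the
#' package version, the output files of the run, and wall-clock metadata.
#'
#' @param path output file.
#' @param config a [sim_config()] (or any serializable list).
#' @param root_seed the run's root seed.
#' @param outputs character vector of files produced by the run.
#' @param extra optional named list merged into the manifest.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config = sim_config(), root_seed = NA,
                           outputs = character(), extra = list()) {
  man <- c(list(
    package = "infarctsim",
    version = as.character(utils::packageVersion("infarctsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    root_seed = root_seed,
    config = unclass(config),
    outputs = outputs), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
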