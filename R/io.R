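# Configuration and state I/O shared by the user-facing pipelines.

#' Export a model state
#'
#' Writes all nodal fields (14 species, ECM, pressure) with coordinates as
#' CSV (one row per node), or as a legacy VTK unstructured-grid file with the
#' triangulation and one point-data array per field.
#'
#' @param state a `plaque_state`.
#' @param path output file path.
#' @param format `"csv"` or `"vtk"`.
#' @return The path, invisibly.
#' @export
export_state <- function(state, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  flds <- c(state$fields, list(rho = state$rho, sigma = state$sigma))
  if (format == "csv") {
    df <- data.frame(node = seq_len(state$mesh$n_nodes),
                     x = state$mesh$nodes[, 1], y = state$mesh$nodes[, 2])
    for (nm in names(flds)) df[[nm]] <- flds[[nm]]
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  n <- state$mesh$n_nodes; m <- state$mesh$n_tri
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("plaque state t=%g day", state$time),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(cbind(state$mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  utils::write.table(cbind(3L, state$mesh$tri - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(flds)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(flds[[nm]], digits = 17), con)
  }
  invisible(path)
}

#' Read a CSV state export back into a state
#'
#' Round-trips [export_state()] CSV output onto the provided mesh (node
#' count and order must match).
#'
#' @param mesh the `plaque_mesh` the export was written from.
#' @param path CSV path.
#' @return A `plaque_state` (not closed).
#' @export
import_state_csv <- function(mesh, path) {
  df <- utils::read.csv(path)
  if (nrow(df) != mesh$n_nodes) stop("node count mismatch for ", path)
  st <- new_state(mesh, fields = as.list(df[plaque_species()]))
  if (!is.null(df$rho)) st$rho <- df$rho
  if (!is.null(df$sigma)) st$sigma <- df$sigma
  st
}

#' Write a run manifest
#'
#' Records the configuration digest, seed and package version so reruns can
#' be matched to outputs.
#'
#' @param path output file (YAML).
#' @param config a configuration list (see [run_config()]).
#' @param seed integer seed or `NA` for deterministic runs.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seed = NA) {
  cfg <- run_config(config)
  digestable <- cfg
  digestable$parameters <- unclass(digestable$parameters)
  bytes <- utf8ToInt(paste(deparse(digestable), collapse = ""))
  digest <- sprintf("%08x",
                    Reduce(function(a, b) (a * 31 + b) %% 2147483647,
                           bytes, accumulate = FALSE))
  yaml::write_yaml(list(
    package = "atherosim",
    version = as.character(utils::packageVersion("atherosim")),
    seed = seed, config_digest = digest,
    fixture = cfg$fixture, h = cfg$h, dt = cfg$dt
  ), path)
  invisible(path)
}
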