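# write a table with doubles rendered at 17 significant digits, which
# round-trips IEEE-754 exactly through fread
fwrite_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  data.table::fwrite(df, path, quote = FALSE)
}

#' Write a simulation result to a directory of tables
#'
#' The container is a directory holding wide CSV tables (`radii.csv`,
#' `flows.csv`, `velocities.csv`, `pressures.csv`, each with a leading
#' `time` column), the graph (`nodes.csv`, `edges.csv`), the endfoot
#' coupling (`endfeet.csv`), and `meta.json` with the full configuration,
#' boundary conditions, calibrated noise amplitudes and the seed.  Numeric
#' values are written with round-trip precision, so
#' [read_results()] reproduces the arrays exactly.
#'
#' @param result a `simulation_result`.
#' @param path output directory (created if missing).
#' @return invisibly, `path`.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  wide <- function(mat, ids, prefix) {
    df <- data.table::as.data.table(mat)
    data.table::setnames(df, paste0(prefix, ids))
    df <- cbind(data.table::data.table(time = result$time), df)
    df
  }
  eid <- result$graph$edges$id
  nid <- result$graph$nodes$id
  fwrite_precise(wide(result$radii, eid, "e"), file.path(path, "radii.csv"))
  fwrite_precise(wide(result$Q, eid, "e"), file.path(path, "flows.csv"))
  fwrite_precise(wide(result$u, eid, "e"), file.path(path, "velocities.csv"))
  fwrite_precise(wide(result$p, nid, "n"), file.path(path, "pressures.csv"))
  write_graph(result$graph, file.path(path, "nodes.csv"), file.path(path, "edges.csv"))
  data.table::fwrite(as.data.frame(result$coupling), file.path(path, "endfeet.csv"))
  meta <- list(
    seed = result$seed,
    sigma = as.list(result$sigma),
    config = result$config[setdiff(names(result$config), "hydraulic")],
    hydraulic = unclass(result$config$hydraulic),
    bc = unclass(result$bc),
    balance = result$balance,
    depth_axis = result$graph$depth_axis,
    package_version = as.character(utils::packageVersion("vasculoflow"))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a simulation result container
#'
#' Validates that every trajectory block is present and reconstructs a
#' `simulation_result` (without the cached solver internals).
#'
#' @param path directory written by [write_results()].
#' @return a `simulation_result`.
#' @export
read_results <- function(path) {
  need <- c("radii.csv", "flows.csv", "velocities.csv", "pressures.csv",
            "nodes.csv", "edges.csv", "endfeet.csv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("results container is missing blocks: ", paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  graph <- load_graph(file.path(path, "nodes.csv"), file.path(path, "edges.csv"),
                      depth_axis = meta$depth_axis)
  unwide <- function(file) {
    df <- data.table::fread(file.path(path, file))
    list(time = df$time, mat = as.matrix(df[, -1, with = FALSE]))
  }
  radii <- unwide("radii.csv")
  flows <- unwide("flows.csv")
  vel <- unwide("velocities.csv")
  pres <- unwide("pressures.csv")
  coupling <- structure(as.data.frame(data.table::fread(file.path(path, "endfeet.csv"))),
                        class = c("endfoot_coupling", "data.frame"))
  cfg <- meta$config
  cfg$hydraulic <- do.call(hydraulic_params, meta$hydraulic[c("eta", "alpha", "beta", "gamma", "delta", "rho")])
  class(cfg) <- "simulation_config"
  bc <- meta$bc
  class(bc) <- "boundary_conditions"
  dimnames(radii$mat) <- dimnames(flows$mat) <- dimnames(vel$mat) <- dimnames(pres$mat) <- NULL
  structure(list(time = radii$time, radii = radii$mat, Q = flows$mat,
                 u = vel$mat, p = pres$mat, balance = meta$balance,
                 graph = graph, coupling = coupling, bc = bc, config = cfg,
                 sigma = unlist(meta$sigma), seed = meta$seed),
            class = "simulation_result")
}
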