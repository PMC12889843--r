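#' Write a trace set as CSV + JSON manifest
#'
#' Writes the dF/F matrix as a CSV table (rows = frames, columns =
#' neurons) plus a sidecar JSON manifest recording mouse id, genotype,
#' session index, frame rate and the half-open 0-based stage boundary
#' frames.
#'
#' @param ts a [trace_set()].
#' @param prefix file path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_trace_set <- function(ts, prefix) {
  stopifnot(inherits(ts, "trace_set"))
  csv <- paste0(prefix, ".csv")
  manifest <- paste0(prefix, ".json")
  df <- as.data.frame(t(ts$dff))
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(mouse_id = ts$mouse_id, genotype = ts$genotype,
         session_index = ts$session_index,
         frame_rate_hz = ts$frame_rate_hz,
         stages = ts$stages),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, manifest = manifest))
}

#' Read a trace set written by [write_trace_set()]
#'
#' @param prefix the path prefix used when writing.
#' @return A [trace_set()].
#' @export
read_trace_set <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dff <- t(as.matrix(df))
  trace_set(dff, meta$frame_rate_hz, meta$stages,
            mouse_id = meta$mouse_id, genotype = meta$genotype,
            session_index = meta$session_index)
}

#' Write a functional graph as edge-list CSV + JSON header
#'
#' The edge list has one `(node_i, node_j)` row per undirected edge with
#' 0-based node indices; the JSON header records stage, threshold and node
#' count (so empty graphs round-trip).
#'
#' @param g a [functional_graph()].
#' @param prefix path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return Invisibly, the file paths.
#' @export
write_graph <- function(g, prefix) {
  stopifnot(inherits(g, "functional_graph"))
  ed <- edge_list(g$adjacency)
  utils::write.csv(
    data.frame(node_i = ed[, 1] - 1L, node_j = ed[, 2] - 1L),
    paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stage = g$stage, threshold = g$threshold,
         n_nodes = n_nodes(g), node_ids = g$node_ids),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(csv = paste0(prefix, ".csv"), header = paste0(prefix, ".json")))
}

#' Read a functional graph written by [write_graph()]
#'
#' @param prefix the path prefix used when writing.
#' @return A [functional_graph()].
#' @export
read_graph <- function(prefix) {
  ed <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  adj <- matrix(0, meta$n_nodes, meta$n_nodes)
  if (nrow(ed)) {
    idx <- cbind(ed$node_i + 1L, ed$node_j + 1L)
    adj[idx] <- 1
    adj[idx[, 2:1, drop = FALSE]] <- 1
  }
  functional_graph(adj, node_ids = meta$node_ids, stage = meta$stage,
                   threshold = meta$threshold)
}

#' Write a dense adjacency CSV
#' @param g a [functional_graph()] or adjacency matrix.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_adjacency <- function(g, path) {
  utils::write.csv(as.data.frame(as_adjacency(g)), path, row.names = FALSE)
  invisible(path)
}

#' Read a dense adjacency CSV written by [write_adjacency()]
#' @param path CSV path.
#' @return A [functional_graph()].
#' @export
read_adjacency <- function(path) {
  functional_graph(as.matrix(utils::read.csv(path, check.names = FALSE)))
}
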