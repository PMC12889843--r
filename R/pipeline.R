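#' Compute the full per-session feature table of a cohort
#'
#' Runs the whole analysis chain on every mouse-session of a cohort:
#' stage-wise activity summaries, correlation graphs at the given
#' threshold, topological indices, cross-stage Laplacian spectral
#' distances, behavior labeling — and assembles the raw 15-predictor
#' feature table. Pass the result through [preprocess_features()] before
#' modeling.
#'
#' @param cohort a cohort from [generate_cohort()], or any list with
#'   `traces` (list of [trace_set()]) and `behavior` (S1/S2 table).
#' @param threshold correlation threshold for [binarize()].
#' @param largest_component passed to [graph_indices()].
#' @return A list with `features` (raw feature table), `indices`,
#'   `spectral`, `activity`, `behavior` (the labeled behavior table) and
#'   `graphs` (per session, the three stage graphs).
#' @export
session_features <- function(cohort, threshold = 0.3,
                             largest_component = FALSE) {
  behavior <- label_motivation(cohort$behavior)
  indices <- list()
  spectral <- list()
  activity <- list()
  graphs <- list()
  for (key in names(cohort$traces)) {
    ts <- cohort$traces[[key]]
    gs <- build_session_graphs(ts, threshold = threshold)
    graphs[[key]] <- gs
    act <- summarize_activity(ts)
    activity[[key]] <- act$per_stage
    gi <- lapply(names(gs), function(st) {
      cbind(data.frame(mouse_id = ts$mouse_id, session = ts$session_index,
                       stage = st, stringsAsFactors = FALSE),
            suppressWarnings(graph_indices(gs[[st]],
                                           largest_component = largest_component)))
    })
    indices[[key]] <- do.call(rbind, gi)
    pairs <- list(c("H", "SB"), c("H", "SN"), c("SB", "SN"))
    spectral[[key]] <- data.frame(
      mouse_id = ts$mouse_id, session = ts$session_index,
      pair = vapply(pairs, paste, character(1), collapse = "-"),
      s = vapply(pairs, function(pr)
        spectral_distance(gs[[pr[1]]], gs[[pr[2]]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  indices <- do.call(rbind, c(indices, list(make.row.names = FALSE)))
  spectral <- do.call(rbind, c(spectral, list(make.row.names = FALSE)))
  activity <- do.call(rbind, c(activity, list(make.row.names = FALSE)))
  features <- assemble_features(indices, spectral, activity, behavior)
  list(features = features, indices = indices, spectral = spectral,
       activity = activity, behavior = behavior, graphs = graphs)
}
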