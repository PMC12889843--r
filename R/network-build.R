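#' Pairwise Pearson correlation matrix of stage traces
#'
#' Correlates every pair of neurons' dF/F traces over the frames of one
#' behavioral stage. Constant traces have no defined Pearson correlation;
#' their correlations with every partner are set to 0 (no functional
#' coupling) with a warning, so degenerate neurons never create edges.
#'
#' @param dff_stage numeric matrix, neurons x frames (>= 2 neurons,
#'   >= 3 frames).
#' @return Symmetric matrix in `[-1, 1]` with unit diagonal.
#' @export
correlation_matrix <- function(dff_stage) {
  dff_stage <- as.matrix(dff_stage)
  if (nrow(dff_stage) < 2) stopf("need at least 2 neurons")
  if (ncol(dff_stage) < 3) stopf("need at least 3 frames")
  sds <- apply(dff_stage, 1, stats::sd)
  const <- sds == 0
  cc <- suppressWarnings(stats::cor(t(dff_stage)))
  if (any(const)) {
    warnf("%d constant trace(s); their correlations set to 0", sum(const))
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Threshold a correlation matrix into a binary functional graph
#'
#' An edge is assigned between i and j iff their correlation strictly
#' exceeds `threshold` (one-sided: strong negative correlations are not
#' edges). The result is an undirected, unweighted [functional_graph()].
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param threshold correlation threshold in `(-1, 1)`; default 0.3. The
#'   threshold is a free analysis parameter — see [threshold_sweep()] for a
#'   sensitivity sweep.
#' @param stage optional stage label carried into the graph.
#' @return A [functional_graph()].
#' @export
binarize <- function(corr, threshold = 0.3, stage = NA_character_) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || any(abs(corr - t(corr)) > 1e-12))
    stopf("corr must be a symmetric square matrix")
  if (threshold <= -1 || threshold >= 1) stopf("threshold must be in (-1, 1)")
  adj <- (corr > threshold) * 1
  diag(adj) <- 0
  adj <- pmax(adj, t(adj))  # guard exact-representation asymmetries
  functional_graph(adj, node_ids = rownames(corr), stage = stage,
                   threshold = threshold)
}

#' Build the three stage graphs of a session
#'
#' Slices a session's dF/F matrix into its H, SB and SN stage windows
#' (half-open frame intervals, so each frame belongs to exactly one stage),
#' correlates and thresholds each stage independently, and returns three
#' graphs over the identical, identically ordered neuron set.
#'
#' @param ts a [trace_set()].
#' @param threshold correlation threshold passed to [binarize()].
#' @return Named list of three [functional_graph()]s (`H`, `SB`, `SN`).
#' @export
build_session_graphs <- function(ts, threshold = 0.3) {
  stopifnot(inherits(ts, "trace_set"))
  out <- lapply(ts$stages$label, function(st) {
    binarize(correlation_matrix(stage_frames(ts, st)), threshold, stage = st)
  })
  names(out) <- ts$stages$label
  out[c("H", "SB", "SN")]
}

#' Edge-count sensitivity sweep over correlation thresholds
#'
#' Rebuilds one stage graph across a grid of thresholds, reporting edge
#' counts and topological indices, to check how conclusions depend on the
#' (free) binarization threshold. Edge sets shrink monotonically as the
#' threshold rises.
#'
#' @param dff_stage neurons x frames matrix for one stage.
#' @param thresholds numeric grid in `(-1, 1)`.
#' @return data.frame with one row per threshold: `threshold`, `n_edges`,
#'   `L_g`, `C_l`, `C_g`.
#' @export
threshold_sweep <- function(dff_stage, thresholds = seq(0.1, 0.6, by = 0.05)) {
  cc <- correlation_matrix(dff_stage)
  out <- lapply(thresholds, function(th) {
    g <- binarize(cc, th)
    gi <- suppressWarnings(graph_indices(g))
    cbind(data.frame(threshold = th), gi[c("n_edges", "L_g", "C_l", "C_g")])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Edge-recovery score against a ground-truth network
#'
#' Edge-wise precision, recall and F1 of an estimated graph against a known
#' generating adjacency — the quantitative check that thresholded
#' correlation graphs built from simulated traces recover the simulated
#' network.
#'
#' @param estimated,truth `functional_graph`s or adjacency matrices on the
#'   same node set.
#' @return data.frame with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
edge_recovery <- function(estimated, truth) {
  a <- as_adjacency(estimated)
  b <- as_adjacency(truth)
  if (!all(dim(a) == dim(b))) stopf("graphs must share a node set")
  ut <- upper.tri(a)
  tp <- sum(a[ut] == 1 & b[ut] == 1)
  fp <- sum(a[ut] == 1 & b[ut] == 0)
  fn <- sum(a[ut] == 0 & b[ut] == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             recall = recall, f1 = f1)
}
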