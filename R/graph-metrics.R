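#' Topological indices of a functional-connectivity graph
#'
#' Computes the characteristic (average shortest) path length, the mean
#' local clustering coefficient, and the global clustering coefficient
#' (transitivity) of a binary undirected graph.
#'
#' Thresholded correlation graphs are frequently disconnected. The path
#' length here averages shortest-path distances over the *reachable*
#' ordered pairs only, and the number of reachable pairs is reported
#' alongside so that averages over graphs of different connectedness can
#' be interpreted. Set `largest_component = TRUE` to restrict the average
#' to the largest connected component instead.
#'
#' @param g a `functional_graph` or binary adjacency matrix.
#' @param largest_component restrict the path-length average to the largest
#'   connected component (default `FALSE`: average over all reachable pairs).
#' @return A one-row `data.frame` with columns `L_g`, `C_l`, `C_g`,
#'   `n_nodes`, `n_edges`, `n_reachable_pairs`.
#' @seealso [shortest_path_length()], [mean_local_clustering()],
#'   [global_clustering()]
#' @export
graph_indices <- function(g, largest_component = FALSE) {
  adj <- as_adjacency(g)
  sp <- shortest_path_length(g, largest_component = largest_component)
  data.frame(
    L_g = sp$L_g,
    C_l = mean_local_clustering(g),
    C_g = global_clustering(g),
    n_nodes = nrow(adj),
    n_edges = as.integer(sum(adj) / 2),
    n_reachable_pairs = sp$n_reachable_pairs
  )
}

## All-pairs BFS distances on a binary adjacency matrix; Inf = unreachable.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  d <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    frontier <- src
    level <- 0
    while (length(frontier)) {
      level <- level + 1
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- level
      frontier <- nxt
    }
    d[src, ] <- dist
  }
  d
}

## Connected-component labels via repeated BFS.
component_labels <- function(adj) {
  d <- bfs_distances(adj)
  lab <- integer(nrow(adj))
  comp <- 0L
  for (i in seq_len(nrow(adj))) {
    if (lab[i] == 0L) {
      comp <- comp + 1L
      lab[is.finite(d[i, ])] <- comp
    }
  }
  lab
}

#' Characteristic path length
#'
#' Average shortest-path distance `L_g` over ordered node pairs (i, j),
#' i != j, computed by breadth-first search. Unreachable pairs are excluded
#' from the average; their number is `n_nodes*(n_nodes-1) -
#' n_reachable_pairs`.
#'
#' @inheritParams graph_indices
#' @return A list with `L_g` (NA with a warning when the graph has no
#'   edges) and `n_reachable_pairs`.
#' @examples
#' k6 <- functional_graph(1 - diag(6))
#' shortest_path_length(k6)$L_g   # 1.0
#' @export
shortest_path_length <- function(g, largest_component = FALSE) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  if (n < 2) stopf("shortest_path_length needs at least 2 nodes")
  if (sum(adj) == 0) {
    warnf("graph has no edges; L_g is undefined")
    return(list(L_g = NA_real_, n_reachable_pairs = 0L))
  }
  d <- bfs_distances(adj)
  if (largest_component) {
    lab <- component_labels(adj)
    keep <- lab == which.max(tabulate(lab))
    d <- d[keep, keep, drop = FALSE]
  }
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  list(L_g = mean(off[reach]), n_reachable_pairs = sum(reach))
}

#' Local clustering coefficient of one node
#'
#' Fraction of a node's neighbor pairs that are themselves connected:
#' `C_v = edges among neighbors / (deg * (deg - 1) / 2)`, defined as 0
#' for nodes of degree < 2.
#'
#' @inheritParams graph_indices
#' @param node node index (1-based) or node id.
#' @return Scalar in `[0, 1]`.
#' @export
local_clustering <- function(g, node) {
  adj <- as_adjacency(g)
  if (is.character(node)) node <- match(node, rownames(adj))
  if (is.na(node) || node < 1 || node > nrow(adj)) stopf("unknown node")
  nb <- which(adj[node, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  sum(adj[nb, nb]) / 2 / (k * (k - 1) / 2)
}

#' Mean local clustering coefficient
#'
#' Unweighted mean of [local_clustering()] over all nodes (`C_l`).
#'
#' @inheritParams graph_indices
#' @return Scalar in `[0, 1]`.
#' @export
mean_local_clustering <- function(g) {
  adj <- as_adjacency(g)
  mean(vapply(seq_len(nrow(adj)), function(v) local_clustering(adj, v),
              numeric(1)))
}

#' Global clustering coefficient (transitivity)
#'
#' `C_g = 3 * (number of triangles) / (number of connected triplets)`,
#' computed from powers of the adjacency matrix; 0 when the graph has no
#' connected triplets.
#'
#' @inheritParams graph_indices
#' @return Scalar in `[0, 1]`.
#' @export
global_clustering <- function(g) {
  adj <- as_adjacency(g)
  deg <- rowSums(adj)
  open_plus_closed <- sum(deg * (deg - 1))          # ordered paths of length 2
  if (open_plus_closed == 0) return(0)
  closed <- sum(diag(adj %*% adj %*% adj))          # 6 * number of triangles
  closed / open_plus_closed
}

#' Laplacian spectrum
#'
#' Eigenvalues of the graph Laplacian `L = D - A` (degree matrix minus
#' adjacency), sorted ascending. For an undirected graph L is symmetric
#' positive semidefinite, so the spectrum is real and nonnegative with the
#' smallest eigenvalue 0; tiny negative values from floating point are
#' clipped to 0 (tolerance 1e-10).
#'
#' @inheritParams graph_indices
#' @return Numeric vector of `n_nodes` eigenvalues, nondecreasing.
#' @export
laplacian_spectrum <- function(g) {
  adj <- as_adjacency(g)
  lap <- diag(rowSums(adj)) - adj
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev)
  ev[ev < 0 & ev > -1e-10] <- 0
  ev
}

#' Spectral distance between two graphs on the same node set
#'
#' Euclidean distance between the two sorted Laplacian spectra, normalized
#' by the square root of the number of nodes:
#' `s = sqrt( sum_i (lambda_i - omega_i)^2 / N )`.
#' It quantifies global reconfiguration of network topology between, e.g.,
#' two behavioral stages recorded over the same neurons. With
#' `exclude_zero_mode = TRUE` the smallest eigenvalue of each spectrum is
#' dropped and N is replaced by N - 1 (the variant used in some graphical
#' illustrations); the default includes all N eigenvalues.
#'
#' @param g1,g2 `functional_graph`s or adjacency matrices with the same
#'   number of nodes.
#' @param exclude_zero_mode drop the smallest (zero) eigenvalue of each
#'   spectrum before differencing.
#' @return Nonnegative scalar; 0 iff the two spectra coincide.
#' @examples
#' ring <- ring_lattice(6, 2)
#' spectral_distance(ring, ring)  # 0
#' @export
spectral_distance <- function(g1, g2, exclude_zero_mode = FALSE) {
  s1 <- laplacian_spectrum(g1)
  s2 <- laplacian_spectrum(g2)
  if (length(s1) != length(s2))
    stopf("spectral_distance requires graphs with the same node count (%d vs %d)",
          length(s1), length(s2))
  if (exclude_zero_mode) {
    s1 <- s1[-1]
    s2 <- s2[-1]
  }
  sqrt(sum((s1 - s2)^2) / length(s1))
}

#' Hub neurons by degree-tail rank statistic
#'
#' For each node i with degree d_i, the rank-based p-value is the fraction
#' of nodes (including i itself) whose degree is at least d_i:
#' `p_i = (1/N) * sum_j I(d_j >= d_i)`. Nodes with `p_i <= alpha` are
#' classified as hubs — approximately the upper `alpha` tail of the
#' within-network degree distribution. Because a node counts itself,
#' `p_i >= 1/N`, and ties make the rule conservative: at most `alpha * N`
#' hubs are ever declared.
#'
#' @inheritParams graph_indices
#' @param alpha tail probability cutoff (default 0.05).
#' @return A list with `degrees`, `p_values` (both named by node) and
#'   `hubs` (character vector of hub node ids).
#' @export
hub_report <- function(g, alpha = 0.05) {
  adj <- as_adjacency(g)
  deg <- rowSums(adj)
  n <- length(deg)
  p <- vapply(deg, function(d) sum(deg >= d) / n, numeric(1))
  ids <- rownames(adj) %||% as.character(seq_len(n))
  names(p) <- ids
  names(deg) <- ids
  list(degrees = deg, p_values = p, hubs = ids[p <= alpha])
}
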