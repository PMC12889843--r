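#' Ring lattice adjacency
#'
#' Regular ring on `n_nodes` nodes where each node is connected to its
#' `mean_degree / 2` nearest neighbors on each side; the deterministic
#' backbone of the small-world generator.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param mean_degree even node degree, `< n_nodes`.
#' @return Binary symmetric adjacency matrix with `n_nodes * mean_degree / 2`
#'   edges.
#' @export
ring_lattice <- function(n_nodes, mean_degree) {
  if (!is_count(n_nodes) || n_nodes < 3) stopf("n_nodes must be a count >= 3")
  if (!is_count(mean_degree) || mean_degree %% 2 != 0 ||
      mean_degree >= n_nodes)
    stopf("mean_degree must be even and < n_nodes")
  adj <- matrix(0, n_nodes, n_nodes)
  for (j in seq_len(mean_degree / 2)) {
    idx <- cbind(seq_len(n_nodes), (seq_len(n_nodes) + j - 1) %% n_nodes + 1)
    adj[idx] <- 1
    adj[idx[, 2:1]] <- 1
  }
  adj
}

#' Small-world stage network (Watts-Strogatz)
#'
#' Starts from a ring lattice and rewires each edge independently with
#' probability `rewire_p` to a uniformly chosen new endpoint, avoiding
#' self-loops and duplicate edges, so the edge count
#' `n_nodes * mean_degree / 2` is preserved exactly. `rewire_p = 0` returns
#' the deterministic ring lattice; `rewire_p = 1` approaches a random graph.
#'
#' @inheritParams ring_lattice
#' @param rewire_p per-edge rewiring probability in `[0, 1]`.
#' @param seed integer seed; the output is a pure function of the arguments.
#' @return Binary symmetric adjacency matrix, zero diagonal.
#' @export
generate_stage_network <- function(n_nodes, mean_degree, rewire_p, seed) {
  if (!is_prob(rewire_p)) stopf("rewire_p must be in [0, 1]")
  adj <- ring_lattice(n_nodes, mean_degree)
  if (rewire_p == 0) return(adj)
  withr::with_seed(seed, {
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(mean_degree / 2)) {
        tgt <- (i + j - 1) %% n_nodes + 1
        if (adj[i, tgt] == 1 && stats::runif(1) < rewire_p) {
          free <- which(adj[i, ] == 0)
          free <- setdiff(free, i)
          if (length(free)) {
            new <- free[sample.int(length(free), 1)]
            adj[i, tgt] <- adj[tgt, i] <- 0
            adj[i, new] <- adj[new, i] <- 1
          }
        }
      }
    }
  })
  adj
}

## Ordered list of edges (i < j) of an adjacency matrix.
edge_list <- function(adj) {
  which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
}

#' Rewire a fraction of edges for the next behavioral stage
#'
#' Models stage-to-stage reconfiguration of a microcircuit: exactly
#' `round(fraction * |E|)` randomly chosen edges are removed and the same
#' number of new edges are added among the current non-edges. Node set and
#' edge count are preserved; degrees generally are not. By default
#' (`local = TRUE`) new edges are drawn from non-edges that share at least
#' one common neighbor in the base graph (circuit remodeling is
#' neighborhood-biased), falling back to uniform non-edges when those run
#' out; `local = FALSE` samples all non-edges uniformly.
#'
#' @param base binary symmetric adjacency matrix.
#' @param fraction fraction of edges to rewire, in `[0, 1]`.
#' @param seed integer seed.
#' @param local prefer new edges within existing neighborhoods.
#' @return Adjacency matrix of the same dimension and edge count.
#' @export
rewire_for_stage <- function(base, fraction, seed, local = TRUE) {
  base <- as_adjacency(base)
  if (!is_prob(fraction)) stopf("fraction must be in [0, 1]")
  edges <- edge_list(base)
  m <- round(fraction * nrow(edges))
  if (m == 0) return(base)
  non_edges <- which(upper.tri(base) & base == 0, arr.ind = TRUE)
  if (m > nrow(non_edges))
    stopf("cannot add %d edges: only %d non-edges available", m,
          nrow(non_edges))
  withr::with_seed(seed, {
    drop <- edges[sample.int(nrow(edges), m), , drop = FALSE]
    if (local) {
      b2 <- base %*% base               # common-neighbor counts
      shared <- b2[non_edges] > 0
      loc <- non_edges[shared, , drop = FALSE]
      oth <- non_edges[!shared, , drop = FALSE]
      if (nrow(loc) >= m) {
        add <- loc[sample.int(nrow(loc), m), , drop = FALSE]
      } else {                          # exhaust local pool, fill uniformly
        add <- rbind(loc, oth[sample.int(nrow(oth), m - nrow(loc)), ,
                              drop = FALSE])
      }
    } else {
      add <- non_edges[sample.int(nrow(non_edges), m), , drop = FALSE]
    }
  })
  adj <- base
  adj[drop] <- 0
  adj[drop[, 2:1, drop = FALSE]] <- 0
  adj[add] <- 1
  adj[add[, 2:1, drop = FALSE]] <- 1
  adj
}

#' Simulate calcium dF/F traces from a ground-truth network
#'
#' Each neuron fires its own Poisson event train; whenever neuron i fires,
#' the event is copied, independently with probability `coupling`, onto
#' each of i's graph neighbors in the same frame. Every source event
#' carries an exponentially distributed amplitude (mean `event_amp` dF/F)
#' that its copies inherit — transient sizes vary burst to burst, and the
#' trace maximum is set by the amplitude tail rather than by the firing
#' rate, so max-normalized activity summaries stay monotone in the rate.
#' Event trains are convolved with a single-exponential calcium kernel
#' `exp(-t / kernel_decay_s)`, Gaussian noise is added, and the traces are
#' clipped at zero to give nonnegative dF/F-like values. Functional
#' connectivity estimated from these traces by [correlation_matrix()] +
#' [binarize()] recovers the generating adjacency when coupling is high
#' and noise moderate.
#'
#' @param adjacency binary symmetric ground-truth adjacency.
#' @param rate_hz mean per-neuron event rate (events/s), > 0 (0 allowed and
#'   yields event-free traces).
#' @param duration_s recording duration in seconds.
#' @param frame_rate_hz sampling rate (frames/s); `duration_s *
#'   frame_rate_hz` must be a whole number >= 2.
#' @param kernel_decay_s calcium-transient decay constant in seconds.
#' @param noise_sd additive Gaussian noise SD, dF/F units.
#' @param coupling probability that a neighbor inherits an event.
#' @param seed integer seed.
#' @param event_amp mean dF/F amplitude of a single event (default 0.08;
#'   GCaMP6f-like).
#' @return Matrix of shape `(n_nodes, duration_s * frame_rate_hz)`,
#'   nonnegative and finite.
#' @export
simulate_traces <- function(adjacency, rate_hz, duration_s, frame_rate_hz,
                            kernel_decay_s = 0.3, noise_sd = 0.05,
                            coupling = 0.9, seed = 1, event_amp = 0.08) {
  adj <- as_adjacency(adjacency)
  n <- nrow(adj)
  n_frames <- duration_s * frame_rate_hz
  if (!isTRUE(all.equal(n_frames, round(n_frames))) || n_frames < 2)
    stopf("duration_s * frame_rate_hz must be a whole number >= 2")
  n_frames <- as.integer(round(n_frames))
  if (rate_hz < 0) stopf("rate_hz must be >= 0")
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  withr::with_seed(seed, {
    events <- matrix(stats::rpois(n * n_frames, rate_hz / frame_rate_hz),
                     n, n_frames)
    ## per source event: exponential amplitude, inherited by copies (shared
    ## amplitudes preserve the pairwise correlation structure exactly)
    amps <- matrix(0, n, n_frames)
    nz <- events > 0
    amps[nz] <- events[nz] * stats::rexp(sum(nz), rate = 1 / event_amp)
    if (coupling > 0 && any(adj > 0)) {
      received <- matrix(0, n, n_frames)
      for (i in seq_len(n)) {
        t_i <- which(events[i, ] > 0)
        k <- length(nbrs[[i]])
        if (length(t_i) == 0L || k == 0L) next
        keep <- matrix(stats::runif(k * length(t_i)) < coupling, k)
        contrib <- keep * rep(amps[i, t_i], each = k)
        received[nbrs[[i]], t_i] <- received[nbrs[[i]], t_i] + contrib
      }
      trains <- amps + received
    } else {
      trains <- amps
    }
    a <- exp(-1 / (frame_rate_hz * kernel_decay_s))
    dff <- t(apply(trains, 1, function(x)
      as.numeric(stats::filter(x, a, method = "recursive"))))
    if (noise_sd > 0)
      dff <- dff + matrix(stats::rnorm(n * n_frames, 0, noise_sd), n, n_frames)
  })
  ## clip at zero: nonnegative dF/F-like output
  pmax(dff, 0)
}

#' Synthetic-cohort configuration
#'
#' Bundles and validates every knob of the cohort generator. The defaults
#' emulate a repeated three-stage social-behavior imaging study: two
#' genotypes ("WT" and "KO", 11 and 9 mice), five weekly sessions per
#' mouse, three 10-minute stages (habituation H, sociability SB, social
#' novelty SN) sampled at 10 frames/s, with the affected genotype showing
#' lower event rates, a more lattice-like (less integrated) network,
#' weaker cross-stage rewiring and lower behavioral preference scores.
#' The event amplitude (0.15 dF/F), kernel decay (0.3 s) and noise SD
#' (0.05) are calibrated so that, at the default 0.3 correlation
#' threshold, direct-edge correlations sit clearly above threshold and
#' common-neighbor (distance-2) correlations below it, making ground-truth
#' edge recovery the generator's operating guarantee.
#'
#' @param n_mice_per_genotype length-2 integer vector: mice in genotype A
#'   and genotype B.
#' @param genotype_labels length-2 character vector of distinct labels.
#' @param n_sessions sessions per mouse.
#' @param stage_duration_s duration of each stage, seconds.
#' @param frame_rate_hz sampling rate, frames/s.
#' @param n_neurons_range inclusive range from which each mouse's neuron
#'   count is drawn.
#' @param topology named list (one entry per genotype) of
#'   `list(mean_degree =, rewire_p =)` small-world parameters.
#' @param cross_stage_rewire_frac named numeric vector (per genotype):
#'   fraction of edges rewired between consecutive stages.
#' @param activity_rate_hz named numeric vector (per genotype): mean event
#'   rate.
#' @param kernel_decay_s calcium kernel decay constant, seconds.
#' @param noise_sd additive noise SD, dF/F units.
#' @param coupling event-copy probability along true edges.
#' @param event_amp single-event dF/F amplitude.
#' @param behavior_effect named list (per genotype) of `list(mean =, sd =)`
#'   for the preference percentages S1 and S2.
#' @param seed integer master seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_mice_per_genotype = c(11, 9),
                          genotype_labels = c("WT", "KO"),
                          n_sessions = 5,
                          stage_duration_s = 600,
                          frame_rate_hz = 10,
                          n_neurons_range = c(60, 90),
                          topology = list(
                            WT = list(mean_degree = 4, rewire_p = 0.10),
                            KO = list(mean_degree = 4, rewire_p = 0.05)),
                          cross_stage_rewire_frac = c(WT = 0.15, KO = 0.06),
                          activity_rate_hz = c(WT = 0.5, KO = 0.3),
                          kernel_decay_s = 0.3,
                          noise_sd = 0.05,
                          coupling = 0.9,
                          event_amp = 0.08,
                          behavior_effect = list(
                            WT = list(mean = 65, sd = 8),
                            KO = list(mean = 45, sd = 8)),
                          seed = 1L) {
  if (length(n_mice_per_genotype) != 2 ||
      !all(vapply(n_mice_per_genotype, is_count, logical(1))))
    stopf("n_mice_per_genotype must be two counts >= 1")
  if (length(genotype_labels) != 2 ||
      anyDuplicated(genotype_labels))
    stopf("genotype_labels must be exactly two distinct values")
  if (!is_count(n_sessions)) stopf("n_sessions must be a count >= 1")
  if (stage_duration_s <= 0 || frame_rate_hz <= 0)
    stopf("durations and rates must be positive")
  if (length(n_neurons_range) != 2 ||
      n_neurons_range[1] > n_neurons_range[2] || n_neurons_range[1] < 3)
    stopf("n_neurons_range must be an increasing range with min >= 3")
  for (gl in genotype_labels) {
    if (is.null(topology[[gl]]))
      stopf("topology must have an entry for genotype '%s'", gl)
    if (!is_prob(unname(cross_stage_rewire_frac[gl])))
      stopf("cross_stage_rewire_frac['%s'] must be in [0, 1]", gl)
    if (is.na(activity_rate_hz[gl]) || activity_rate_hz[gl] < 0)
      stopf("activity_rate_hz['%s'] must be >= 0", gl)
    if (is.null(behavior_effect[[gl]]))
      stopf("behavior_effect must have an entry for genotype '%s'", gl)
  }
  if (noise_sd < 0 || kernel_decay_s <= 0 || !is_prob(coupling))
    stopf("invalid noise/kernel/coupling parameters")
  structure(
    list(n_mice_per_genotype = as.integer(n_mice_per_genotype),
         genotype_labels = genotype_labels,
         n_sessions = as.integer(n_sessions),
         stage_duration_s = stage_duration_s,
         frame_rate_hz = frame_rate_hz,
         n_neurons_range = as.integer(n_neurons_range),
         topology = topology,
         cross_stage_rewire_frac = cross_stage_rewire_frac,
         activity_rate_hz = activity_rate_hz,
         kernel_decay_s = kernel_decay_s,
         noise_sd = noise_sd,
         coupling = coupling,
         event_amp = event_amp,
         behavior_effect = behavior_effect,
         seed = as.integer(seed)),
    class = "cohort_config")
}

stage_labels <- c("H", "SB", "SN")

#' Generate a synthetic imaging cohort
#'
#' Produces, for every mouse-session, a [trace_set()] whose three stage
#' blocks are driven by ground-truth small-world networks (the habituation
#' network per session is the baseline; the SB and SN networks are each
#' obtained from it by partial rewiring, modeling stage-dependent
#' reconfiguration relative to the no-social-target condition),
#' plus a behavior table of exploration percentages and the full ground
#' truth for recovery testing. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort` with elements:
#'   \describe{
#'     \item{traces}{list of `trace_set`s, one per mouse-session, named
#'       `"<mouse>_s<session>"`.}
#'     \item{behavior}{data.frame with `mouse_id`, `genotype`, `session`,
#'       `S1_percent`, `S2_percent`.}
#'     \item{ground_truth}{list with per-mouse genotypes and, per
#'       mouse-session, the three true stage adjacencies.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gl <- config$genotype_labels
  mice <- data.frame(
    mouse_id = c(sprintf("%s%02d", gl[1], seq_len(config$n_mice_per_genotype[1])),
                 sprintf("%s%02d", gl[2], seq_len(config$n_mice_per_genotype[2]))),
    genotype = rep(gl, config$n_mice_per_genotype),
    stringsAsFactors = FALSE)
  n_neurons <- withr::with_seed(child_seed(config$seed, 1), {
    sample(seq(config$n_neurons_range[1], config$n_neurons_range[2]),
           nrow(mice), replace = TRUE)
  })
  ## mean_degree must be even and < n_nodes
  traces <- list()
  gt_adj <- list()
  behavior <- list()
  stream <- 100
  for (m in seq_len(nrow(mice))) {
    g <- mice$genotype[m]
    topo <- config$topology[[g]]
    n_nrn <- n_neurons[m]
    for (s in seq_len(config$n_sessions)) {
      stream <- stream + 1
      base_seed <- child_seed(config$seed, stream)
      adj_h <- generate_stage_network(n_nrn, topo$mean_degree, topo$rewire_p,
                                      seed = base_seed)
      frac <- unname(config$cross_stage_rewire_frac[g])
      adj_sb <- rewire_for_stage(adj_h, frac, seed = child_seed(base_seed, 2))
      adj_sn <- rewire_for_stage(adj_h, frac, seed = child_seed(base_seed, 3))
      stage_adj <- list(H = adj_h, SB = adj_sb, SN = adj_sn)
      blocks <- lapply(seq_along(stage_labels), function(k) {
        simulate_traces(stage_adj[[k]],
                        rate_hz = unname(config$activity_rate_hz[g]),
                        duration_s = config$stage_duration_s,
                        frame_rate_hz = config$frame_rate_hz,
                        kernel_decay_s = config$kernel_decay_s,
                        noise_sd = config$noise_sd,
                        coupling = config$coupling,
                        seed = child_seed(base_seed, 10 + k),
                        event_amp = config$event_amp)
      })
      dff <- do.call(cbind, blocks)
      frames_per_stage <- ncol(blocks[[1]])
      stages <- data.frame(
        label = stage_labels,
        start = (seq_along(stage_labels) - 1) * frames_per_stage,
        end = seq_along(stage_labels) * frames_per_stage,
        stringsAsFactors = FALSE)
      key <- sprintf("%s_s%d", mice$mouse_id[m], s)
      traces[[key]] <- trace_set(dff, config$frame_rate_hz, stages,
                                 mouse_id = mice$mouse_id[m], genotype = g,
                                 session_index = s)
      gt_adj[[key]] <- stage_adj
      be <- config$behavior_effect[[g]]
      sc <- withr::with_seed(child_seed(base_seed, 20), {
        pmin(100, pmax(0, stats::rnorm(2, be$mean, be$sd)))
      })
      behavior[[key]] <- data.frame(
        mouse_id = mice$mouse_id[m], genotype = g, session = s,
        S1_percent = sc[1], S2_percent = sc[2], stringsAsFactors = FALSE)
    }
  }
  structure(
    list(traces = traces,
         behavior = do.call(rbind, c(behavior, list(make.row.names = FALSE))),
         ground_truth = list(mice = mice, adjacency = gt_adj),
         config = config),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d mice (%s), %d sessions, %d trace sets\n",
              nrow(x$ground_truth$mice),
              paste(table(x$ground_truth$mice$genotype), collapse = " + "),
              x$config$n_sessions, length(x$traces)))
  invisible(x)
}
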