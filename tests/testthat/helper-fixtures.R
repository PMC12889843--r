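# Shared fixtures, built in code and memoised so expensive cohorts are
# generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Desk-scale cohort with the default (strong) genotype effects: 5 + 5 mice,
# 5 sessions, 60 s stages, ~32 neurons.
small_cohort_config <- function(seed = 2024, ...) {
  cohort_config(n_mice_per_genotype = c(5, 5), n_sessions = 5,
                stage_duration_s = 60, n_neurons_range = c(30, 36),
                seed = seed, ...)
}

small_cohort <- function() {
  memoise_fixture("small_cohort", function() {
    generate_cohort(small_cohort_config())
  })
}

small_features <- function() {
  memoise_fixture("small_features", function() {
    session_features(small_cohort(), threshold = 0.3)
  })
}

small_preprocessed <- function() {
  memoise_fixture("small_preprocessed", function() {
    preprocess_features(small_features()$features)
  })
}

# Tiny named graphs used across graph-metric tests.
k_complete <- function(n) functional_graph(1 - diag(n))
ring6 <- function() functional_graph(ring_lattice(6, 2))
path3 <- function() {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1
  functional_graph(adj)
}
star_graph <- function(n) {
  adj <- matrix(0, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1
  functional_graph(adj)
}

random_adjacency <- function(n, p = 0.35) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

# Independent Floyd-Warshall oracle for average shortest path length.
floyd_warshall_lg <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  off <- d[row(d) != col(d)]
  if (!any(is.finite(off))) return(NA_real_)
  mean(off[is.finite(off)])
}

# Exhaustive triplet enumeration oracle for transitivity.
triplet_transitivity <- function(adj) {
  n <- nrow(adj)
  closed <- 0; connected <- 0
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    prs <- utils::combn(nb, 2)
    for (c_ in seq_len(ncol(prs))) {
      connected <- connected + 1
      if (adj[prs[1, c_], prs[2, c_]] == 1) closed <- closed + 1
    }
  }
  if (connected == 0) return(0)
  closed / connected
}
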