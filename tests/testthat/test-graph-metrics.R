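test_that("toy six-node networks reproduce the worked path-length and clustering values", {
  k6 <- k_complete(6)
  ring <- ring6()
  expect_equal(shortest_path_length(k6)$L_g, 1.0)
  expect_equal(shortest_path_length(ring)$L_g, 1.8)
  expect_equal(local_clustering(k6, 1), 1.0)
  expect_equal(local_clustering(ring, 1), 0)
  expect_equal(global_clustering(k6), 1.0)
  expect_equal(global_clustering(ring), 0)
  expect_equal(mean_local_clustering(k6), 1.0)
})

test_that("path graph and disconnected graphs average over reachable pairs", {
  expect_equal(shortest_path_length(path3())$L_g, 4 / 3)
  # two disjoint edges on 4 nodes: reachable ordered pairs = 4, all distance 1
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[3, 4] <- adj[4, 3] <- 1
  sp <- shortest_path_length(adj)
  expect_equal(sp$L_g, 1)
  expect_equal(sp$n_reachable_pairs, 4L)
  expect_warning(sp0 <- shortest_path_length(matrix(0, 3, 3)), "no edges")
  expect_true(is.na(sp0$L_g))
})

test_that("Laplacian spectra match closed forms", {
  expect_equal(laplacian_spectrum(k_complete(2)), c(0, 2))
  expect_equal(laplacian_spectrum(matrix(0, 5, 5)), rep(0, 5))
  expect_equal(laplacian_spectrum(k_complete(3)), c(0, 3, 3))
  # trace identity on the 6-ring: sum of eigenvalues = 2|E|
  expect_equal(sum(laplacian_spectrum(ring6())), 12)
})

test_that("spectral distance matches hand-computed values and its contract", {
  g <- functional_graph(random_adjacency(7))
  expect_equal(spectral_distance(g, g), 0)
  expect_equal(spectral_distance(k_complete(2), matrix(0, 2, 2)), sqrt(2))
  expect_equal(spectral_distance(k_complete(3), path3()), 2 / sqrt(3),
               tolerance = 1e-12)
  expect_error(spectral_distance(k_complete(3), k_complete(4)), "node count")
  # zero-mode exclusion drops one eigenvalue and renormalizes
  s_all <- spectral_distance(k_complete(3), path3())
  s_nz <- spectral_distance(k_complete(3), path3(), exclude_zero_mode = TRUE)
  expect_equal(s_nz, sqrt((0^2 + (3 - 1)^2 + 0^2) / 2))
  expect_false(isTRUE(all.equal(s_all, s_nz)))
})

test_that("spectral distance is a pseudometric on same-size graphs", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      g1 <- random_adjacency(8)
      g2 <- random_adjacency(8)
      g3 <- random_adjacency(8)
      s12 <- spectral_distance(g1, g2)
      s13 <- spectral_distance(g1, g3)
      s23 <- spectral_distance(g2, g3)
      expect_gte(s12, 0)
      expect_equal(s12, spectral_distance(g2, g1))
      expect_lte(s13, s12 + s23 + 1e-12)
    }
  })
})

test_that("indices and spectra are invariant under node relabeling", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      adj <- random_adjacency(9)
      perm <- sample(9)
      padj <- adj[perm, perm]
      expect_equal(shortest_path_length(adj)$L_g,
                   shortest_path_length(padj)$L_g)
      expect_equal(mean_local_clustering(adj), mean_local_clustering(padj))
      expect_equal(global_clustering(adj), global_clustering(padj))
      expect_equal(laplacian_spectrum(adj), laplacian_spectrum(padj),
                   tolerance = 1e-9)
      expect_equal(spectral_distance(adj, padj), 0, tolerance = 1e-7)
    }
  })
})

test_that("metrics agree with independent oracles on random graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(31, {
    for (rep in 1:60) {
      n <- sample(4:12, 1)
      adj <- random_adjacency(n, p = stats::runif(1, 0.2, 0.7))
      ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      lg <- suppressWarnings(shortest_path_length(adj)$L_g)
      expect_equal(lg, floyd_warshall_lg(adj), tolerance = 1e-8)
      if (sum(adj) > 0) {
        expect_equal(lg, igraph::mean_distance(ig, unconnected = TRUE),
                     tolerance = 1e-8)
      }
      expect_equal(global_clustering(adj), triplet_transitivity(adj),
                   tolerance = 1e-8)
      tg <- igraph::transitivity(ig, type = "global")
      if (!is.nan(tg)) expect_equal(global_clustering(adj), tg,
                                    tolerance = 1e-8)
      expect_equal(sum(laplacian_spectrum(adj)), sum(adj), tolerance = 1e-8)
      cl_ig <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
      expect_equal(mean_local_clustering(adj), mean(cl_ig), tolerance = 1e-8)
    }
  })
})

test_that("hub identification follows the degree-tail rank rule", {
  # any regular graph: every node ties, p = 1, no hubs
  hr <- hub_report(ring6())
  expect_true(all(hr$p_values == 1))
  expect_length(hr$hubs, 0)
  # star on 20 nodes: center has p = 1/20 = 0.05, exactly one hub
  hr <- hub_report(star_graph(20), alpha = 0.05)
  expect_equal(unname(hr$p_values[1]), 0.05)
  expect_equal(hr$hubs, "n1")
  # N = 10: minimum possible p is 0.1 > 0.05, never a hub
  hr <- hub_report(star_graph(10), alpha = 0.05)
  expect_length(hr$hubs, 0)
})

test_that("hub count never exceeds the alpha fraction of nodes", {
  withr::with_seed(41, {
    for (rep in 1:40) {
      n <- sample(5:30, 1)
      hr <- hub_report(random_adjacency(n, stats::runif(1, 0.1, 0.8)),
                       alpha = 0.05)
      expect_lte(length(hr$hubs), 0.05 * n)
      expect_true(all(hr$p_values >= 1 / n))
    }
  })
})
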