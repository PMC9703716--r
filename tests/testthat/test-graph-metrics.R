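test_that("canonical graphs give the textbook metric values", {
  K3 <- complete_graph(3); K4 <- complete_graph(4)
  P3 <- path_graph(3); S5 <- star_graph(5)
  expect_equal(nodal_clustering(K3), rep(1, 3))
  expect_equal(mean_clustering(K3), 1)
  expect_equal(mean_clustering(P3), 0)
  expect_equal(characteristic_path_length(K4), 1)
  expect_equal(characteristic_path_length(P3), 4 / 3)
  expect_equal(global_efficiency(K4), 1)
  expect_equal(global_efficiency(P3), 5 / 6)
  expect_equal(graph_transitivity(K3), 1)
  expect_equal(graph_transitivity(S5), 0)
  expect_equal(nodal_betweenness(S5), c(1, 0, 0, 0, 0))
  expect_equal(nodal_betweenness(P3), c(0, 1, 0))
  # star centre's neighbours form an edgeless subgraph
  expect_equal(local_efficiency(S5)[1], 0)
  expect_equal(local_efficiency(K4), rep(1, 4))
})

test_that("metrics match exhaustive oracles on random small graphs", {
  set.seed(20)
  for (rep in 1:100) {
    A <- random_connected_graph(sample(4:8, 1), runif(1, 0.3, 0.9))
    expect_equal(nodal_clustering(A), oracle_clustering(A), tolerance = 1e-12)
    expect_equal(graph_transitivity(A), oracle_transitivity(A),
                 tolerance = 1e-12)
    expect_equal(characteristic_path_length(A), oracle_path_length(A),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(A), oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(nodal_betweenness(A), oracle_betweenness(A),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling and obey handshake", {
  set.seed(21)
  for (rep in 1:10) {
    A <- random_connected_graph(8, 0.5)
    perm <- sample(8)
    B <- A[perm, perm]
    expect_equal(sum(nodal_degree(A)), sum(A))
    expect_equal(mean_clustering(B), mean_clustering(A), tolerance = 1e-12)
    expect_equal(graph_transitivity(B), graph_transitivity(A),
                 tolerance = 1e-12)
    expect_equal(characteristic_path_length(B),
                 characteristic_path_length(A), tolerance = 1e-12)
    expect_equal(global_efficiency(B), global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(nodal_betweenness(B), nodal_betweenness(A)[perm],
                 tolerance = 1e-12)
    expect_equal(nodal_clustering(B), nodal_clustering(A)[perm],
                 tolerance = 1e-12)
  }
})

test_that("disconnected graphs fall back to reachable pairs with a warning", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  expect_warning(lp <- characteristic_path_length(A), "disconnected")
  expect_equal(lp, 1)
  expect_equal(global_efficiency(A), 2 / 10)
})

test_that("rewired nulls preserve the degree sequence reproducibly", {
  set.seed(22)
  A <- random_connected_graph(20, 0.3)
  nulls <- rewired_nulls(A, n_nulls = 10, seed = 5)
  for (N in nulls) {
    expect_equal(sort(rowSums(N)), sort(rowSums(A)))
    expect_equal(N, t(N))
    expect_true(all(diag(N) == 0))
  }
  expect_identical(rewired_nulls(A, n_nulls = 10, seed = 5), nulls)
  # a ring lattice loses clustering under rewiring
  lattice <- ring_graph(30)
  for (i in 1:30) {
    lattice[i, (i %% 30) + 1] <- 1
    lattice[(i %% 30) + 1, i] <- 1
    j <- ((i + 1) %% 30) + 1
    lattice[i, j] <- lattice[j, i] <- 1
  }
  nl <- rewired_nulls(lattice, n_nulls = 10, seed = 6)
  expect_lt(mean(vapply(nl, mean_clustering, 0)), mean_clustering(lattice))
  # a triangle admits no swap: nulls equal the input
  expect_warning(nt <- rewired_nulls(path_graph(2), n_nulls = 3, seed = 1),
                 "no degree-preserving swap")
  expect_equal(nt[[1]], path_graph(2), ignore_attr = TRUE)
})

test_that("a graph with no rewirable pair has sigma exactly 1", {
  # K3 is invariant under edge swaps, so nulls equal the graph itself
  sw <- small_world(complete_graph(3), n_nulls = 5, seed = 1)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("modularity closed forms and planted blocks are recovered", {
  two_k3 <- rbind(cbind(complete_graph(3), matrix(0, 3, 3)),
                  cbind(matrix(0, 3, 3), complete_graph(3)))
  res <- graph_modularity(two_k3, seed = 3)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res$membership)), 2)
  expect_equal(res$membership[1:3], rep(res$membership[1], 3))
  expect_equal(graph_modularity(complete_graph(6), seed = 3)$Q, 0)
  expect_error(graph_modularity(matrix(0, 4, 4)), "edgeless")

  # planted two-block graph: partition recovers the blocks
  set.seed(23)
  n <- 20
  truth <- rep(1:2, each = n / 2)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (truth[i] == truth[j]) 0.9 else 0.05
    A[i, j] <- A[j, i] <- rbinom(1, 1, p)
  }
  fit <- graph_modularity(A, seed = 4)
  expect_gt(rand_index(fit$membership, truth), 0.95)
})

test_that("metric and hub tables line up with the atlas", {
  cohort <- null_cohort(n_regions = 20, n_per_group = 30, seed = 24)
  nets <- suppressWarnings(build_networks(cohort))
  curves <- global_metric_curves(nets, metrics = c("clustering",
                                                   "path_length"))
  expect_equal(nrow(curves), 2 * 13 * 2)
  nodal <- nodal_metric_curves(nets, metrics = c("degree", "betweenness"))
  expect_equal(nrow(nodal), 2 * 13 * 2 * 20)
  expect_setequal(unique(nodal$region), cohort$atlas$region)
  # handshake at every density in the written curves
  deg <- dplyr::filter(nodal, metric == "degree")
  for (g in c("case", "control")) {
    nw <- nets$networks[[g]]
    for (t in seq_along(nw$densities)) {
      expect_equal(
        sum(deg$value[deg$group == g & deg$density == nw$densities[t]]),
        2 * nw$edge_counts[t]
      )
    }
  }
})
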