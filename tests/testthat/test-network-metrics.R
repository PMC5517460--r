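# Thresholding, the five graph metrics, and AUC summaries.

path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))      # a - b - c
star5 <- {A <- matrix(0, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1; A}
k4 <- matrix(1, 4, 4) - diag(4)
k3 <- matrix(1, 3, 3) - diag(3)

test_that("sparsity thresholding keeps the documented edge counts", {
  set.seed(14)
  # common factor keeps most correlations positive, as in unregressed
  # resting-state FC, so the whole sparsity grid is feasible
  common <- rnorm(400)
  V <- cor(matrix(rnorm(400 * 46), 400) + 0.8 * common)
  net <- threshold_network(V, 0.17)
  expect_equal(sum(net$adjacency[upper.tri(net$adjacency)]), 176)  # round(175.95)
  expect_length(sparsity_grid(), 34)
  for (s in sparsity_grid()) {
    m <- sum(threshold_network(V, s)$adjacency[upper.tri(V)])
    expect_equal(m, floor(s * 1035 + 0.5))
  }
  # weighted mode keeps the surviving correlation values
  netw <- threshold_network(V, 0.2, mode = "weighted")
  kept <- netw$adjacency[netw$adjacency != 0]
  expect_true(all(kept > 0))
  expect_true(all(kept %in% V))
})

test_that("ties at the threshold break deterministically and negatives are never taken", {
  V <- matrix(0.4, 6, 6); diag(V) <- 1
  n1 <- threshold_network(V, 0.3)
  n2 <- threshold_network(V, 0.3)
  expect_identical(n1$adjacency, n2$adjacency)
  expect_equal(sum(n1$adjacency[upper.tri(V)]), floor(0.3 * 15 + 0.5))
  # with total ties, edges fill in (row, column) lexicographic order
  ut <- which(upper.tri(V), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), ]
  expected <- ut[seq_len(floor(0.3 * 15 + 0.5)), , drop = FALSE]
  got <- which(n1$adjacency > 0 & upper.tri(V), arr.ind = TRUE)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(expected))

  Vneg <- -V; diag(Vneg) <- 1
  expect_error(threshold_network(Vneg, 0.3), "positive correlations")
})

test_that("metrics reproduce closed-form values on canonical graphs", {
  expect_equal(nodal_efficiency(k4), rep(1, 4))
  expect_equal(nodal_efficiency(path3), c(0.75, 1, 0.75))
  expect_equal(nodal_betweenness(path3), c(0, 0.5, 0))
  # star center routes every unordered leaf pair: (n-1)(n-2)/2 of them
  expect_equal(nodal_betweenness(star5)[1], 0.5)
  expect_equal(nodal_betweenness(star5)[-1], rep(0, 4))
  expect_equal(as.numeric(clustering_coefficient(k3)), 1)
  expect_equal(as.numeric(clustering_coefficient(path3)), 0)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(global_efficiency(diag(0, 4)), 0)
  expect_equal(local_efficiency(k3), 1)
  expect_equal(local_efficiency(star5), 0)
  # isolated node: infinite distances, zero efficiency
  A <- rbind(cbind(k3, 0), 0)
  D <- shortest_paths_matrix(A)$distances
  expect_true(all(is.infinite(D[4, -4])))
  expect_equal(nodal_efficiency(A)[4], 0)
})

test_that("distances and path counts match the Floyd-Warshall / enumeration oracles", {
  for (seed in 1:10) {
    A <- random_graph(12, p = 0.3, seed = seed)
    sp <- shortest_paths_matrix(A, counts = TRUE)
    expect_equal(sp$distances, oracle_fw(oracle_length_matrix(A, FALSE)))
    expect_equal(sp$path_counts, oracle_path_counts(A))
  }
  Aw <- random_graph(10, p = 0.4, weighted = TRUE, seed = 99)
  spw <- shortest_paths_matrix(Aw, counts = TRUE)
  expect_equal(spw$distances, oracle_fw(oracle_length_matrix(Aw, TRUE)),
               tolerance = 1e-12)
  expect_equal(spw$path_counts, oracle_path_counts(Aw, weighted = TRUE))
})

test_that("all five metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:15) {
    weighted <- seed %% 2 == 0
    n <- sample(5:12, 1)
    A <- random_graph(n, p = runif(1, 0.2, 0.6), weighted = weighted, seed = seed)
    tol <- if (weighted) 1e-9 else 1e-12
    expect_equal(nodal_efficiency(A), oracle_nodal_efficiency(A, weighted),
                 tolerance = tol)
    expect_equal(nodal_betweenness(A), oracle_betweenness(A, weighted),
                 tolerance = tol)
    expect_equal(as.numeric(clustering_coefficient(A)),
                 oracle_clustering(A, weighted), tolerance = tol)
    expect_equal(global_efficiency(A), oracle_global_efficiency(A, weighted),
                 tolerance = tol)
    expect_equal(local_efficiency(A), oracle_local_efficiency(A, weighted),
                 tolerance = tol)
  }
})

test_that("betweenness mass equals the oracle's total dependency on every graph", {
  for (seed in 21:26) {
    A <- random_graph(9, p = 0.35, seed = seed)
    expect_equal(sum(nodal_betweenness(A)), sum(oracle_betweenness(A)),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases any efficiency", {
  for (seed in 31:36) {
    A <- random_graph(10, p = 0.25, seed = seed)
    off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample.int(nrow(off), 1), ]
    B <- A
    B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1
    expect_true(all(nodal_efficiency(B) >= nodal_efficiency(A) - 1e-12))
    expect_gte(global_efficiency(B), global_efficiency(A) - 1e-12)
  }
})

test_that("AUC is the composite trapezoid over the sparsity grid", {
  grid <- sparsity_grid()
  expect_equal(metric_auc(rep(2, 34), grid), 0.33 * 2, tolerance = 1e-12)
  lin <- seq(0, 1, length.out = 34)
  expect_equal(metric_auc(lin, grid), 0.33 * 0.5, tolerance = 1e-12)
  set.seed(44)
  y <- runif(34)
  expect_equal(metric_auc(y, grid), oracle_trapz(y, grid), tolerance = 1e-14)
  expect_error(metric_auc(runif(10), grid), "grid")
  expect_error(metric_auc(c(1, 2), c(0.2, 0.1)), "increasing")
})

test_that("metric profiles are deterministic functions of the FC matrix", {
  set.seed(15)
  V <- cor(matrix(rnorm(200 * 12), 200))
  p1 <- network_metric_profile(V, grid = seq(0.2, 0.4, 0.05))
  p2 <- network_metric_profile(V, grid = seq(0.2, 0.4, 0.05))
  expect_identical(p1, p2)
  expect_equal(p1$global$global_efficiency$values,
               colMeans(p1$nodal$nodal_efficiency$values))
})
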