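# Sparsity thresholding and graph-theory metrics of thresholded networks.
#
# Betweenness (Brandes) and weighted full-graph distances are delegated to
# igraph; binary all-pairs distances use a vectorized matrix BFS and
# neighbor-subgraph distances a vectorized Floyd-Warshall, which avoids
# building an igraph object per node when sweeping thousands of networks.
# All metrics are deterministic functions of the FC matrix.

round_half_up <- function(x) floor(x + 0.5)

#' Default sparsity threshold grid
#'
#' The 34 sparsity values from 0.17 to 0.50 in steps of 0.01 commonly used
#' for small-world brain networks.
#'
#' @return Numeric vector of length 34.
#' @export
sparsity_grid <- function() seq(17L, 50L) / 100

#' Threshold an FC matrix at a target sparsity
#'
#' Ranks the `n(n-1)/2` unique off-diagonal correlations in descending
#' order (so negative correlations are never selected before positive ones)
#' and keeps the top `round(sparsity * n(n-1)/2)` as edges. Binary mode
#' sets kept entries to 1; weighted mode retains their correlation values.
#' Ties at the cutoff are broken deterministically by (smaller row, smaller
#' column) index order.
#'
#' @param fc A `connectivity_matrix` or a plain symmetric matrix.
#' @param sparsity Edge fraction in (0, 1).
#' @param mode `"binary"` or `"weighted"`.
#' @param rounding Edge-count rounding rule: `"half_up"` (default) or
#'   `"floor"`.
#' @return An object of class `thresholded_network` with fields
#'   `adjacency`, `sparsity`, `mode`.
#' @export
threshold_network <- function(fc, sparsity, mode = c("binary", "weighted"),
                              rounding = c("half_up", "floor")) {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  V <- if (inherits(fc, "connectivity_matrix")) fc$values else as.matrix(fc)
  stopifnot(sparsity > 0, sparsity < 1, nrow(V) == ncol(V))
  if (max(abs(V - t(V))) > 1e-9) stop("FC matrix must be symmetric")
  n <- nrow(V)
  M <- n * (n - 1) / 2
  m <- if (rounding == "half_up") round_half_up(sparsity * M) else floor(sparsity * M)
  ut <- which(upper.tri(V), arr.ind = TRUE)
  vals <- V[ut]
  n_pos <- sum(vals > 0)
  if (m > n_pos) {
    stop(sprintf(
      "sparsity %.3f requires %d edges but only %d positive correlations are available",
      sparsity, m, n_pos))
  }
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  A <- matrix(0, n, n, dimnames = dimnames(V))
  sel <- ut[keep, , drop = FALSE]
  w <- if (mode == "binary") rep(1, m) else vals[keep]
  A[sel] <- w
  A[sel[, 2:1, drop = FALSE]] <- w
  structure(list(adjacency = A, sparsity = sparsity, mode = mode),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf("<thresholded_network> %s | %d nodes, %d edges (sparsity %.3f)\n",
              x$mode, nrow(x$adjacency), sum(x$adjacency[upper.tri(x$adjacency)] != 0),
              x$sparsity))
  invisible(x)
}

as_network <- function(net) {
  if (inherits(net, "thresholded_network")) return(net)
  A <- as.matrix(net)
  structure(list(adjacency = A, sparsity = NA_real_,
                 mode = if (all(A %in% c(0, 1))) "binary" else "weighted"),
            class = "thresholded_network")
}

net_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# All-pairs hop counts of a binary adjacency by repeated boolean products.
bfs_distances <- function(A) {
  n <- nrow(A)
  A <- A > 0
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(TRUE, n)
  seen <- reach
  d <- 0
  repeat {
    reach <- (reach %*% A) > 0
    new <- reach & !seen
    if (!any(new)) break
    d <- d + 1
    D[new] <- d
    seen <- seen | new
  }
  D
}

# Vectorized Floyd-Warshall on a length matrix (Inf = no edge, 0 diagonal).
fw_distances <- function(L) {
  D <- L
  n <- nrow(D)
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    if (any(upd)) D[upd] <- Dk[upd]
  }
  D
}

# Length matrix of a network: 1 per hop for binary, 1/weight for weighted.
length_matrix <- function(net) {
  A <- net$adjacency
  L <- matrix(Inf, nrow(A), ncol(A))
  if (net$mode == "binary") L[A > 0] <- 1 else L[A > 0] <- 1 / A[A > 0]
  diag(L) <- 0
  L
}

# Distance matrix dispatch used by every metric.
net_distances <- function(net) {
  if (net$mode == "binary") {
    bfs_distances(net$adjacency)
  } else {
    g <- net_graph(net)
    igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  }
}

#' All-pairs shortest path lengths (and shortest-path counts)
#'
#' Binary networks use hop counts; weighted networks use edge length
#' `1/weight`. Unreachable pairs have distance `Inf`.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @param counts Also return the number of distinct shortest paths per pair.
#' @return A list with `distances` (n x n) and, if requested, `path_counts`.
#' @export
shortest_paths_matrix <- function(net, counts = FALSE) {
  net <- as_network(net)
  out <- list(distances = net_distances(net))
  if (counts) out$path_counts <- count_shortest_paths(net, out$distances)
  out
}

# Number of shortest paths per pair, by dynamic programming over nodes in
# order of distance from each source (tolerance handles weighted lengths).
count_shortest_paths <- function(net, D, tol = 1e-9) {
  A <- net$adjacency
  n <- nrow(A)
  len <- length_matrix(net)
  diag(len) <- Inf
  P <- matrix(0, n, n)
  for (h in seq_len(n)) {
    ordv <- order(D[h, ])
    cnt <- numeric(n)
    cnt[h] <- 1
    for (j in ordv) {
      if (j == h || !is.finite(D[h, j])) next
      pred <- which(A[, j] > 0 & abs(D[h, ] + len[, j] - D[h, j]) <= tol * (1 + D[h, j]))
      cnt[j] <- sum(cnt[pred])
    }
    P[h, ] <- cnt
  }
  P
}

efficiency_from_distances <- function(D) {
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (nrow(D) - 1)
}

#' Nodal efficiency
#'
#' Mean inverse shortest-path distance from each node to all others,
#' `E_nodal(i) = 1/(N-1) * sum_j 1/d_ij`; unreachable pairs contribute 0.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return Numeric vector of per-node efficiencies in `[0, 1]`.
#' @export
nodal_efficiency <- function(net) {
  net <- as_network(net)
  efficiency_from_distances(net_distances(net))
}

#' Nodal betweenness centrality
#'
#' Summed dependency of unordered node pairs on each node — the fraction
#' `rho_hj(i) / rho_hj` of shortest h-j paths passing through i, summed
#' over pairs with `h, j != i` — normalized by `(n-1)(n-2)`, so values lie
#' in `[0, 0.5]` (a 3-node path's middle node scores 0.5). Pairs with no
#' connecting path contribute 0.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return Numeric vector of per-node betweenness values.
#' @export
nodal_betweenness <- function(net) {
  net <- as_network(net)
  g <- net_graph(net)
  n <- nrow(net$adjacency)
  if (n < 3) return(rep(0, n))
  w <- if (net$mode == "binary") NULL else 1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE, weights = w)
  as.numeric(b / ((n - 1) * (n - 2)))
}

#' Network clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' `C_i = 2 t_i / (k_i (k_i - 1))`, where `t_i` counts edges among the
#' neighbors of node i; nodes with fewer than 2 neighbors contribute 0.
#' Weighted networks use the geometric-mean (Onnela) triangle intensity
#' with weights normalized by the maximum weight.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return A scalar; per-node values are attached as attribute `"per_node"`.
#' @export
clustering_coefficient <- function(net) {
  net <- as_network(net)
  A <- net$adjacency
  k <- rowSums(A > 0)
  W <- if (net$mode == "binary") (A > 0) * 1 else {
    mx <- max(A)
    if (mx > 0) (A / mx)^(1 / 3) else A
  }
  t_i <- diag(W %*% W %*% W) / 2
  ci <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  structure(mean(ci), per_node = ci)
}

#' Network global efficiency
#'
#' Mean of nodal efficiency across nodes:
#' `E_glob = 1/(N(N-1)) * sum_{i != j} 1/d_ij`.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  mean(nodal_efficiency(net))
}

# Global efficiency of the subgraph induced by each node's neighbors,
# shared by local_efficiency and the profile fast path.
local_efficiency_values <- function(net) {
  A <- net$adjacency
  L <- length_matrix(net)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    Ls <- L[nb, nb, drop = FALSE]
    Ds <- if (net$mode == "binary") {
      bfs_distances(A[nb, nb, drop = FALSE])
    } else {
      fw_distances(Ls)
    }
    mean(efficiency_from_distances(Ds))
  }, numeric(1))
}

#' Network local efficiency
#'
#' `E_loc = 1/N * sum_i E_glob(G_i)`, where `G_i` is the subgraph induced
#' by the neighbors of node i (excluding i itself); nodes with fewer than
#' two neighbors contribute 0. A fault-tolerance measure.
#'
#' @param net A `thresholded_network` (or adjacency matrix).
#' @return Scalar in `[0, 1]` (binary mode).
#' @export
local_efficiency <- function(net) {
  net <- as_network(net)
  mean(local_efficiency_values(net))
}

#' Area under a metric-versus-sparsity curve
#'
#' Composite trapezoid integral of metric values over a strictly increasing
#' sparsity grid; gives a threshold-independent summary.
#'
#' @param values Metric value at each grid point.
#' @param grid Sparsity grid (strictly increasing, length >= 2).
#' @return Scalar AUC.
#' @export
metric_auc <- function(values, grid = sparsity_grid()) {
  if (length(values) != length(grid)) {
    stop(sprintf("curve has %d values but grid has %d points",
                 length(values), length(grid)))
  }
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least 2 points")
  }
  sum(diff(grid) * (head(values, -1) + tail(values, -1)) / 2)
}

#' All network metrics of an FC matrix across the sparsity grid
#'
#' Thresholds the FC matrix at every sparsity in `grid`, computes the five
#' metrics, and summarizes each as its AUC over the grid.
#'
#' @param fc A `connectivity_matrix` or symmetric matrix.
#' @param grid Sparsity grid (default [sparsity_grid()]).
#' @param mode `"binary"` or `"weighted"`.
#' @param rounding Edge-count rounding rule (see [threshold_network()]).
#' @return A list with `nodal` (list of node x sparsity matrices plus
#'   per-node AUC vectors for `nodal_efficiency`, `nodal_betweenness`) and
#'   `global` (list of per-sparsity curves plus scalar AUCs for
#'   `clustering_coefficient`, `global_efficiency`, `local_efficiency`),
#'   and the `grid`.
#' @export
network_metric_profile <- function(fc, grid = sparsity_grid(),
                                   mode = c("binary", "weighted"),
                                   rounding = "half_up") {
  mode <- match.arg(mode)
  V <- if (inherits(fc, "connectivity_matrix")) fc$values else as.matrix(fc)
  n <- nrow(V)
  ne <- matrix(NA_real_, n, length(grid))
  nb <- matrix(NA_real_, n, length(grid))
  cc <- ge <- le <- numeric(length(grid))
  for (s in seq_along(grid)) {
    net <- threshold_network(V, grid[s], mode, rounding)
    ne[, s] <- efficiency_from_distances(net_distances(net))
    nb[, s] <- nodal_betweenness(net)
    cc[s] <- clustering_coefficient(net)
    ge[s] <- mean(ne[, s])
    le[s] <- mean(local_efficiency_values(net))
  }
  list(
    nodal = list(
      nodal_efficiency = list(values = ne, auc = apply(ne, 1, metric_auc, grid = grid)),
      nodal_betweenness = list(values = nb, auc = apply(nb, 1, metric_auc, grid = grid))),
    global = list(
      clustering_coefficient = list(values = cc, auc = metric_auc(cc, grid)),
      global_efficiency = list(values = ge, auc = metric_auc(ge, grid)),
      local_efficiency = list(values = le, auc = metric_auc(le, grid))),
    grid = grid, mode = mode)
}
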