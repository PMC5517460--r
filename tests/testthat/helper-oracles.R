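# Independent brute-force oracles for graph metrics, correlation and ANOVA.
# These deliberately use naive algorithms (triple-loop Floyd-Warshall,
# exhaustive shortest-path enumeration, explicit triangle counting) and
# never call the package's own machinery.

# Naive Floyd-Warshall over a length matrix (Inf where no edge, 0 diagonal).
oracle_fw <- function(L) {
  n <- nrow(L)
  D <- L
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_length_matrix <- function(A, weighted) {
  L <- matrix(Inf, nrow(A), ncol(A))
  L[A > 0] <- if (weighted) 1 / A[A > 0] else 1
  if (!weighted) L[A > 0] <- 1
  diag(L) <- 0
  L
}

# Enumerate every shortest path between h and j by depth-first search,
# guided by the oracle distance matrix. Returns a list of node vectors.
oracle_all_shortest_paths <- function(A, L, D, h, j, tol = 1e-9) {
  paths <- list()
  walk <- function(node, sofar) {
    if (node == j) {
      paths[[length(paths) + 1L]] <<- sofar
      return(invisible())
    }
    for (m in which(A[node, ] > 0)) {
      # m continues a shortest path h -> j if d(h,node)+len(node,m)+d(m,j)=d(h,j)
      here <- D[h, node] + L[node, m] + D[m, j]
      if (is.finite(here) && abs(here - D[h, j]) <= tol * (1 + D[h, j])) {
        walk(m, c(sofar, m))
      }
    }
  }
  if (is.finite(D[h, j])) walk(h, h)
  paths
}

# Betweenness by exhaustive path enumeration over unordered pairs,
# normalized by (n-1)(n-2) as in the nodal-betweenness definition.
oracle_betweenness <- function(A, weighted = FALSE) {
  n <- nrow(A)
  L <- oracle_length_matrix(A, weighted)
  D <- oracle_fw(L)
  b <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h >= j || !is.finite(D[h, j])) next
    paths <- oracle_all_shortest_paths(A, L, D, h, j)
    if (!length(paths)) next
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior)) {
      tab <- tabulate(interior, nbins = n)
      b <- b + tab / length(paths)
    }
  }
  b / ((n - 1) * (n - 2))
}

oracle_path_counts <- function(A, weighted = FALSE) {
  n <- nrow(A)
  L <- oracle_length_matrix(A, weighted)
  D <- oracle_fw(L)
  P <- matrix(0, n, n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) { P[h, j] <- 1; next }
    P[h, j] <- length(oracle_all_shortest_paths(A, L, D, h, j))
  }
  P
}

oracle_nodal_efficiency <- function(A, weighted = FALSE) {
  D <- oracle_fw(oracle_length_matrix(A, weighted))
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    s / (n - 1)
  })
}

oracle_global_efficiency <- function(A, weighted = FALSE) {
  mean(oracle_nodal_efficiency(A, weighted))
}

oracle_local_efficiency <- function(A, weighted = FALSE) {
  n <- nrow(A)
  vals <- sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE], weighted)
  })
  mean(vals)
}

# Clustering by explicit triangle counting; weighted uses the Onnela
# geometric-mean intensity with max-weight normalization.
oracle_clustering <- function(A, weighted = FALSE) {
  n <- nrow(A)
  W <- if (weighted && max(A) > 0) A / max(A) else (A > 0) * 1
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] > 0) {
        t_i <- t_i + (W[i, nb[a]] * W[i, nb[b]] * W[nb[a], nb[b]])^(1 / 3)
      }
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(ci)
}

# Two-pass summation-formula Pearson correlation matrix.
oracle_pearson <- function(X) {
  n <- nrow(X)
  N <- ncol(X)
  R <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    xi <- X[i, ]; xj <- X[j, ]
    mi <- sum(xi) / N; mj <- sum(xj) / N
    num <- sum((xi - mi) * (xj - mj))
    den <- sqrt(sum((xi - mi)^2)) * sqrt(sum((xj - mj)^2))
    R[i, j] <- R[j, i] <- num / den
  }
  R
}

oracle_trapz <- function(y, x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# One-way ANOVA ICC through R's aov() machinery (independent of the
# package's closed-form implementation).
oracle_icc_aov <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))))
  tab <- summary(stats::aov(y ~ Error(subject), data = df))
  msb <- tab[["Error: subject"]][[1]][["Mean Sq"]]
  msw <- tab[["Error: Within"]][[1]][["Mean Sq"]]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Random undirected graph fixtures.
random_graph <- function(n, p = 0.35, weighted = FALSE, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- ut[runif(length(ut)) < p]
  A[on] <- if (weighted) runif(length(on), 0.1, 1) else 1
  A + t(A)
}
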