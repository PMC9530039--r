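# Brute-force reference implementations used to cross-check the compiled
# graph core.  Written for clarity, not speed; only ever applied to graphs
# with n <= 8 (or toy graphs), where exhaustive computation is feasible.

# Floyd-Warshall all-pairs shortest path lengths (Inf = unreachable)
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# number of distinct shortest paths between every pair, via matrix powers:
# sigma_ij = (A^d_ij)_ij (each walk of minimal length is a shortest path)
oracle_path_counts <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sig <- matrix(0, n, n)
  pw <- diag(n)
  for (len in seq_len(n)) {
    pw <- pw %*% a
    hit <- d == len
    sig[hit] <- pw[hit]
  }
  diag(sig) <- 0
  sig
}

# ordered-pair betweenness: sum over (h, j), h != j != i, of the fraction of
# shortest h-j paths through i, normalized by (n-1)(n-2)
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sig <- oracle_path_counts(a)
  bc <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (h in seq_len(n)) for (j in seq_len(n)) {
      if (h == j || h == i || j == i) next
      if (!is.finite(d[h, j]) || sig[h, j] == 0) next
      if (d[h, i] + d[i, j] == d[h, j])
        acc <- acc + sig[h, i] * sig[i, j] / sig[h, j]
    }
    bc[i] <- acc / ((n - 1) * (n - 2))
  }
  bc
}

oracle_degree <- function(a) rowSums(a > 0)

oracle_triangles <- function(a) {
  n <- nrow(a)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) >= 2) {
      pr <- combn(nb, 2)
      t_i[i] <- sum(a[cbind(pr[1, ], pr[2, ])] > 0)
    }
  }
  t_i
}

oracle_clustering <- function(a) {
  k <- oracle_degree(a)
  t_i <- oracle_triangles(a)
  ci <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  list(ci = ci, c_mean = mean(ci))
}

# mean distance to reachable nodes; NaN for a node with none reachable
oracle_nlp <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    dd <- d[i, -i]
    dd <- dd[is.finite(dd)]
    if (length(dd) == 0) NaN else mean(dd)
  }, numeric(1))
}

oracle_L <- function(a) {
  nlp <- oracle_nlp(a)
  mean(nlp[is.finite(nlp)])
}

oracle_eglob <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  ei <- vapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }, numeric(1))
  list(eglob_i = ei, eglob = mean(ei))
}

oracle_eloc <- function(a) {
  n <- nrow(a)
  ei <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- a[nb, nb, drop = FALSE]
    d <- oracle_distances(sub)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    ei[i] <- sum(inv) / (k * (k - 1))
  }
  list(eloc_i = ei, eloc = mean(ei))
}

# all set partitions of n labeled items (Bell(8) = 4140)
oracle_partitions <- function(n) {
  if (n == 1) return(list(1L))
  prev <- oracle_partitions(n - 1)
  out <- list()
  for (p in prev) {
    k <- max(p)
    for (c in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, c)
  }
  out
}

# Newman Q computed directly from the adjacency matrix, independent of any
# package code: Q = sum_c (l_c / m - (d_c / 2m)^2)
oracle_modularity_value <- function(a, membership) {
  m <- sum(a) / 2
  if (m == 0) return(NA_real_)
  deg <- rowSums(a)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    lc <- sum(a[idx, idx, drop = FALSE]) / 2
    dc <- sum(deg[idx])
    q <- q + lc / m - (dc / (2 * m))^2
  }
  q
}

# exhaustive-search maximum modularity over all partitions
oracle_best_modularity_adj <- function(a) {
  max(vapply(oracle_partitions(nrow(a)),
             function(mem) oracle_modularity_value(a, mem), numeric(1)))
}

oracle_best_modularity <- function(g) {
  max(vapply(oracle_partitions(g$n), function(m) modularity_q(g, m),
             numeric(1)))
}

# textbook step-up BH adjusted q-values
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# random Erdos-Renyi adjacency with at least one edge
random_adjacency <- function(n, p) {
  repeat {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
    a <- a + t(a)
    if (sum(a) > 0) return(a)
  }
}

# even-degree ring lattice on n nodes (each node linked to k/2 neighbors on
# each side); the classical high-clustering, long-path baseline
ring_lattice <- function(n, k) {
  stopifnot(k %% 2 == 0, k < n)
  edges <- NULL
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    edges <- rbind(edges, c(min(i, j), max(i, j)))
  }
  binary_graph(n, unique(edges))
}
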