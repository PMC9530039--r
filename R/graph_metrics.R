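#' Shortest path lengths and path counts
#'
#' Breadth-first distances `d_ij` (in hops) and the number of distinct
#' shortest paths `rho_ij` for every ordered node pair.  Unreachable pairs
#' have `d = Inf` and `rho = 0`.
#'
#' @param g a `"binary_graph"`.
#' @return list with matrices `d` and `sigma`.
#' @export
shortest_paths <- function(g) {
  res <- cpp_shortest_paths(g$n, g$edges)
  if (!is.null(g$regions))
    dimnames(res$d) <- dimnames(res$sigma) <- list(g$regions, g$regions)
  res
}

#' Degree and triangle counts
#'
#' `k_i` is the number of links of node `i`; `t_i` counts the triangles
#' around it (pairs of neighbors that are themselves linked).
#'
#' @param g a `"binary_graph"`.
#' @return list with integer vectors `k` and `t`.
#' @export
degree_triangles <- function(g) {
  res <- cpp_graph_metrics(g$n, g$edges, paths = FALSE, bc = FALSE,
                           clustering = TRUE, eloc = FALSE)
  list(k = name_nodes(res$degree, g), t = name_nodes(as.integer(res$triangles), g))
}

#' Clustering coefficient
#'
#' `C_i = 2 t_i / (k_i (k_i - 1))`, with `C_i = 0` for `k_i < 2`; the network
#' value `C` is the mean over all nodes.
#'
#' @param g a `"binary_graph"`.
#' @return list with vector `ci` and scalar `c_mean`.
#' @export
clustering_coef <- function(g) {
  res <- cpp_graph_metrics(g$n, g$edges, paths = FALSE, bc = FALSE,
                           clustering = TRUE, eloc = FALSE)
  list(ci = name_nodes(res$ci, g), c_mean = res$c_mean)
}

#' Mean nodal path length
#'
#' The average shortest path length from each node to every other node.  On a
#' disconnected graph the mean is taken over reachable nodes only and the
#' result carries attribute `connected = FALSE`; an isolated node gets `NaN`.
#'
#' @param g a `"binary_graph"`.
#' @return numeric vector `Nlp_i` with attribute `connected`.
#' @export
nodal_path_length <- function(g) {
  res <- cpp_graph_metrics(g$n, g$edges, paths = TRUE, bc = FALSE,
                           clustering = FALSE, eloc = FALSE)
  structure(name_nodes(res$nlp, g), connected = res$connected)
}

#' Characteristic path length
#'
#' Mean of the nodal path lengths over nodes with at least one reachable
#' partner.
#'
#' @param g a `"binary_graph"`.
#' @return scalar `L` with attribute `connected`.
#' @export
char_path_length <- function(g) {
  res <- cpp_graph_metrics(g$n, g$edges, paths = TRUE, bc = FALSE,
                           clustering = FALSE, eloc = FALSE)
  structure(res$L, connected = res$connected)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between other node pairs that pass through each
#' node, summed over ordered pairs `(h, j)` and normalized by
#' `(n-1)(n-2)`, so values lie in `[0, 1]` and a star center scores exactly 1.
#' (Halve to convert to the unordered-pair convention.)
#'
#' @param g a `"binary_graph"` with at least 3 nodes.
#' @return numeric vector `b_i`.
#' @export
betweenness_centrality <- function(g) {
  fail_if(g$n < 3, "betweenness is undefined for n < 3")
  res <- cpp_graph_metrics(g$n, g$edges, paths = TRUE, bc = TRUE,
                           clustering = FALSE, eloc = FALSE)
  name_nodes(res$bc, g)
}

#' Global efficiency
#'
#' Mean over nodes of the average inverse shortest path length to all other
#' nodes; unreachable pairs contribute 0 (the standard efficiency
#' convention).
#'
#' @param g a `"binary_graph"`.
#' @return list with vector `eglob_i` and scalar `eglob`.
#' @export
global_efficiency <- function(g) {
  res <- cpp_graph_metrics(g$n, g$edges, paths = TRUE, bc = FALSE,
                           clustering = FALSE, eloc = FALSE)
  list(eglob_i = name_nodes(res$eglob_i, g), eglob = res$eglob)
}

#' Local efficiency
#'
#' For each node, the efficiency of the subgraph induced by its neighbors
#' (paths running only through neighbors), normalized by `k_i (k_i - 1)`;
#' zero for `k_i < 2`.  The network value is the mean over nodes.
#'
#' @param g a `"binary_graph"`.
#' @return list with vector `eloc_i` and scalar `eloc`.
#' @export
local_efficiency <- function(g) {
  res <- cpp_graph_metrics(g$n, g$edges, paths = FALSE, bc = FALSE,
                           clustering = FALSE, eloc = TRUE)
  list(eloc_i = name_nodes(res$eloc_i, g), eloc = res$eloc)
}

#' All nodal and global metrics of one graph
#'
#' One pass computing degree, triangles, clustering, nodal path length,
#' betweenness, global and local efficiency.
#'
#' @param g a `"binary_graph"`.
#' @return named list of nodal vectors and global scalars.
#' @export
graph_metrics <- function(g) {
  res <- cpp_graph_metrics(g$n, g$edges, paths = TRUE, bc = g$n >= 3,
                           clustering = TRUE, eloc = TRUE)
  out <- list(k = name_nodes(res$degree, g),
              t = name_nodes(as.integer(res$triangles), g),
              ci = name_nodes(res$ci, g),
              C = res$c_mean,
              Nlp = name_nodes(res$nlp, g),
              L = res$L,
              eglob_i = name_nodes(res$eglob_i, g),
              Eglob = res$eglob,
              eloc_i = name_nodes(res$eloc_i, g),
              Eloc = res$eloc,
              connected = res$connected)
  if (g$n >= 3) out$Bc <- name_nodes(res$bc, g)
  out
}

name_nodes <- function(x, g) {
  if (!is.null(g$regions)) names(x) <- g$regions
  x
}

#' Community partition by greedy modularity maximization
#'
#' Finds a partition with a Louvain-type greedy optimizer (local moving plus
#' community aggregation) run with `restarts` randomized node orders, keeping
#' the partition with the highest Newman modularity.  The reported `Q` is
#' re-evaluated on the returned partition with the mixing-matrix formula
#' `Q = sum_u [e_uu - (sum_v e_uv)^2]` (see [modularity_q()]); the two
#' computations agree to machine precision.
#'
#' @param g a `"binary_graph"` with at least one edge.
#' @param restarts randomized restarts (default 10).
#' @param seed integer seed making the optimization deterministic.
#' @return list with `membership` (integer vector), `Q`, and `n_modules`.
#' @export
modularity_partition <- function(g, restarts = 10L, seed = 1L) {
  fail_if(nrow(g$edges) < 1, "modularity is undefined for an edgeless graph")
  res <- cpp_modularity(g$n, g$edges, as.integer(restarts), as.numeric(seed))
  membership <- name_nodes(res$membership, g)
  q_formula <- modularity_q(g, res$membership)
  list(membership = membership, Q = q_formula, n_modules = res$n_modules)
}

#' Modularity of a given partition
#'
#' Evaluates `Q = sum_u [e_uu - (sum_v e_uv)^2]`, where `e_uu` is the
#' proportion of links inside module `u` (each undirected link counted once)
#' and, for `u != v`, each between-module link contributes half to `e_uv` and
#' half to `e_vu`, so the mixing matrix sums to 1.  With this convention two
#' disjoint triangles partitioned by component score `Q = 0.5` and any
#' single-module partition scores 0.
#'
#' @param g a `"binary_graph"` with at least one edge.
#' @param membership integer module label per node.
#' @return scalar `Q` in `[-0.5, 1)`.
#' @export
modularity_q <- function(g, membership) {
  m <- nrow(g$edges)
  fail_if(m < 1, "modularity is undefined for an edgeless graph")
  fail_if(length(membership) != g$n, "need one module label per node")
  labs <- as.integer(factor(membership))
  k <- max(labs)
  e <- matrix(0, k, k)
  cu <- labs[g$edges[, 1]]
  cv <- labs[g$edges[, 2]]
  for (idx in seq_len(m)) {
    if (cu[idx] == cv[idx]) {
      e[cu[idx], cu[idx]] <- e[cu[idx], cu[idx]] + 1 / m
    } else {
      e[cu[idx], cv[idx]] <- e[cu[idx], cv[idx]] + 0.5 / m
      e[cv[idx], cu[idx]] <- e[cv[idx], cu[idx]] + 0.5 / m
    }
  }
  sum(diag(e) - rowSums(e)^2)
}

#' Degree-preserving rewired surrogate
#'
#' One Maslov-Sneppen surrogate: random double-edge swaps that preserve every
#' node's degree exactly while destroying all other structure.
#'
#' @param g a `"binary_graph"`.
#' @param n_swaps attempted swaps (default `10 * |E|`).
#' @param seed integer seed.
#' @return a rewired `"binary_graph"` with the identical degree sequence.
#' @export
rewire_graph <- function(g, n_swaps = 10L * nrow(g$edges), seed = 1L) {
  edges <- cpp_rewire(g$n, g$edges, as.integer(n_swaps), as.numeric(seed))
  binary_graph(g$n, edges, regions = g$regions,
               sparsity_target = g$sparsity_target)
}

#' Small-world indices against a degree-preserving null ensemble
#'
#' Computes the normalized clustering coefficient `gamma = C / C_random`, the
#' normalized characteristic path length `lambda = L / L_random`, and the
#' small-world index `sigma = gamma / lambda`, where the null values are
#' means over `n_null` Maslov-Sneppen rewired surrogates.  `gamma > 1`,
#' `lambda ~ 1` and `sigma > 1` indicate small-world organization.  With
#' `null = "self"` the graph is its own ensemble and all three indices are
#' exactly 1 (a degenerate sanity mode).
#'
#' @param g a `"binary_graph"`.
#' @param n_null surrogate count (default 100).
#' @param seed integer seed.
#' @param null `"rewire"` (default) or `"self"`.
#' @param swap_factor attempted swaps per surrogate as a multiple of `|E|`.
#' @return list with `C`, `L`, `C_random`, `L_random`, `gamma`, `lambda`,
#'   `sigma` and `connected`.
#' @export
small_world <- function(g, n_null = 100L, seed = 1L,
                        null = c("rewire", "self"), swap_factor = 10L) {
  null <- match.arg(null)
  real <- cpp_graph_metrics(g$n, g$edges, paths = TRUE, bc = FALSE,
                            clustering = TRUE, eloc = FALSE)
  if (null == "self") {
    crand <- real$c_mean
    lrand <- real$L
  } else {
    cs <- numeric(n_null)
    ls <- numeric(n_null)
    for (b in seq_len(n_null)) {
      sub_seed <- as.numeric(seed) * 1000 + b
      edges <- cpp_rewire(g$n, g$edges, as.integer(swap_factor) * nrow(g$edges),
                          sub_seed)
      surro <- cpp_graph_metrics(g$n, edges, paths = TRUE, bc = FALSE,
                                 clustering = TRUE, eloc = FALSE)
      cs[b] <- surro$c_mean
      ls[b] <- surro$L
    }
    crand <- mean(cs)
    lrand <- mean(ls[is.finite(ls)])
  }
  if (!is.finite(crand) || crand == 0) {
    warning("degenerate null ensemble (C_random = 0); reporting unnormalized C and L")
    gamma <- lambda <- sigma <- NA_real_
  } else {
    gamma <- real$c_mean / crand
    lambda <- real$L / lrand
    sigma <- gamma / lambda
  }
  list(C = real$c_mean, L = real$L, C_random = crand, L_random = lrand,
       gamma = gamma, lambda = lambda, sigma = sigma,
       connected = real$connected)
}
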