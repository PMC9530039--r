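#' Sliding age windows over one group
#'
#' Sorts the subjects of one group by ascending age (ties broken by
#' `subject_id`, so window membership never depends on input row order) and
#' slides a window of `width` subjects in increments of `step`.  Consecutive
#' windows share exactly `width - step` subjects; the number of windows is
#' `floor((n - width) / step) + 1`.
#'
#' @param table thickness table restricted to a single group.
#' @param width subjects per window (>= 3, correlation needs at least three
#'   observations).
#' @param step increment in subjects (>= 1).
#' @return list of windows, each a list with `window_index`, `subject_ids`
#'   (ordered), and `age_span = c(min, max)`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 1))
#' hc <- cohort[cohort$group == "HC", ]
#' length(make_windows(hc))   # 35 - 10 + 1 = 26
#' @export
make_windows <- function(table, width = 10L, step = 1L) {
  fail_if(length(unique(table$group)) > 1,
          "make_windows expects a single group; got %d",
          length(unique(table$group)))
  width <- as.integer(width); step <- as.integer(step)
  fail_if(width < 3L, "degenerate window: width must be >= 3, got %d", width)
  fail_if(step < 1L, "step must be >= 1, got %d", step)
  n <- nrow(table)
  fail_if(n < width, "insufficient subjects: group has %d, window width is %d",
          n, width)
  ord <- order(table$age, table$subject_id)
  ids <- table$subject_id[ord]
  ages <- table$age[ord]
  n_win <- (n - width) %/% step + 1L
  lapply(seq_len(n_win), function(k) {
    pos <- ((k - 1L) * step + 1L):((k - 1L) * step + width)
    list(window_index = k,
         subject_ids = ids[pos],
         age_span = c(min(ages[pos]), max(ages[pos])))
  })
}

#' Interregional Pearson correlation matrix for one window
#'
#' Correlates the cortical thickness of every pair of regions across the
#' subjects of one age window, yielding the window's structural covariance
#' network.  The diagonal is stored as 0 (self-edges are excluded).  A region
#' with zero variance within the window gets all its correlations set to 0
#' and triggers a warning rather than an abort.
#'
#' @param window one element of [make_windows()].
#' @param table the thickness table containing the window's subjects.
#' @param regions region labels defining node order.
#' @param residualize_age if `TRUE`, each region is linearly residualized on
#'   age within the window before correlating (sensitivity analysis; the
#'   sliding window itself is the primary age control).
#' @return 68 x 68 symmetric numeric matrix with region dimnames and
#'   attributes `window_index` and `age_span`.
#' @export
correlation_matrix <- function(window, table, regions = dk_atlas()$label,
                               residualize_age = FALSE) {
  idx <- match(window$subject_ids, table$subject_id)
  fail_if(anyNA(idx), "window subjects missing from table: %s",
          paste(window$subject_ids[is.na(idx)], collapse = ", "))
  x <- as.matrix(table[idx, regions, drop = FALSE])
  storage.mode(x) <- "double"
  if (residualize_age) {
    age <- table$age[idx]
    x <- apply(x, 2, function(col) col - fitted_line(age, col))
  }
  sds <- apply(x, 2, sd)
  degenerate <- sds == 0 | is.na(sds)
  if (any(degenerate)) {
    warning(sprintf("zero-variance region(s) in window %d: %s (correlations set to 0)",
                    window$window_index,
                    paste(regions[degenerate], collapse = ", ")))
    x[, degenerate] <- 0
  }
  r <- suppressWarnings(cor(x))
  r[, degenerate] <- 0
  r[degenerate, ] <- 0
  diag(r) <- 0
  dimnames(r) <- list(regions, regions)
  attr(r, "window_index") <- window$window_index
  attr(r, "age_span") <- window$age_span
  r
}

fitted_line <- function(x, y) {
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  a + b * x
}

#' Sparsity grid
#'
#' The default analysis grid runs from 0.05 to 0.50 in steps of 0.05, where
#' sparsity is the fraction of retained edges out of the `n(n-1)/2` possible.
#'
#' @param from,to,by grid limits and step, each in (0, 1].
#' @return ascending numeric vector.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.50, by = 0.05) {
  g <- seq(from, to, by = by)
  fail_if(any(g <= 0 | g > 1), "sparsity values must lie in (0, 1]")
  fail_if(is.unsorted(g, strictly = TRUE), "grid must be strictly increasing")
  g
}

#' Rank region pairs by correlation strength
#'
#' @param m correlation matrix.
#' @param edge_rank `"signed"` ranks by the signed coefficient (the structural
#'   covariance convention: positive covariance is connectivity); `"abs"`
#'   ranks by magnitude.
#' @return integer matrix with columns `i`, `j` (1-based, i < j) ordered by
#'   decreasing rank value, ties broken by lexicographic region-pair order.
#' @keywords internal
rank_edges <- function(m, edge_rank = c("signed", "abs")) {
  edge_rank <- match.arg(edge_rank)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[upper.tri(m)]
  if (edge_rank == "abs") vals <- abs(vals)
  ord <- order(-vals, ut[, 1], ut[, 2])
  cbind(i = ut[ord, 1], j = ut[ord, 2])
}

#' Threshold a correlation matrix at a target sparsity
#'
#' Retains the `round(s * n(n-1)/2)` region pairs with the largest (signed,
#' by default) correlation, producing an undirected, unweighted graph.
#' Rounding is half-up; ties in `r` break by lexicographic region-pair order
#' so the edge set is fully deterministic, and edge sets are nested across
#' ascending sparsities.
#'
#' @param m correlation matrix (diagonal ignored).
#' @param s target sparsity in (0, 1].
#' @inheritParams rank_edges
#' @return an object of class `"binary_graph"`: a list with `n`, `edges`
#'   (two-column integer matrix), `sparsity` (realized), `sparsity_target`
#'   and `regions`.
#' @examples
#' r <- diag(0, 68)
#' r[upper.tri(r)] <- runif(sum(upper.tri(r)), -1, 1)
#' r <- (r + t(r))
#' g <- threshold_at_sparsity(r, 0.5)
#' nrow(g$edges)   # 1139
#' @export
threshold_at_sparsity <- function(m, s, edge_rank = c("signed", "abs")) {
  fail_if(s <= 0 || s > 1, "sparsity must lie in (0, 1], got %g", s)
  n <- nrow(m)
  maxe <- n * (n - 1) / 2
  n_edges <- round_half_up(s * maxe)
  fail_if(n_edges < 1, "sparsity %g yields an empty graph on %d nodes", s, n)
  ranked <- rank_edges(m, edge_rank)
  edges <- ranked[seq_len(n_edges), , drop = FALSE]
  binary_graph(n, edges, regions = rownames(m), sparsity_target = s)
}

#' Construct a binary graph
#'
#' @param n node count.
#' @param edges two-column integer matrix of 1-based endpoints.
#' @param regions optional node labels.
#' @param sparsity_target target sparsity that produced the graph, if any.
#' @return `"binary_graph"` object.
#' @export
binary_graph <- function(n, edges, regions = NULL, sparsity_target = NA_real_) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    fail_if(any(edges[, 1] == edges[, 2]), "self-loops are not allowed")
    fail_if(any(edges < 1 | edges > n), "edge endpoint out of range")
    fail_if(anyDuplicated(edges) > 0, "duplicate edges are not allowed")
  }
  structure(list(n = as.integer(n), edges = edges,
                 sparsity = nrow(edges) / (n * (n - 1) / 2),
                 sparsity_target = sparsity_target,
                 regions = regions),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary graph: %d nodes, %d edges (sparsity %.4f)\n",
              x$n, nrow(x$edges), x$sparsity))
  invisible(x)
}

#' Build a binary graph from a 0/1 adjacency matrix
#'
#' @param a square symmetric 0/1 matrix with zero diagonal.
#' @return `"binary_graph"` object.
#' @export
graph_from_adjacency <- function(a) {
  fail_if(!isSymmetric(unname(a > 0)), "adjacency must be symmetric")
  fail_if(any(diag(a) != 0), "diagonal must be zero")
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  binary_graph(nrow(a), idx, regions = rownames(a))
}

#' Adjacency matrix of a binary graph
#'
#' @param g `"binary_graph"`.
#' @return square 0/1 integer matrix.
#' @export
as_adjacency <- function(g) {
  a <- matrix(0L, g$n, g$n)
  if (nrow(g$edges) > 0) {
    a[g$edges] <- 1L
    a[g$edges[, 2:1, drop = FALSE]] <- 1L
  }
  if (!is.null(g$regions)) dimnames(a) <- list(g$regions, g$regions)
  a
}

#' Minimum sparsity at which the network is fully connected
#'
#' Adds ranked edges one at a time (grid step `1 / (n(n-1)/2)`) until the
#' graph spans all nodes in a single connected component, and returns the
#' corresponding sparsity.  The result is always at least
#' `(n-1) / (n(n-1)/2) = 2/n`, the spanning-tree bound.
#'
#' @inheritParams threshold_at_sparsity
#' @return smallest sparsity on the one-edge grid giving a connected graph.
#' @export
min_connected_sparsity <- function(m, edge_rank = c("signed", "abs")) {
  n <- nrow(m)
  ranked <- rank_edges(m, edge_rank)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  components <- n
  for (e in seq_len(nrow(ranked))) {
    ri <- find(ranked[e, 1]); rj <- find(ranked[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      components <- components - 1
      if (components == 1) return(e / nrow(ranked))
    }
  }
  1
}
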