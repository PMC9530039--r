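make_test_matrix <- function(n = 68, seed = 1) {
  withr::with_seed(seed, {
    r <- matrix(0, n, n)
    r[upper.tri(r)] <- runif(n * (n - 1) / 2, -1, 1)
    r <- r + t(r)
  })
  r
}

test_that("edge counts follow round-half-up of s * n(n-1)/2", {
  r <- make_test_matrix()
  expect_equal(nrow(threshold_at_sparsity(r, 0.05)$edges), 114)  # 113.9 -> 114
  expect_equal(nrow(threshold_at_sparsity(r, 0.25)$edges), 570)  # 569.5 -> 570
  expect_equal(nrow(threshold_at_sparsity(r, 0.50)$edges), 1139)
  g <- threshold_at_sparsity(r, 0.20)
  expect_equal(g$sparsity, nrow(g$edges) / 2278)
  expect_equal(g$sparsity_target, 0.20)
})

test_that("edge sets are nested across ascending sparsities", {
  r <- make_test_matrix(seed = 2)
  key <- function(e) paste(e[, 1], e[, 2])
  prev <- character(0)
  for (s in sparsity_grid()) {
    cur <- key(threshold_at_sparsity(r, s)$edges)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("retained edges are exactly the strongest correlations", {
  r <- make_test_matrix(seed = 3)
  g <- threshold_at_sparsity(r, 0.10)
  vals_in <- r[g$edges]
  ut <- r[upper.tri(r)]
  cutoff <- sort(ut, decreasing = TRUE)[nrow(g$edges)]
  expect_true(min(vals_in) >= cutoff)
  expect_equal(sum(ut >= cutoff), nrow(g$edges))
})

test_that("signed ranking keeps strong negatives out; abs ranking keeps them", {
  r <- diag(0, 5)
  r[1, 2] <- r[2, 1] <- -0.99
  r[3, 4] <- r[4, 3] <- 0.50
  r[1, 5] <- r[5, 1] <- 0.40
  r[2, 5] <- r[5, 2] <- 0.30
  g_signed <- threshold_at_sparsity(r, 0.2)   # top 2 of 10 pairs
  expect_false(any(g_signed$edges[, 1] == 1 & g_signed$edges[, 2] == 2))
  g_abs <- threshold_at_sparsity(r, 0.2, edge_rank = "abs")
  expect_true(any(g_abs$edges[, 1] == 1 & g_abs$edges[, 2] == 2))
})

test_that("rank ties break lexicographically so edge sets are deterministic", {
  r <- diag(0, 4)
  r[upper.tri(r)] <- 0.5                      # all six pairs tie
  r <- r + t(r)
  g <- threshold_at_sparsity(r, 0.5)          # 3 edges
  expect_equal(unname(g$edges), rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
})

test_that("binary_graph validates its edge list", {
  expect_error(binary_graph(4, rbind(c(1, 1))), "self-loops")
  expect_error(binary_graph(4, rbind(c(1, 5))), "out of range")
  expect_error(binary_graph(4, rbind(c(1, 2), c(2, 1))), "duplicate")
  g <- binary_graph(4, rbind(c(3, 1)))        # endpoints get ordered
  expect_equal(unname(g$edges), rbind(c(1L, 3L)))
})

test_that("adjacency conversions round-trip", {
  r <- make_test_matrix(10, seed = 4)
  g <- threshold_at_sparsity(r, 0.3)
  a <- as_adjacency(g)
  expect_true(isSymmetric(unname(a)))
  g2 <- graph_from_adjacency(a)
  key <- function(e) sort(paste(e[, 1], e[, 2]))
  expect_equal(key(g2$edges), key(g$edges))
  expect_error(graph_from_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("min_connected_sparsity finds the one-edge connectivity threshold", {
  # hand-built 4-node matrix: strongest edges 1-2 (.9), 3-4 (.8), 1-3 (.7)
  r <- diag(0, 4)
  r[1, 2] <- r[2, 1] <- 0.9
  r[3, 4] <- r[4, 3] <- 0.8
  r[1, 3] <- r[3, 1] <- 0.7
  r[2, 4] <- r[4, 2] <- 0.1
  expect_equal(min_connected_sparsity(r), 3 / 6)   # connected after 3rd edge
  # spanning-tree lower bound 2/n always holds
  big <- make_test_matrix(seed = 5)
  expect_gte(min_connected_sparsity(big), 2 / 68)
})

test_that("sparsity_grid validates its range", {
  expect_equal(sparsity_grid(), seq(0.05, 0.50, 0.05))
  expect_error(sparsity_grid(0, 0.5, 0.05), "sparsity")
  expect_error(sparsity_grid(0.5, 0.05, 0.05), "increasing|by")
})
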