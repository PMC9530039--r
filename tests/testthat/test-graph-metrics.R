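path3 <- binary_graph(3, rbind(c(1, 2), c(2, 3)))
cycle4 <- binary_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
star5 <- binary_graph(5, cbind(1L, 2:5))
k4 <- binary_graph(4, t(combn(4, 2)))

test_that("shortest paths count multiplicities (4-cycle has two paths across)", {
  sp <- shortest_paths(cycle4)
  expect_equal(sp$d[1, 3], 2)
  expect_equal(sp$sigma[1, 3], 2)     # both ways around
  expect_equal(sp$sigma[1, 2], 1)
  expect_equal(unname(diag(sp$d)), rep(0, 4))
  # unreachable pair
  iso <- binary_graph(3, rbind(c(1, 2)))
  spi <- shortest_paths(iso)
  expect_equal(spi$d[1, 3], Inf)
  expect_equal(spi$sigma[1, 3], 0)
})

test_that("P3: center carries every cross pair (ordered-pair Bc = 1)", {
  m <- graph_metrics(path3)
  expect_equal(unname(m$Bc), c(0, 1, 0))
  expect_equal(unname(m$Nlp), c(1.5, 1, 1.5))
  expect_equal(m$L, mean(c(1.5, 1, 1.5)))
  expect_equal(unname(m$ci), c(0, 0, 0))      # k < 2 and no triangles
})

test_that("4-cycle: Nlp = 4/3, Eglob = 5/6, Bc = 1/6 everywhere", {
  m <- graph_metrics(cycle4)
  expect_equal(unname(m$Nlp), rep(4 / 3, 4))
  expect_equal(m$Eglob, 5 / 6)
  expect_equal(unname(m$Bc), rep(1 / 6, 4))
  expect_equal(m$C, 0)
  expect_equal(m$Eloc, 0)
  expect_true(m$connected)
})

test_that("star: center Bc = 1, leaves 0; Eloc = 0; C = 0", {
  m <- graph_metrics(star5)
  expect_equal(unname(m$Bc), c(1, 0, 0, 0, 0))
  expect_equal(m$C, 0)
  expect_equal(m$Eloc, 0)
  expect_equal(unname(m$k), c(4, 1, 1, 1, 1))
  expect_equal(unname(m$Nlp), c(1, 7 / 4, 7 / 4, 7 / 4, 7 / 4))
})

test_that("complete graph: C = L = Eglob = Eloc = 1, Bc = 0", {
  m <- graph_metrics(k4)
  expect_equal(m$C, 1)
  expect_equal(m$L, 1)
  expect_equal(m$Eglob, 1)
  expect_equal(m$Eloc, 1)
  expect_equal(unname(m$Bc), rep(0, 4))
  expect_equal(unname(m$t), rep(3L, 4))
})

test_that("disconnected graphs: reachable-pair means, flags, NaN isolates", {
  g <- binary_graph(4, rbind(c(1, 2)))        # edge + two isolates
  nlp <- nodal_path_length(g)
  expect_equal(unname(nlp[1:2]), c(1, 1))
  expect_true(all(is.nan(nlp[3:4])))
  expect_false(attr(nlp, "connected"))
  expect_equal(as.numeric(char_path_length(g)), 1)  # mean over nodes with reach
  eg <- global_efficiency(g)
  expect_equal(eg$eglob, mean(c(1 / 3, 1 / 3, 0, 0)))  # 1/d -> 0 convention
  expect_equal(global_efficiency(binary_graph(2, matrix(0L, 0, 2)))$eglob, 0)
})

test_that("betweenness requires n >= 3 and metrics carry region names", {
  expect_error(betweenness_centrality(binary_graph(2, rbind(c(1, 2)))), "n < 3")
  g <- binary_graph(3, rbind(c(1, 2), c(2, 3)), regions = c("a", "b", "c"))
  expect_equal(names(betweenness_centrality(g)), c("a", "b", "c"))
  expect_equal(names(graph_metrics(g)$Nlp), c("a", "b", "c"))
})

test_that("compiled metrics match the brute-force oracles on random graphs", {
  withr::with_seed(11, {
    for (rep in 1:40) {
      n <- sample(4:8, 1)
      a <- random_adjacency(n, runif(1, 0.25, 0.9))
      g <- graph_from_adjacency(a)
      m <- graph_metrics(g)
      expect_identical(unname(m$k), as.integer(oracle_degree(a)))
      expect_identical(unname(m$t), as.integer(oracle_triangles(a)))
      orc <- oracle_clustering(a)
      expect_equal(unname(m$ci), orc$ci, tolerance = 1e-10)
      expect_equal(m$C, orc$c_mean, tolerance = 1e-10)
      expect_equal(unname(m$Nlp), oracle_nlp(a), tolerance = 1e-10)
      expect_equal(m$L, oracle_L(a), tolerance = 1e-10)
      expect_equal(unname(m$Bc), oracle_betweenness(a), tolerance = 1e-10)
      expect_equal(m$Eglob, oracle_eglob(a)$eglob, tolerance = 1e-10)
      expect_equal(m$Eloc, oracle_eloc(a)$eloc, tolerance = 1e-10)
    }
  })
})

test_that("compiled metrics agree with igraph on a mid-sized random graph", {
  withr::with_seed(8, a <- random_adjacency(30, 0.2))
  g <- graph_from_adjacency(a)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  m <- graph_metrics(g)
  expect_equal(unname(m$k), unname(igraph::degree(ig)))
  # igraph betweenness counts unordered pairs; ours sums ordered pairs and
  # normalizes by (n-1)(n-2)
  expect_equal(unname(m$Bc),
               unname(2 * igraph::betweenness(ig) / (29 * 28)),
               tolerance = 1e-10)
  ci_ig <- igraph::transitivity(ig, type = "local", isolates = "zero")
  expect_equal(unname(m$ci), ci_ig, tolerance = 1e-10)
  d_ig <- igraph::distances(ig)
  expect_equal(unname(m$Nlp),
               unname(vapply(1:30, function(i) {
                 dd <- d_ig[i, -i]
                 mean(dd[is.finite(dd)])
               }, numeric(1))), tolerance = 1e-10)
})
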