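test_that("auc_trapz computes the trapezoid rule on the sparsity grid", {
  grid <- sparsity_grid()
  expect_equal(auc_trapz(rep(1, 10), grid), 0.45)
  expect_equal(auc_trapz(grid, grid), (0.50^2 - 0.05^2) / 2)  # exact for linear
  expect_equal(auc_trapz(c(0, 1), c(0, 1)), 0.5)
  expect_error(auc_trapz(1:3, grid), "lengths differ")
  expect_error(auc_trapz(1, 0.3), "two grid points")
  expect_true(is.na(auc_trapz(c(1, NaN, 1, 1, 1, 1, 1, 1, 1, 1), grid)))
})

test_that("metric_curves agrees with the single-graph R implementations", {
  co <- generate_cohort(cohort_spec(seed = 6))
  hc <- co[co$group == "HC", ]
  r <- correlation_matrix(make_windows(hc)[[5]], hc)
  cfg <- scn_config(grid = c(0.15, 0.30, 0.45), n_null = 10,
                    modularity_restarts = 4, seed = 2)
  mp <- metric_curves(r, cfg, seed = 2)

  expect_equal(mp$edge_counts,
               scnet:::round_half_up(cfg$grid * 68 * 67 / 2))
  for (ti in seq_along(cfg$grid)) {
    g <- threshold_at_sparsity(r, cfg$grid[ti])
    m <- graph_metrics(g)
    expect_equal(unname(mp$global[ti, "C"]), m$C, tolerance = 1e-12)
    expect_equal(unname(mp$global[ti, "L"]),
                 as.numeric(m$L), tolerance = 1e-12)
    expect_equal(unname(mp$global[ti, "Eglob"]), m$Eglob, tolerance = 1e-12)
    expect_equal(unname(mp$global[ti, "Eloc"]), m$Eloc, tolerance = 1e-12)
    expect_equal(unname(mp$nodal$Nlp[, ti]), unname(m$Nlp), tolerance = 1e-12)
    expect_equal(unname(mp$nodal$Bc[, ti]), unname(m$Bc), tolerance = 1e-12)
    expect_equal(mp$connected[ti], m$connected)
  }
  # Q from the batch path is a valid modularity value for this graph: it can
  # never exceed a many-restart reference run, and must be positive here
  g2 <- threshold_at_sparsity(r, 0.15)
  ref <- modularity_partition(g2, restarts = 30, seed = 9)
  expect_lte(mp$global[1, "Q"], ref$Q + 1e-9)
  expect_gt(mp$global[1, "Q"], 0)
  # AUCs are the trapezoids of the curves
  expect_equal(unname(mp$auc_global["C"]),
               auc_trapz(mp$global[, "C"], cfg$grid))
  expect_equal(unname(mp$auc_nodal$Bc[3]),
               auc_trapz(mp$nodal$Bc[3, ], cfg$grid))
})

test_that("normalized metrics from the batch path sit in the expected regime", {
  co <- generate_cohort(cohort_spec(seed = 6))
  hc <- co[co$group == "HC", ]
  r <- correlation_matrix(make_windows(hc)[[1]], hc)
  cfg <- scn_config(grid = c(0.2, 0.3), n_null = 20, seed = 3)
  mp <- metric_curves(r, cfg, seed = 3)
  sw <- small_world(threshold_at_sparsity(r, 0.2), n_null = 50, seed = 4)
  # two independent surrogate ensembles: same gamma up to Monte Carlo noise
  expect_equal(unname(mp$global[1, "gamma"]), sw$gamma, tolerance = 0.1)
  expect_equal(unname(mp$global[1, "lambda"]), sw$lambda, tolerance = 0.05)
  expect_equal(unname(mp$global[, "sigma"]),
               unname(mp$global[, "gamma"] / mp$global[, "lambda"]),
               tolerance = 1e-12)
})

test_that("metric curves are reproducible and seed-sensitive", {
  co <- generate_cohort(cohort_spec(seed = 6))
  hc <- co[co$group == "HC", ]
  r <- correlation_matrix(make_windows(hc)[[1]], hc)
  cfg <- scn_config(grid = c(0.2, 0.3), n_null = 10, seed = 3)
  expect_identical(metric_curves(r, cfg, seed = 3),
                   metric_curves(r, cfg, seed = 3))
  a <- metric_curves(r, cfg, seed = 3)$global[, "gamma"]
  b <- metric_curves(r, cfg, seed = 4)$global[, "gamma"]
  expect_false(identical(a, b))
})

test_that("cohort_aucs yields one AUC row per window, per group", {
  co <- generate_cohort(cohort_spec(seed = 6))
  cfg <- scn_config(grid = c(0.2, 0.3, 0.4),
                    global_metrics = c("C", "Eglob"),
                    nodal_metrics = "Bc", seed = 1)
  aucs <- cohort_aucs(co, cfg, seed = 1)
  expect_setequal(aucs$groups, unique(as.character(co$group)))
  expect_equal(unname(aucs$window_counts[c("cARTpos", "cARTneg", "HC")]),
               c(25, 22, 26))
  expect_equal(dim(aucs$global$HC), c(26, 2))
  expect_equal(dim(aucs$nodal$HC$Bc), c(26, 68))
  expect_true(all(is.finite(aucs$global$HC)))
})

test_that("scn_config validates metric names and null sizes", {
  expect_error(scn_config(global_metrics = "bogus"), "unknown global metric")
  expect_error(scn_config(nodal_metrics = "Qx"), "unknown nodal metric")
  expect_error(scn_config(global_metrics = "gamma", n_null = 0), "n_null")
  cfg <- scn_config(global_metrics = c("C", "Q"))   # no surrogates needed
  expect_equal(cfg$n_null, 0L)
})
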