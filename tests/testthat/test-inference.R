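test_that("anova_auc matches the textbook one-way F", {
  withr::with_seed(1, {
    groups <- list(rnorm(8), rnorm(6, 0.5), rnorm(7, 1))
  })
  f <- anova_auc(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(letters[1:3], lengths(groups)))
  ref <- anova(lm(y ~ g, df))[["F value"]][1]
  expect_equal(f, ref, tolerance = 1e-12)
  expect_error(anova_auc(list(1:5)), "two groups")
  expect_error(anova_auc(list(1:5, 3)), "insufficient data")
  # zero within-variance conventions
  expect_identical(anova_auc(list(c(1, 1), c(2, 2))), Inf)
  expect_identical(anova_auc(list(c(1, 1), c(1, 1))), 0)
})

test_that("posthoc_t matches t.test(var.equal = TRUE), first minus second", {
  withr::with_seed(2, {
    a <- rnorm(9)
    b <- rnorm(11, 0.8)
  })
  expect_equal(posthoc_t(a, b),
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  expect_lt(posthoc_t(a, b), 0)           # a is lower on average
  expect_identical(posthoc_t(c(1, 1), c(2, 2)), -Inf)
  expect_identical(posthoc_t(c(2, 2), c(2, 2)), 0)
  expect_error(posthoc_t(1, c(1, 2)), ">= 2 values")
})

test_that("vectorized row statistics equal per-row loops, with NA rows", {
  withr::with_seed(3, {
    m1 <- matrix(rnorm(50), 10)
    m2 <- matrix(rnorm(40, 0.3), 10)
    m3 <- matrix(rnorm(60), 10)
  })
  m1[4, 2] <- NA
  f <- scnet:::fstat_rows(list(m1, m2, m3))
  t12 <- scnet:::tstat_rows(m1, m2)
  for (i in (1:10)[-4]) {
    expect_equal(f[i], anova_auc(list(m1[i, ], m2[i, ], m3[i, ])),
                 tolerance = 1e-10)
    expect_equal(t12[i], posthoc_t(m1[i, ], m2[i, ]), tolerance = 1e-10)
  }
  expect_true(is.na(f[4]))
  expect_true(is.na(t12[4]))
})

test_that("perm_pvalue implements the add-one rule", {
  expect_equal(perm_pvalue(5, rep(0, 99)), 1 / 100)
  expect_equal(perm_pvalue(0, rep(5, 99)), 1)
  expect_equal(perm_pvalue(2, c(1, 3, -2.5)), 3 / 4)   # two-sided via |.|
  expect_true(is.na(perm_pvalue(NA, 1:5)))
  expect_error(perm_pvalue(1, numeric(0)), "n_perm")
})

test_that("fdr_correct reproduces step-up BH", {
  expect_equal(fdr_correct(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  withr::with_seed(4, p <- runif(40)^2)
  expect_equal(fdr_correct(p), oracle_bh(p), tolerance = 1e-12)
  expect_error(fdr_correct(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(fdr_correct(c(0.01, NA)), p.adjust(c(0.01, NA), "BH"))
})

small_cfg <- scn_config(width = 10, step = 3, grid = c(0.2, 0.35),
                        global_metrics = c("C", "Eglob"),
                        nodal_metrics = "Bc", n_perm = 9, seed = 1)

test_that("compare_groups returns a complete, FDR-corrected comparison table", {
  spec <- cohort_spec(group_names = c("A", "B"), group_sizes = c(16, 16),
                      seed = 12)
  co <- generate_cohort(spec)
  cmp <- compare_groups(co, small_cfg, n_perm = 9, seed = 2)
  d <- as.data.frame(cmp)
  # cells: 2 global + 68 Bc nodes, each with F and one contrast
  expect_equal(nrow(d), (2 + 68) * 2)
  expect_setequal(unique(d$contrast), c("F", "A vs B"))
  expect_true(all(d$p_perm >= 1 / 10 & d$p_perm <= 1, na.rm = TRUE))
  expect_true(all(d$q_fdr >= d$p_perm - 1e-12, na.rm = TRUE))
  expect_true(all(is.na(d$direction[d$contrast == "F"])))
  expect_true(all(d$direction[d$contrast != "F"] %in% c(-1, 0, 1), na.rm = TRUE))
  # q-values are BH within families (global together, nodes per metric)
  glob_rows <- d$node == "global" & d$contrast == "F"
  expect_equal(d$q_fdr[glob_rows], fdr_correct(d$p_perm[glob_rows]))
  bc_rows <- d$metric == "Bc" & d$contrast == "A vs B"
  expect_equal(d$q_fdr[bc_rows], fdr_correct(d$p_perm[bc_rows]))
  expect_equal(attr(cmp, "n_perm"), 9)
})

test_that("compare_groups is reproducible and label-order invariant", {
  spec <- cohort_spec(group_names = c("A", "B"), group_sizes = c(14, 14),
                      seed = 13)
  co <- generate_cohort(spec)
  c1 <- compare_groups(co, small_cfg, n_perm = 9, seed = 5)
  c2 <- compare_groups(co, small_cfg, n_perm = 9, seed = 5)
  expect_identical(c1, c2)
  # shuffling subject rows must not change observed statistics
  co_shuf <- co[sample(nrow(co)), ]
  c3 <- compare_groups(co_shuf, small_cfg, n_perm = 9, seed = 5)
  expect_equal(c3$statistic, c1$statistic, tolerance = 1e-12)
})

test_that("statistics are invariant under affine rescaling of thickness", {
  spec <- cohort_spec(group_names = c("A", "B"), group_sizes = c(14, 14),
                      seed = 14)
  co <- generate_cohort(spec)
  co2 <- co
  regs <- dk_atlas()$label
  co2[, regs] <- co2[, regs] * 3.7 + 0.9   # correlations unchanged
  c1 <- compare_groups(co, small_cfg, n_perm = 9, seed = 6)
  c2 <- compare_groups(co2, small_cfg, n_perm = 9, seed = 6)
  expect_equal(c1$statistic, c2$statistic, tolerance = 1e-9)
  expect_equal(c1$p_perm, c2$p_perm)
})

test_that("compare_groups rejects degenerate requests", {
  co <- generate_cohort(cohort_spec(group_names = "only", group_sizes = 14,
                                    seed = 15))
  expect_error(compare_groups(co, small_cfg), "two groups")
  co2 <- generate_cohort(cohort_spec(group_names = c("A", "B"),
                                     group_sizes = c(14, 14), seed = 15))
  expect_error(compare_groups(co2, small_cfg, n_perm = 0), "n_perm")
})
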