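test_that("generate_cohort draws the specified design, reproducibly", {
  spec <- cohort_spec(seed = 42)
  co <- generate_cohort(spec)
  expect_s3_class(co, "scn_cohort")
  expect_equal(nrow(co), 100)
  expect_equal(ncol(co), 4 + 68)
  expect_equal(as.vector(table(factor(co$group,
                                      levels = c("cARTpos", "cARTneg", "HC")))),
               c(34, 31, 35))
  expect_equal(anyDuplicated(co$subject_id), 0)
  expect_true(all(co$age >= 25 & co$age <= 50))
  expect_equal(co$age, round(co$age, 1))
  expect_true(all(co$sex %in% c("M", "F")))
  # strict positivity of every thickness value
  thick <- as.matrix(co[, dk_atlas()$label])
  expect_true(all(thick > 0))
  # bit-identical regeneration under the same seed
  expect_identical(co, generate_cohort(cohort_spec(seed = 42)))
  # different seed, different data
  expect_false(identical(co, generate_cohort(cohort_spec(seed = 43))))
})

test_that("cohort_spec rejects invalid designs with named-field messages", {
  expect_error(cohort_spec(group_sizes = c(10, 10)), "group_sizes")
  expect_error(cohort_spec(group_names = c("A", "A", "B")), "group_names")
  expect_error(cohort_spec(age_range = c(50, 25)), "age_range")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(within_module_load = 1.2), "within_module_load")
  expect_error(cohort_spec(within_module_load = 0.9, cross_module_load = 0.6),
               "within_module_load")
  expect_error(cohort_spec(baseline_mean = -1), "baseline_mean")
})

test_that("factor loads reproduce the implied within-module correlation", {
  # single group, many subjects: empirical within-module correlation must
  # approach (w^2 + c^2) / (w^2 + c^2 + sigma^2)
  w <- 0.8; cc <- 0; sig <- 0.36
  # age_slope = 0: the age trend is a confounder common to all regions and
  # would inflate every pairwise correlation (the sliding window controls it
  # in the real pipeline)
  spec <- cohort_spec(group_names = "G", group_sizes = 5000,
                      within_module_load = w, cross_module_load = cc,
                      noise_sd = sig, age_slope = 0, seed = 9)
  co <- generate_cohort(spec)
  comm <- atlas_communities()
  regs <- names(comm)[comm == 1][1:6]
  r <- cor(as.matrix(co[, regs]))
  expected <- (w^2 + cc^2) / (w^2 + cc^2 + sig^2)   # 0.8316
  expect_equal(mean(r[upper.tri(r)]), expected, tolerance = 0.02)
  # cross-module correlation should be ~0 when cross load is 0
  other <- names(comm)[comm == 2][1:6]
  r2 <- cor(as.matrix(co[, regs]), as.matrix(co[, other]))
  expect_lt(max(abs(r2)), 0.1)
})

test_that("age slope induces the configured thinning trend", {
  spec <- cohort_spec(group_names = "G", group_sizes = 2000,
                      age_slope = -0.01, seed = 10)
  co <- generate_cohort(spec)
  slope <- coef(lm(co[[dk_atlas()$label[1]]] ~ co$age))[2]
  expect_lt(abs(unname(slope) - (-0.01)), 0.002)
})

test_that("validate_cohort collects all problems with row/column pointers", {
  co <- generate_cohort(cohort_spec(seed = 3))
  expect_length(validate_cohort(co), 0)

  bad <- co
  bad$subject_id[2] <- bad$subject_id[1]
  bad[[dk_atlas()$label[5]]][7] <- -1
  bad$age[3] <- NA
  errs <- validate_cohort(bad)
  expect_true(any(grepl("duplicate subject_id", errs)))
  expect_true(any(grepl("row 7", errs)))
  expect_true(any(grepl("age", errs)))

  bad2 <- co[, setdiff(names(co), c("sex", dk_atlas()$label[1]))]
  errs2 <- validate_cohort(bad2)
  expect_true(any(grepl("missing metadata column 'sex'", errs2)))
  expect_true(any(grepl(dk_atlas()$label[1], errs2, fixed = TRUE)))
})

test_that("cohort TSV round-trips losslessly", {
  co <- generate_cohort(cohort_spec(seed = 5))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(as.matrix(back[, dk_atlas()$label]),
               as.matrix(co[, dk_atlas()$label]), tolerance = 1e-12)
  expect_error(read_cohort(tempfile()), "not found")
})
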