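test_that("trials are deterministic and order-independent given the seed", {
  cfg <- tiny_config(design = "individual_pf", seed = 71L)
  a <- run_trial(cfg, iteration = 5L)
  b <- run_trial(cfg, iteration = 5L)
  expect_identical(a, b)
  # precomputed stream and on-the-fly derivation agree
  s <- trial_streams(cfg$seed, 6L)
  c_ <- run_trial(cfg, iteration = 5L, stream = s[[5L]])
  expect_identical(a, c_)
  # different iterations differ
  expect_false(identical(a$p_crude_lm, run_trial(cfg, 6L)$p_crude_lm))
})

test_that("each design populates exactly its models' p-values", {
  grp <- run_trial(tiny_config(design = "group_pf"))
  expect_setequal(grep("^p_", names(grp), value = TRUE),
                  c("p_crude_lm", "p_adjusted_lm"))
  ind <- run_trial(tiny_config(design = "individual_pf"))
  expect_setequal(grep("^p_", names(ind), value = TRUE),
                  c("p_crude_lm", "p_pair_lmm", "p_adjusted_lm",
                    "p_pair_lmm_adjusted"))
  expect_true(all(vapply(ind[grep("^p_", names(ind))], function(p)
    p >= 0 && p <= 1, logical(1))))
})

test_that("the chi-square test against nominal alpha matches known values", {
  # observed equals expected
  eq <- test_against_nominal(500, 10000, 0.05)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # hand-checkable count
  chi <- test_against_nominal(626, 10000, 0.05)
  expect_equal(chi$p_value, 7.414e-09, tolerance = 1e-3)
  # extreme inflation
  expect_lt(test_against_nominal(4251, 10000, 0.05)$p_value, 2.2e-16)
  # base-R chisq.test as independent oracle
  for (x in c(626, 475, 1155, 494, 6943, 1720)) {
    oracle <- suppressWarnings(
      chisq.test(c(x, 10000 - x), p = c(0.05, 0.95)))
    got <- test_against_nominal(x, 10000, 0.05)
    expect_equal(got$statistic, unname(oracle$statistic))
    expect_equal(got$p_value, oracle$p.value)
    # significance classification agrees with the exact binomial test
    exact <- binom.test(x, 10000, 0.05)
    expect_equal(got$p_value < 0.001, exact$p.value < 0.001)
  }
  expect_error(test_against_nominal(5, 0), "n_reps")
  expect_error(test_against_nominal(11, 10), "rejections")
})

test_that("t1er summaries count rejections exactly", {
  cfg <- tiny_config(seed = 72L, n_reps = 120L)
  est <- estimate_t1er(cfg)
  expect_equal(est$summary$t1er,
               est$summary$rejections / est$summary$n_reps)
  for (tag in est$summary$model) {
    expect_equal(est$summary$rejections[est$summary$model == tag],
                 sum(est$results[[paste0("p_", tag)]] < cfg$alpha))
  }
  # reproducible: the whole summary is identical across runs
  expect_identical(est$summary, estimate_t1er(cfg)$summary)
  expect_error(estimate_t1er(cfg, n_reps = 50L), "at least 100")
})

test_that("p-values are uniform when truncation is disabled", {
  cfg <- design_config(m_per_group = 8L, n_days = 5L, truncation = FALSE,
                       seed = 73L)
  est <- estimate_t1er(cfg, models = "crude_lm", n_reps = 400L)
  ks <- ks.test(est$results$p_crude_lm, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("design comparison finds the larger individual deficit", {
  cfg_g <- design_config(m_per_group = 8L, n_days = 10L,
                         design = "group_pf", seed = 74L)
  cfg_i <- design_config(m_per_group = 8L, n_days = 10L,
                         design = "individual_pf", seed = 75L)
  cmp <- compare_designs(cfg_g, cfg_i, n_reps = 300L)
  expect_length(cmp$diffs_group, 300L)
  expect_length(cmp$diffs_individual, 300L)
  # pair-feeding only ever removes intake
  expect_lt(cmp$means[["group_pf"]], 0)
  expect_lt(cmp$means[["individual_pf"]], cmp$means[["group_pf"]])
  expect_lt(cmp$t_test$p.value, 0.01)
  # mismatched scenarios are rejected
  cfg_bad <- design_config(m_per_group = 4L, n_days = 10L,
                           design = "individual_pf")
  expect_error(compare_designs(cfg_g, cfg_bad), "share")
})

test_that("design comparison is null-centered without truncation", {
  cfg_g <- design_config(m_per_group = 6L, n_days = 8L, design = "group_pf",
                         truncation = FALSE, seed = 76L)
  cfg_i <- design_config(m_per_group = 6L, n_days = 8L,
                         design = "individual_pf", truncation = FALSE,
                         seed = 77L)
  cmp <- compare_designs(cfg_g, cfg_i, n_reps = 300L)
  se <- cmp$sds / sqrt(300)
  expect_lt(abs(cmp$means[["group_pf"]]), 3 * se[["group_pf"]])
  expect_lt(abs(cmp$means[["individual_pf"]]), 3 * se[["individual_pf"]])
  expect_gt(cmp$t_test$p.value, 0.01)
})

test_that("summary tables assemble and round-trip losslessly", {
  cfg1 <- tiny_config(seed = 78L)
  cfg2 <- design_config(m_per_group = 3L, n_days = 4L, seed = 79L)
  est1 <- estimate_t1er(cfg1, n_reps = 100L)
  est2 <- estimate_t1er(cfg2, n_reps = 100L)
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- render_tables(list(est1, est2), path = csv)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("design", "n_animals", "n_days", "Model_1",
                      "p_value_1", "Model_2", "p_value_2"))
  expect_equal(tab$Model_1, c(est1$summary$t1er[1], est2$summary$t1er[1]))
  expect_true(file.exists(csv))
  json <- withr::local_tempfile(fileext = ".json")
  write_table_json(tab, json)
  expect_equal(read_table_json(json), tab)
})

test_that("the full-grid runner writes tables and a manifest", {
  out <- withr::local_tempdir()
  res <- reproduce_tables(seed = 80L, n_reps = 100L, out_dir = out,
                          designs = "group_pf", n_animals_grid = 8L,
                          n_days_grid = 3L, progress = FALSE)
  expect_length(res, 1L)
  expect_true(file.exists(file.path(out, "group_pf_t1er.csv")))
  expect_true(file.exists(file.path(out, "group_pf_t1er.json")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 80L)
  expect_equal(manifest$scenarios[[1]]$n_animals, 8L)
  expect_equal(manifest$scenarios[[1]]$rejections$Model_1,
               res[[1]]$summary$rejections[1])
})
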