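test_that("weight-rank pairing matches ascending ranks across groups", {
  cohort <- manual_cohort(
    weights = c(32.0, 34.0, 33.0, 31.0, 35.0, 33.5),
    intakes = rep(13.3, 6),
    groups = c("pf", "pf", "pf", "non_pf", "non_pf", "non_pf")
  )
  pairs <- pair_by_weight(cohort)
  got <- data.frame(pf_w = cohort$weight0[pairs$pf_id],
                    np_w = cohort$weight0[pairs$non_pf_id])
  expect_equal(got$pf_w, c(32.0, 33.0, 34.0))
  expect_equal(got$np_w, c(31.0, 33.5, 35.0))
})

test_that("pairing is a rank-monotone bijection for any cohort", {
  set.seed(21)
  for (i in 1:10) {
    cohort <- draw_baseline(design_config(m_per_group = 7L, n_days = 1L))
    pairs <- pair_by_weight(cohort)
    expect_setequal(pairs$pf_id,
                    cohort$animal_id[cohort$group == "pf"])
    expect_setequal(pairs$non_pf_id,
                    cohort$animal_id[cohort$group == "non_pf"])
    # ascending weights on both sides of the match
    expect_false(is.unsorted(cohort$weight0[pairs$pf_id]))
    expect_false(is.unsorted(cohort$weight0[pairs$non_pf_id]))
  }
  unbal <- manual_cohort(1:4, rep(13, 4), c("pf", "pf", "pf", "non_pf"))
  expect_error(pair_by_weight(unbal), "unbalanced")
})

test_that("proposal intakes are iid draws from the baseline distribution", {
  set.seed(22)
  expect_true(all(generate_proposals(tiny_config(sigma_f = 0)) == 13.3))
  big <- generate_proposals(design_config(m_per_group = 500L, n_days = 1000L))
  expect_lt(abs(mean(big) - 13.3), 0.01)
  # day-to-day independence: per-animal lag-1 autocorrelation near zero
  ac <- apply(big[1:20, ], 1L, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(max(abs(ac)), 4 / sqrt(999))
})

test_that("group truncation caps at the previous day's non-pf mean", {
  cohort <- manual_cohort(weights = 31:34, intakes = c(13.2, 13.4, 13.0, 13.6),
                          groups = c("pf", "non_pf", "pf", "non_pf"))
  cfg <- design_config(m_per_group = 2L, n_days = 3L)
  # non-pf rows are animals 2 and 4; mean baseline = 13.5
  proposals <- rbind(c(13.5, 13.0, 14.0),
                     c(13.8, 13.1, 13.3),
                     c(13.3, 13.9, 13.2),
                     c(13.6, 13.5, 13.9))
  intakes <- apply_group_pf(proposals, cohort, cfg)
  # caps: day1 = mean(13.4, 13.6) = 13.5; day2 = mean(13.8, 13.6) = 13.7;
  # day3 = mean(13.1, 13.5) = 13.3
  expect_equal(intakes$realized[1, ], c(13.5, 13.0, 13.3))
  expect_equal(intakes$realized[3, ], c(13.3, 13.7, 13.2))
  # non-pair-fed rows exactly the proposals
  expect_identical(intakes$realized[c(2, 4), ], proposals[c(2, 4), ])
})

test_that("individual truncation caps at the partner's previous-day intake", {
  cohort <- manual_cohort(weights = c(31, 32, 33, 34),
                          intakes = c(13.2, 13.4, 13.0, 13.6),
                          groups = c("pf", "non_pf", "pf", "non_pf"))
  cfg <- design_config(m_per_group = 2L, n_days = 2L,
                       design = "individual_pf")
  pairs <- pair_by_weight(cohort)  # 31<->32 (ids 1,2), 33<->34 (ids 3,4)
  proposals <- rbind(c(13.5, 13.1),
                     c(13.3, 13.2),
                     c(13.4, 13.9),
                     c(13.8, 13.5))
  intakes <- apply_individual_pf(proposals, pairs, cohort, cfg)
  # animal 1 capped by partner 2: day1 cap 13.4 (baseline), day2 cap 13.3
  expect_equal(intakes$realized[1, ], c(13.4, 13.1))
  # animal 3 capped by partner 4: day1 cap 13.6, day2 cap 13.8
  expect_equal(intakes$realized[3, ], c(13.4, 13.8))
  expect_identical(intakes$realized[c(2, 4), ], proposals[c(2, 4), ])
  expect_error(apply_individual_pf(proposals, NULL, cohort, cfg), "pairing")
})

test_that("truncation satisfies the min rule exactly and never cascades", {
  set.seed(23)
  for (design in c("group_pf", "individual_pf")) {
    cfg <- design_config(m_per_group = 6L, n_days = 8L, design = design)
    trial <- simulate_trial(cfg, iteration = 1L)
    intk <- trial$intakes
    expect_equal(intk$realized, pmin(intk$proposals, intk$cap))
    expect_true(all(intk$realized <= intk$cap))
    np <- trial$cohort$group == "non_pf"
    expect_identical(intk$realized[np, ], intk$proposals[np, ])
  }
})

test_that("disabling truncation reproduces the proposals bit-for-bit", {
  for (design in c("group_pf", "individual_pf")) {
    cfg <- design_config(m_per_group = 5L, n_days = 6L, design = design,
                         truncation = FALSE, seed = 7L)
    trial <- simulate_trial(cfg, iteration = 2L)
    expect_identical(trial$intakes$realized, trial$intakes$proposals)
    expect_true(all(is.infinite(trial$intakes$cap)))
  }
})

test_that("long-run truncated means match the closed forms", {
  # Independent oracle: E[min(X, C)] for independent normals with equal
  # means is mu - sqrt(var_X + var_C) / sqrt(2*pi).
  mu <- 13.3; s <- 0.3; m <- 40L
  expected_ind <- mu - s * sqrt(2) / sqrt(2 * pi)     # = mu - s/sqrt(pi)
  expected_grp <- mu - sqrt(s^2 * (1 + 1 / m)) / sqrt(2 * pi)
  set.seed(24)
  mc_oracle <- mean(pmin(rnorm(2e5, mu, s), rnorm(2e5, mu, s / sqrt(m))))
  expect_lt(abs(mc_oracle - expected_grp), 0.005)

  cfg_i <- design_config(m_per_group = m, n_days = 400L,
                         design = "individual_pf", seed = 31L)
  trial_i <- simulate_trial(cfg_i)
  pf <- trial_i$cohort$group == "pf"
  expect_lt(abs(mean(trial_i$intakes$realized[pf, ]) - expected_ind), 0.01)

  cfg_g <- design_config(m_per_group = m, n_days = 400L,
                         design = "group_pf", seed = 32L)
  trial_g <- simulate_trial(cfg_g)
  pf <- trial_g$cohort$group == "pf"
  expect_lt(abs(mean(trial_g$intakes$realized[pf, ]) - expected_grp), 0.01)
})

test_that("the audit table is a faithful long-format view", {
  cfg <- tiny_config(design = "individual_pf")
  trial <- simulate_trial(cfg)
  tab <- intake_frame(trial$intakes)
  expect_equal(nrow(tab), 8L * 5L)
  expect_named(tab, c("animal_id", "group", "day", "proposal", "realized",
                      "cap"))
  i <- tab$animal_id == 3 & tab$day == 2
  expect_equal(tab$realized[i], trial$intakes$realized[3, 2])
  expect_equal(tab$proposal[i], trial$intakes$proposals[3, 2])
})
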