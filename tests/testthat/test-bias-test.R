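test_that("make_null_pair returns a zero-I^2 pair deterministically", {
  cfg <- bias_test_config(seed = 7)
  pair <- make_null_pair(82, 75, 95, cfg)
  expect_equal(round(pair$null_i_squared), 0)
  expect_lte(pair$attempts_used, cfg$max_null_attempts)
  expect_equal(pair$sct_1$n_total, 82L)

  again <- make_null_pair(82, 75, 95, cfg)
  expect_identical(again$sct_1$data, pair$sct_1$data)
  expect_identical(again$attempts_used, pair$attempts_used)
})

test_that("a degenerate constant range forces a first-attempt null pair", {
  pair <- make_null_pair(4, 50, 50, bias_test_config(seed = 1))
  expect_equal(pair$attempts_used, 1L)
  expect_equal(pair$null_i_squared, 0)
  # constant values: both mean differences are exactly zero
  expect_equal(diff(pair$sct_1$arm_summaries$mean), 0)
  expect_equal(diff(pair$sct_2$arm_summaries$mean), 0)
})

test_that("make_null_pair fails loudly when no pair can qualify", {
  # this seed's first generated pair is heterogeneous, so a one-attempt
  # budget cannot produce a qualifying pair
  cfg1 <- bias_test_config(seed = 110, max_null_attempts = 1)
  err <- tryCatch(make_null_pair(12, 18, 80, cfg1), error = function(e) e)
  expect_s3_class(err, "sctbias_domain_error")
  expect_match(conditionMessage(err), "attempted I\\^2 values")
  # a two-attempt budget recovers
  cfg2 <- bias_test_config(seed = 110, max_null_attempts = 100)
  pair <- make_null_pair(12, 18, 80, cfg2)
  expect_gt(pair$attempts_used, 1L)
})

test_that("a balanced RCT tests negative and a shifted cohort positive", {
  rct <- trial_baseline("balanced", 81.30, 4.80, 41, 81.30, 4.80, 41, 75, 95)
  res <- run_bias_test(rct, bias_test_config(seed = 11))
  expect_equal(res$result, 0L)
  expect_equal(res$bias_risk, "N")
  expect_equal(res$null_i_squared_rounded, 0L)
  expect_equal(res$n_t, 82L)

  cohort <- trial_baseline("shifted", 64.22, 12, 31, 50.73, 14, 30, 18, 80)
  res2 <- run_bias_test(cohort, bias_test_config(seed = 11))
  expect_equal(res2$result, 1L)
  expect_equal(res2$bias_risk, "Y")
  expect_gt(res2$combined_i_squared, 0)

  # determinism of the whole test
  res3 <- run_bias_test(cohort, bias_test_config(seed = 11))
  expect_equal(res3$combined_i_squared, res2$combined_i_squared)
  expect_equal(res3$attempts_used, res2$attempts_used)
})

test_that("a trial coinciding with one comparator adds no heterogeneity", {
  pair <- make_null_pair(60, 18, 80, bias_test_config(seed = 3))
  summ <- pair$sct_1$arm_summaries
  a <- summ[summ$arm == "A", ]
  b <- summ[summ$arm == "B", ]
  trial <- trial_baseline("coincident", a$mean, a$sd, a$n,
                          b$mean, b$sd, b$n, 18, 80)
  sct_summaries <- dplyr::bind_rows(
    dplyr::mutate(pair$sct_1$arm_summaries, trial_id = "coincident", sct = 1),
    dplyr::mutate(pair$sct_2$arm_summaries, trial_id = "coincident", sct = 2)
  )
  res <- run_bias_test_with_scts(trial, sct_summaries)
  expect_equal(res$result, 0L)
  expect_equal(res$combined_i_squared_rounded, res$null_i_squared_rounded)
})

test_that("swapping the two comparator trials leaves the combined I^2 unchanged", {
  trials <- example_trials()
  scts <- example_sct_summaries()
  swapped <- dplyr::mutate(scts, sct = 3 - sct)
  res <- run_bias_test_with_scts(trials, scts)
  res_sw <- run_bias_test_with_scts(trials, swapped)
  expect_equal(res_sw$combined_i_squared, res$combined_i_squared)
})

test_that("combined I^2 is monotone in the trial's arm imbalance", {
  trials <- example_trials()
  scts <- example_sct_summaries()
  base <- trials[trials$trial_id == "REF17", ]
  deltas <- seq(0, 20, by = 2)
  i2 <- vapply(deltas, function(d) {
    t <- base
    t$test_mean <- t$control_mean + d
    run_bias_test_with_scts(t, scts)$combined_i_squared
  }, numeric(1))
  expect_true(all(diff(i2) >= 0))
})

test_that("a supplied pair with non-zero I^2 warns but still replays", {
  trial <- trial_baseline("T1", 50, 10, 30, 50, 10, 30, 18, 80)
  bad_pair <- tibble::tibble(
    trial_id = "T1",
    sct = c(1, 1, 2, 2),
    arm = c("A", "B", "A", "B"),
    mean = c(60, 40, 40, 60),
    sd = 5,
    n = 30
  )
  expect_warning(
    res <- run_bias_test_with_scts(trial, bad_pair),
    "expected 0"
  )
  expect_equal(nrow(res), 1)
  expect_gt(res$null_i_squared, 0)
})

test_that("classification basis distinguishes rounded from raw I^2", {
  # three studies engineered so Q is just above df: raw I^2 in (0, 0.5)
  x <- sqrt(3 * 2.005 / 2)
  trial <- trial_baseline("edge", x, 3, 18, 0, 3, 18, 18, 80)
  pair <- tibble::tibble(
    trial_id = "edge",
    sct = c(1, 1, 2, 2),
    arm = c("A", "B", "A", "B"),
    mean = 0,
    sd = 3,
    n = 18
  )
  rounded <- run_bias_test_with_scts(trial, pair, bias_test_config())
  raw <- run_bias_test_with_scts(trial, pair,
                                 bias_test_config(classification_basis = "raw"))
  expect_gt(rounded$combined_i_squared, 0)
  expect_equal(rounded$combined_i_squared_rounded, 0L)
  expect_equal(rounded$result, 0L)
  expect_equal(raw$result, 1L)
})

test_that("degenerate trials with zero-variance arms cannot be tested", {
  trial <- trial_baseline("degen", 50, 0, 30, 52, 0, 30, 18, 80)
  expect_error(run_bias_test(trial, bias_test_config(seed = 1)),
               "degenerate", class = "sctbias_domain_error")
})
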