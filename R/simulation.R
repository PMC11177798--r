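#' Define scenarios for the accuracy simulation study
#'
#' Builds a table of simulation scenarios, one per bias fraction, sharing a
#' trial size, baseline range and replicate count. A bias fraction of 0 is
#' the unbiased arm of the study (true randomisation); positive fractions
#' control how strongly the directional misallocation mechanism of
#' [simulate_trial()] distorts allocation. Per-scenario seeds are derived
#' from `seed`.
#'
#' @inheritParams sample_baseline_values
#' @param n_total Combined patient number of each simulated trial (>= 4).
#' @param bias_fractions Numeric vector of misallocation fractions in
#'   `[0, 1]`; must include 0 and at least one positive value for
#'   [estimate_accuracy()] to estimate both specificity and sensitivity.
#' @param n_replicates Simulated trials per scenario (>= 1).
#' @param seed Optional integer master seed.
#' @return A tibble with one row per scenario: `n_total`, `range_low`,
#'   `range_high`, `bias_fraction`, `n_replicates`, `seed`.
#' @export
simulation_scenarios <- function(n_total, range_low, range_high,
                                 bias_fractions, n_replicates,
                                 seed = NULL) {
  if (any(bias_fractions < 0 | bias_fractions > 1)) {
    stop_domain("`bias_fractions` must lie in [0, 1].")
  }
  if (!is_count(n_replicates) || n_replicates < 1) {
    stop_domain("`n_replicates` must be a positive integer.")
  }
  k <- length(bias_fractions)
  scenario_seeds <- with_seed_opt(seed, draw_seeds(k))
  tibble::tibble(
    n_total = as.integer(n_total),
    range_low = as.integer(range_low),
    range_high = as.integer(range_high),
    bias_fraction = as.numeric(bias_fractions),
    n_replicates = as.integer(n_replicates),
    seed = scenario_seeds
  )
}

#' Simulate one trial with a controllable selection-bias mechanism
#'
#' Emulates a two-arm trial whose allocation may be partially corrupted.
#' Baseline values are drawn uniformly on the integer range and allocation
#' starts from ideal block randomisation, exactly as in [build_sct()].
#' Discordant patient pairs (one A, one B) are then formed at random, a
#' `bias_fraction` share of them is selected, and within each selected pair
#' the patient with the higher baseline value is forced into the test arm
#' (group A) — directional misallocation linked to the baseline variable,
#' the canonical picture of selection bias. `bias_fraction = 0` leaves the
#' ideal randomisation untouched.
#'
#' @inheritParams build_sct
#' @param bias_fraction Fraction of discordant pairs subjected to the
#'   override, in `[0, 1]`.
#' @param trial_id Identifier for the resulting record.
#' @param seed Optional integer seed; fixed seeds reproduce the trial
#'   exactly.
#' @return A one-row validated trials tibble (test arm = group A, control
#'   arm = group B) ready for [run_bias_test()].
#' @export
#' @examples
#' simulate_trial(100, 18, 80, bias_fraction = 0.5, seed = 7)
simulate_trial <- function(n_total, range_low, range_high, bias_fraction,
                           block_size = 4, seed = NULL, trial_id = "sim") {
  if (bias_fraction < 0 || bias_fraction > 1) {
    stop_domain("`bias_fraction` must lie in [0, 1].")
  }
  with_seed_opt(seed, {
    allocation <- block_randomize(n_total, block_size)
    values <- sample_baseline_values(range_low, range_high, n_total)

    idx_a <- which(allocation == "A")
    idx_b <- which(allocation == "B")
    n_pairs <- min(length(idx_a), length(idx_b))
    pair_a <- sample(idx_a, n_pairs)
    pair_b <- sample(idx_b, n_pairs)
    n_biased <- as.integer(round_half_up(bias_fraction * n_pairs))
    if (n_biased > 0) {
      chosen <- sample.int(n_pairs, n_biased)
      flip <- chosen[values[pair_b[chosen]] > values[pair_a[chosen]]]
      allocation[pair_a[flip]] <- "B"
      allocation[pair_b[flip]] <- "A"
    }

    summ <- summarize_groups(tibble::tibble(allocation = allocation,
                                            value = values))
    a <- summ[summ$arm == "A", ]
    b <- summ[summ$arm == "B", ]
    trial_baseline(
      trial_id,
      test_mean = a$mean, test_sd = a$sd, test_n = a$n,
      control_mean = b$mean, control_sd = b$sd, control_n = b$n,
      range_low = range_low, range_high = range_high
    )
  })
}

# Wilson score interval for a binomial proportion (no continuity
# correction), via stats::prop.test.
wilson_ci <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::prop.test(x, n, correct = FALSE)$conf.int)
}

#' Estimate the bias test's sensitivity and specificity by simulation
#'
#' Runs the accuracy study: every scenario's replicates are simulated with
#' [simulate_trial()] and tested with [run_bias_test()]; positives and
#' negatives are tabulated against the ground-truth bias labels
#' (`bias_fraction > 0` = truly biased). Sensitivity is the positive rate
#' among biased replicates, specificity the negative rate among unbiased
#' ones, each with a 95% Wilson score interval. The full per-replicate log
#' is retained.
#'
#' @param scenarios A scenario tibble from [simulation_scenarios()] (or of
#'   the same shape); must contain at least one scenario with
#'   `bias_fraction == 0` and one with `bias_fraction > 0`.
#' @param config A [bias_test_config()] applied to every replicate's test
#'   (per-replicate test seeds are derived from the scenario seeds, so the
#'   whole study is reproducible from the scenario table alone).
#' @return An object of class `accuracy_estimate`: a list with
#'   `sensitivity` and `specificity` (one-row tibbles: estimate, 95% CI,
#'   counts), `by_scenario` (observed positive rate per bias fraction with
#'   Wilson CIs), and `replicates` (per-replicate log). [tidy()] returns
#'   `by_scenario`, [glance()] a one-row summary, and
#'   [autoplot.accuracy_estimate()] plots the operating characteristic.
#' @export
#' @examples
#' \donttest{
#' sc <- simulation_scenarios(100, 18, 80, c(0, 0.5), 50, seed = 1)
#' acc <- estimate_accuracy(sc)
#' glance(acc)
#' }
estimate_accuracy <- function(scenarios, config = bias_test_config()) {
  scenarios <- tibble::as_tibble(scenarios)
  needed <- c("n_total", "range_low", "range_high", "bias_fraction",
              "n_replicates", "seed")
  missing <- setdiff(needed, names(scenarios))
  if (length(missing) > 0) {
    stop_schema("missing scenario column(s): %s.",
                paste0("'", missing, "'", collapse = ", "))
  }
  if (!any(scenarios$bias_fraction == 0) || !any(scenarios$bias_fraction > 0)) {
    stop_domain("need at least one scenario with bias_fraction = 0 and one with bias_fraction > 0.")
  }
  if (any(scenarios$n_replicates < 1)) {
    stop_domain("every scenario needs n_replicates >= 1.")
  }

  replicates <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    rep_seeds <- with_seed_opt(sc$seed, draw_seeds(sc$n_replicates))
    purrr::map(seq_len(sc$n_replicates), function(r) {
      sub <- with_seed_opt(rep_seeds[r], draw_seeds(2L))
      trial <- simulate_trial(
        sc$n_total, sc$range_low, sc$range_high, sc$bias_fraction,
        block_size = config$block_size, seed = sub[1],
        trial_id = sprintf("bias%.2f_rep%03d", sc$bias_fraction, r)
      )
      cfg <- config
      cfg$seed <- sub[2]
      res <- run_bias_test(trial, cfg)
      tibble::tibble(
        bias_fraction = sc$bias_fraction,
        n_total = sc$n_total,
        replicate = r,
        replicate_seed = rep_seeds[r],
        md = trial$test_mean - trial$control_mean,
        combined_i_squared = res$combined_i_squared,
        combined_i_squared_rounded = res$combined_i_squared_rounded,
        result = res$result
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  by_scenario <- replicates |>
    dplyr::group_by(.data$bias_fraction, .data$n_total) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_positive = sum(.data$result),
      positive_rate = .data$n_positive / .data$n,
      .groups = "drop"
    )
  cis <- purrr::map2(by_scenario$n_positive, by_scenario$n, wilson_ci)
  by_scenario$conf_low <- purrr::map_dbl(cis, 1)
  by_scenario$conf_high <- purrr::map_dbl(cis, 2)

  biased <- replicates[replicates$bias_fraction > 0, ]
  unbiased <- replicates[replicates$bias_fraction == 0, ]
  sens_ci <- wilson_ci(sum(biased$result), nrow(biased))
  spec_ci <- wilson_ci(sum(unbiased$result == 0), nrow(unbiased))

  structure(
    list(
      sensitivity = tibble::tibble(
        estimate = sum(biased$result) / nrow(biased),
        conf_low = sens_ci[1], conf_high = sens_ci[2],
        n_biased = nrow(biased)
      ),
      specificity = tibble::tibble(
        estimate = sum(unbiased$result == 0) / nrow(unbiased),
        conf_low = spec_ci[1], conf_high = spec_ci[2],
        n_unbiased = nrow(unbiased)
      ),
      by_scenario = by_scenario,
      replicates = replicates
    ),
    class = "accuracy_estimate"
  )
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat("Selection-bias test accuracy (simulation study)\n\n")
  cat(sprintf("sensitivity: %.3f [%.3f, %.3f] (%d biased replicates)\n",
              x$sensitivity$estimate, x$sensitivity$conf_low,
              x$sensitivity$conf_high, x$sensitivity$n_biased))
  cat(sprintf("specificity: %.3f [%.3f, %.3f] (%d unbiased replicates)\n\n",
              x$specificity$estimate, x$specificity$conf_low,
              x$specificity$conf_high, x$specificity$n_unbiased))
  cat("positive rate by bias fraction:\n")
  print(x$by_scenario)
  invisible(x)
}

#' Tidy an accuracy estimate
#'
#' @param x An `accuracy_estimate` object.
#' @param ... Unused.
#' @return `tidy()`: the per-scenario positive-rate tibble with Wilson
#'   intervals. `glance()`: a one-row tibble with sensitivity and
#'   specificity point estimates, their 95% intervals and class sizes.
#' @exportS3Method generics::tidy
tidy.accuracy_estimate <- function(x, ...) {
  x$by_scenario
}

#' @rdname tidy.accuracy_estimate
#' @exportS3Method generics::glance
glance.accuracy_estimate <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$sensitivity$estimate,
    sensitivity_low = x$sensitivity$conf_low,
    sensitivity_high = x$sensitivity$conf_high,
    specificity = x$specificity$estimate,
    specificity_low = x$specificity$conf_low,
    specificity_high = x$specificity$conf_high,
    n_biased = x$sensitivity$n_biased,
    n_unbiased = x$specificity$n_unbiased
  )
}

#' Plot the observed positive rate against the bias fraction
#'
#' @param object An `accuracy_estimate` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.accuracy_estimate <- function(object, ...) {
  ggplot2::ggplot(object$by_scenario,
                  ggplot2::aes(x = .data$bias_fraction,
                               y = .data$positive_rate)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      width = 0.02
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "misallocation fraction",
      y = "observed positive rate",
      title = "Operating characteristic of the selection-bias test"
    ) +
    ggplot2::theme_minimal()
}
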