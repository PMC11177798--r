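#' Configuration for the selection-bias test
#'
#' Procedural knobs of the bias test. `block_size` controls the comparator
#' trials' randomisation blocks. `max_null_attempts` caps how many simulated
#' comparator pairs may be generated while searching for a pair whose
#' two-study meta-analysis shows a rounded I-squared of exactly 0 — under
#' ideal randomisation a two-study Q exceeds its degrees of freedom with
#' non-trivial probability, so regeneration is occasionally needed.
#' `classification_basis` decides whether the positive/negative call uses the
#' rounded integer I-squared (the default, matching how the estimate is
#' displayed) or the raw value, which would flag microscopic heterogeneity.
#'
#' @param block_size Positive even integer, default 4.
#' @param max_null_attempts Positive integer, default 100.
#' @param seed Optional integer seed; all comparator generation and any
#'   derived randomness is reproducible given it.
#' @param classification_basis `"rounded"` (default) or `"raw"`.
#' @return A list of class `bias_test_config`.
#' @export
bias_test_config <- function(block_size = 4,
                             max_null_attempts = 100,
                             seed = NULL,
                             classification_basis = c("rounded", "raw")) {
  classification_basis <- match.arg(classification_basis)
  if (!is_count(block_size) || block_size < 2 || block_size %% 2 != 0) {
    stop_domain("`block_size` must be a positive even integer.")
  }
  if (!is_count(max_null_attempts) || max_null_attempts < 1) {
    stop_domain("`max_null_attempts` must be a positive integer.")
  }
  structure(
    list(
      block_size = as.integer(block_size),
      max_null_attempts = as.integer(max_null_attempts),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      classification_basis = classification_basis
    ),
    class = "bias_test_config"
  )
}

# Mean-difference effect (A minus B) of an arm-summary tibble with columns
# arm, n, mean, sd.
arm_summary_effect <- function(summ, study_id) {
  a <- summ[summ$arm == "A", ]
  b <- summ[summ$arm == "B", ]
  eff <- mean_difference(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
  eff$study_id <- study_id
  eff[, c("study_id", "md", "variance")]
}

trial_effect <- function(trial_row) {
  eff <- mean_difference(
    trial_row$test_mean, trial_row$test_sd, trial_row$test_n,
    trial_row$control_mean, trial_row$control_sd, trial_row$control_n
  )
  eff$study_id <- trial_row$trial_id
  eff[, c("study_id", "md", "variance")]
}

#' Generate a null pair of simulated comparator trials
#'
#' Builds pairs of SCTs for the given trial size and baseline range (with
#' seeds derived successively from `config$seed`) until the pair's two-study
#' fixed-effect meta-analysis shows a rounded I-squared of 0 — the zero
#' heterogeneity expected of ideal randomisation, confirmed explicitly. The
#' first qualifying pair is returned together with the number of attempts
#' used; failing within `config$max_null_attempts` raises an error reporting
#' every attempted I-squared value.
#'
#' @inheritParams build_sct
#' @param config A [bias_test_config()].
#' @return A list with elements `sct_1`, `sct_2` (class `sct`),
#'   `null_i_squared` (raw percent, rounds to 0), `attempts_used`, and
#'   `meta` (the pair's `meta_fixed` fit).
#' @export
#' @examples
#' pair <- make_null_pair(82, 75, 95, bias_test_config(seed = 1))
#' pair$attempts_used
make_null_pair <- function(n_total, range_low, range_high,
                           config = bias_test_config()) {
  with_seed_opt(config$seed, {
    seeds <- draw_seeds(2L * config$max_null_attempts)
    attempted <- numeric(0)
    for (attempt in seq_len(config$max_null_attempts)) {
      sct_1 <- build_sct(n_total, range_low, range_high,
                         block_size = config$block_size,
                         seed = seeds[2L * attempt - 1L])
      sct_2 <- build_sct(n_total, range_low, range_high,
                         block_size = config$block_size,
                         seed = seeds[2L * attempt])
      # a constant baseline range gives zero-variance arms; such a pair has
      # identical arm means by construction, i.e. a trivially perfect null
      summ_all <- dplyr::bind_rows(sct_1$arm_summaries, sct_2$arm_summaries)
      if (all(summ_all$sd == 0) &&
          diff(sct_1$arm_summaries$mean) == 0 &&
          diff(sct_2$arm_summaries$mean) == 0) {
        return(list(
          sct_1 = sct_1,
          sct_2 = sct_2,
          null_i_squared = 0,
          attempts_used = attempt,
          meta = NULL
        ))
      }
      effects <- dplyr::bind_rows(
        arm_summary_effect(sct_1$arm_summaries, "SCT 1"),
        arm_summary_effect(sct_2$arm_summaries, "SCT 2")
      )
      fit <- pool_fixed(effects)
      if (fit$i_squared_rounded == 0L) {
        return(list(
          sct_1 = sct_1,
          sct_2 = sct_2,
          null_i_squared = fit$i_squared,
          attempts_used = attempt,
          meta = fit
        ))
      }
      attempted <- c(attempted, fit$i_squared)
    }
    stop_domain(
      "no SCT pair reached rounded I^2 = 0 within %d attempts (attempted I^2 values: %s).",
      config$max_null_attempts,
      paste(sprintf("%.1f", attempted), collapse = ", ")
    )
  })
}

classify_i2 <- function(fit, basis) {
  value <- if (basis == "rounded") fit$i_squared_rounded else fit$i_squared
  as.integer(value > 0)
}

bias_test_row <- function(trial_row, null_fit, combined_fit, basis,
                          attempts_used, seed, sct_pair) {
  result <- classify_i2(combined_fit, basis)
  tibble::tibble(
    trial_id = trial_row$trial_id,
    n_t = trial_row$n_t,
    null_i_squared = null_fit$i_squared,
    null_i_squared_rounded = null_fit$i_squared_rounded,
    combined_i_squared = combined_fit$i_squared,
    combined_i_squared_rounded = combined_fit$i_squared_rounded,
    result = result,
    bias_risk = ifelse(result == 1L, "Y", "N"),
    attempts_used = attempts_used,
    seed = seed,
    meta = list(combined_fit),
    sct_pair = list(sct_pair)
  )
}

#' Test trials for selection-bias risk
#'
#' The full test: for each trial, a pair of simulated comparator trials of
#' the same combined size and baseline range is generated and confirmed to
#' pool with zero (rounded) I-squared; the trial's own baseline summaries
#' are then added as a third study and the fixed-effect meta-analysis is
#' repeated. A combined I-squared above 0 classifies the trial as at risk of
#' selection bias (`result = 1`, `bias_risk = "Y"`); an I-squared still at 0
#' clears it. Each comparator study enters the pooling as group A minus
#' group B, the trial as test arm minus control arm, and the trial enters
#' last.
#'
#' @param trials A trials data frame ([read_trials()], [trial_baseline()]);
#'   one test is run per row, with per-trial seeds derived from
#'   `config$seed`.
#' @param config A [bias_test_config()].
#' @return A tibble of class `bias_test_results`, one row per trial:
#'   `trial_id`, `n_t`, the null pair's I-squared (raw and rounded), the
#'   combined I-squared (raw and rounded), `result` (0/1), `bias_risk`
#'   (`"N"`/`"Y"`), `attempts_used`, `seed`, plus list columns `meta` (the
#'   three-study `meta_fixed` fit) and `sct_pair` (the two `sct` objects).
#' @seealso [run_bias_test_with_scts()] to test against fixed, already
#'   summarised comparator trials.
#' @export
#' @examples
#' trial <- trial_baseline("cohort-1", 64.22, 12, 31, 50.73, 14, 30, 18, 80)
#' run_bias_test(trial, bias_test_config(seed = 42))
run_bias_test <- function(trials, config = bias_test_config()) {
  trials <- validate_trials(trials)
  if (nrow(trials) == 0) {
    stop_domain("`trials` has no rows.")
  }
  trial_seeds <- with_seed_opt(config$seed, draw_seeds(nrow(trials)))

  rows <- purrr::map(seq_len(nrow(trials)), function(i) {
    trial_row <- trials[i, ]
    cfg <- config
    cfg$seed <- trial_seeds[i]
    pair <- make_null_pair(trial_row$n_t, trial_row$range_low,
                           trial_row$range_high, cfg)
    effects <- dplyr::bind_rows(
      arm_summary_effect(pair$sct_1$arm_summaries, "SCT 1"),
      arm_summary_effect(pair$sct_2$arm_summaries, "SCT 2"),
      trial_effect(trial_row)
    )
    combined <- pool_fixed(effects)
    bias_test_row(trial_row, pair$meta, combined,
                  config$classification_basis,
                  attempts_used = pair$attempts_used,
                  seed = trial_seeds[i],
                  sct_pair = list(pair$sct_1, pair$sct_2))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bias_test_results", class(out))
  out
}

#' Test trials against supplied comparator-trial summaries (replay mode)
#'
#' Identical to [run_bias_test()] except that the two comparator trials are
#' not generated: their arm summaries (group, mean, SD, n) are supplied, as
#' when replaying a published analysis from its printed comparator
#' summaries. The pair's own I-squared is recomputed and reported rather
#' than forced to zero; a supplied pair whose rounded I-squared exceeds 0
#' triggers a warning but the test still proceeds.
#'
#' @inheritParams run_bias_test
#' @param sct_summaries A data frame with columns `trial_id`, `sct` (1 or
#'   2), `arm` (`"A"`/`"B"`), `mean`, `sd`, `n` — four rows per trial. See
#'   [example_sct_summaries()].
#' @return A `bias_test_results` tibble as in [run_bias_test()];
#'   `attempts_used` and `seed` are `NA` and `sct_pair` holds the supplied
#'   summary tibbles.
#' @export
#' @examples
#' run_bias_test_with_scts(example_trials(), example_sct_summaries())
run_bias_test_with_scts <- function(trials, sct_summaries,
                                    config = bias_test_config()) {
  trials <- validate_trials(trials)
  sct_summaries <- validate_sct_summaries(sct_summaries)
  missing <- setdiff(trials$trial_id, unique(sct_summaries$trial_id))
  if (length(missing) > 0) {
    stop_validation("no SCT summaries supplied for trial(s): %s.",
                    paste(missing, collapse = ", "))
  }

  rows <- purrr::map(seq_len(nrow(trials)), function(i) {
    trial_row <- trials[i, ]
    summ <- sct_summaries[sct_summaries$trial_id == trial_row$trial_id, ]
    summ_1 <- summ[summ$sct == 1, ]
    summ_2 <- summ[summ$sct == 2, ]
    null_fit <- pool_fixed(dplyr::bind_rows(
      arm_summary_effect(summ_1, "SCT 1"),
      arm_summary_effect(summ_2, "SCT 2")
    ))
    if (null_fit$i_squared_rounded > 0L) {
      rlang::warn(sprintf(
        "trial '%s': supplied SCT pair has rounded I^2 = %d%% (expected 0); proceeding with the replay.",
        trial_row$trial_id, null_fit$i_squared_rounded
      ))
    }
    combined <- pool_fixed(dplyr::bind_rows(
      arm_summary_effect(summ_1, "SCT 1"),
      arm_summary_effect(summ_2, "SCT 2"),
      trial_effect(trial_row)
    ))
    bias_test_row(trial_row, null_fit, combined,
                  config$classification_basis,
                  attempts_used = NA_integer_,
                  seed = NA_integer_,
                  sct_pair = list(summ_1, summ_2))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bias_test_results", class(out))
  out
}

#' Plot bias-test results across trials
#'
#' Combined I-squared per trial, coloured by the positive/negative call.
#'
#' @param object A `bias_test_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bias_test_results <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$trial_id <- factor(d$trial_id, levels = rev(unique(d$trial_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combined_i_squared,
                                  y = .data$trial_id,
                                  fill = .data$bias_risk)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_manual(values = c(N = "#4477AA", Y = "#CC3311")) +
    ggplot2::labs(
      x = expression(I^2 ~ "(%), comparator pair + trial"),
      y = NULL, fill = "bias risk",
      title = "Selection-bias test results"
    ) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}
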