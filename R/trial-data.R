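#' @importFrom rlang .data
NULL

trial_cols_required <- c(
  "trial_id",
  "test_mean", "test_sd", "test_n",
  "control_mean", "control_sd", "control_n",
  "range_low", "range_high"
)

trial_cols_numeric <- setdiff(trial_cols_required, "trial_id")

#' Read trial baseline summaries from a CSV file
#'
#' Reads a comma-separated table of two-arm trial baseline summaries, one
#' trial per row, and validates every record. The required header columns are
#' `trial_id`, `test_mean`, `test_sd`, `test_n`, `control_mean`, `control_sd`,
#' `control_n`, `range_low`, `range_high`; a `variable_name` column is
#' optional (defaulting to `"age"`) and any further columns (for example a
#' study-design label) are carried through untouched.
#'
#' @param file Path to a CSV file with a header row, UTF-8 encoded, `"."` as
#'   decimal separator.
#'
#' @return A tibble with one validated row per trial, the columns above, and
#'   a derived `n_t` column holding the combined patient number
#'   (`test_n + control_n`) that fixes the length of any simulated comparator
#'   trial built for that study.
#' @seealso [write_trials()], [example_trials()], [run_bias_test()]
#' @export
#' @examples
#' path <- system.file("extdata", "trials_16studies.csv", package = "sctbias")
#' read_trials(path)
read_trials <- function(file) {
  raw <- readr::read_csv(
    file,
    show_col_types = FALSE,
    progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  validate_trials(raw)
}

#' Write trial baseline summaries to a CSV file
#'
#' Writes trials back in the same schema that [read_trials()] accepts, so a
#' written table re-reads to field-identical records. The derived `n_t`
#' column is dropped on write (it is recomputed on read).
#'
#' @param trials A trials data frame as returned by [read_trials()] or
#'   [trial_baseline()].
#' @param file Output path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, file) {
  trials <- validate_trials(trials)
  out <- trials[setdiff(names(trials), "n_t")]
  readr::write_csv(out, file)
  invisible(trials)
}

#' Construct a single trial baseline record
#'
#' Builds a one-row validated trials tibble from inline values, for testing a
#' trial whose summaries are typed in directly rather than read from a file.
#' Rows from several calls can be combined with [dplyr::bind_rows()].
#'
#' @param trial_id Free-text trial identifier.
#' @param test_mean,test_sd,test_n Mean, standard deviation and patient count
#'   of the test arm's baseline variable. When a source trial reports more
#'   than one test group, supply the first group listed.
#' @param control_mean,control_sd,control_n The same for the control arm.
#' @param range_low,range_high Inclusive integer limits of the baseline
#'   variable over both arms combined (for age in years, for example 18 and
#'   80). Used to sample simulated comparator values.
#' @param variable_name Name of the baseline variable (default `"age"`).
#'   Units are carried as part of the label; no conversion is attempted.
#' @param range_estimated Logical flag recording that a range limit was a
#'   reviewer estimate rather than reported.
#' @return A one-row validated trials tibble (see [read_trials()]).
#' @export
#' @examples
#' trial_baseline("cohort-1", 64.22, 12, 31, 50.73, 14, 30, 18, 80)
trial_baseline <- function(trial_id,
                           test_mean, test_sd, test_n,
                           control_mean, control_sd, control_n,
                           range_low, range_high,
                           variable_name = "age",
                           range_estimated = FALSE) {
  validate_trials(tibble::tibble(
    trial_id = as.character(trial_id),
    test_mean = test_mean, test_sd = test_sd, test_n = test_n,
    control_mean = control_mean, control_sd = control_sd,
    control_n = control_n,
    range_low = range_low, range_high = range_high,
    variable_name = variable_name,
    range_estimated = range_estimated
  ))
}

# Validate a trials data frame: schema, numeric coercion, per-row field
# checks. Returns the tibble with variable_name filled and n_t derived.
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) {
    stop_schema("`trials` must be a data frame; got %s.", class(trials)[1])
  }
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(trial_cols_required, names(trials))
  if (length(missing) > 0) {
    stop_schema("missing required column(s): %s.",
                paste0("'", missing, "'", collapse = ", "))
  }

  for (col in trial_cols_numeric) {
    vals <- trials[[col]]
    if (!is.numeric(vals)) {
      num <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(num) & !is.na(vals))
      if (length(bad) > 0) {
        stop_validation("row %d, field '%s': non-numeric value '%s'.",
                        bad[1], col, as.character(vals[bad[1]]))
      }
      trials[[col]] <- num
    }
  }

  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    for (col in trial_cols_numeric) {
      if (is.na(row[[col]])) {
        stop_validation("row %d, field '%s': missing value.", i, col)
      }
    }
    for (col in c("test_n", "control_n")) {
      n <- row[[col]]
      if (n < 1 || n != as.integer(n)) {
        stop_validation("row %d, field '%s': must be a positive integer, got %s.",
                        i, col, format(n))
      }
    }
    for (col in c("test_sd", "control_sd")) {
      if (row[[col]] < 0) {
        stop_validation("row %d, field '%s': standard deviation must be non-negative, got %s.",
                        i, col, format(row[[col]]))
      }
    }
    if (row$range_low >= row$range_high) {
      stop_validation("row %d, field 'range_low': range_low (%s) must be below range_high (%s).",
                      i, format(row$range_low), format(row$range_high))
    }
  }

  if (!"variable_name" %in% names(trials)) {
    trials$variable_name <- rep("age", nrow(trials))
  }
  trials$variable_name[is.na(trials$variable_name)] <- "age"
  trials$n_t <- as.integer(trials$test_n + trials$control_n)
  trials
}

#' Published worked examples: 16 appraised studies
#'
#' Baseline age summaries of 16 published prospective controlled studies —
#' eight randomised controlled trials with reported negative Berger-Exner
#' test results (negative controls for the bias test) and eight prospective
#' controlled cohort studies (positive controls). Each row carries the
#' per-arm mean, SD and patient count of the baseline variable, the combined
#' age range used for simulated-comparator sampling (estimated upper limits
#' flagged in `range_estimated`), and the study design. One RCT records age
#' in months rather than years.
#'
#' @return A validated trials tibble with 16 rows (see [read_trials()]) plus
#'   `design` (`"rct"`/`"cohort"`) and `range_estimated` columns.
#' @seealso [example_sct_summaries()] for the matching simulated-comparator
#'   arm summaries, [run_bias_test_with_scts()] to replay the published
#'   analyses.
#' @export
example_trials <- function() {
  read_trials(system.file("extdata", "trials_16studies.csv",
                          package = "sctbias", mustWork = TRUE))
}

#' Published worked examples: simulated-comparator arm summaries
#'
#' The arm summaries (group, mean, SD, n) of the two simulated comparator
#' trials generated for each of the 16 studies in [example_trials()], as
#' published. Feeding these into [run_bias_test_with_scts()] replays the
#' published analyses exactly, without regenerating comparator trials.
#'
#' @return A tibble with 64 rows and columns `trial_id`, `sct` (1 or 2),
#'   `arm` (`"A"`/`"B"`), `mean`, `sd`, `n`.
#' @export
example_sct_summaries <- function() {
  path <- system.file("extdata", "sct_summaries_16studies.csv",
                      package = "sctbias", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sct_summaries(out)
}

# Check the replay-mode arm-summary table: 4 rows (2 SCTs x 2 arms) per trial.
validate_sct_summaries <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("trial_id", "sct", "arm", "mean", "sd", "n")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop_schema("missing required column(s) in SCT summaries: %s.",
                paste0("'", missing, "'", collapse = ", "))
  }
  if (!all(x$sct %in% c(1, 2))) {
    stop_validation("column 'sct' must contain only 1 or 2.")
  }
  if (!all(x$arm %in% c("A", "B"))) {
    stop_validation("column 'arm' must contain only 'A' or 'B'.")
  }
  if (any(x$sd < 0) || any(x$n < 1)) {
    stop_validation("SCT summaries need sd >= 0 and n >= 1 in every row.")
  }
  counts <- dplyr::count(x, .data$trial_id)
  if (any(counts$n != 4)) {
    bad <- counts$trial_id[counts$n != 4][1]
    stop_validation("trial '%s' must have exactly 4 SCT summary rows (2 SCTs x 2 arms).",
                    bad)
  }
  x
}

#' Approximate mean and SD from a reported median and range
#'
#' When a trial reports only the median and range of its baseline variable,
#' reviewers can approximate the mean and SD before testing. The mean is
#' estimated as `(low + 2 * median + high) / 4`. The SD estimate depends on
#' the group size: for `n <= 15` it is
#' `sqrt(((low - 2 * median + high)^2 / 4 + (high - low)^2) / 12)`, for
#' `15 < n <= 70` it is `(high - low) / 4`, and for `n > 70` it is
#' `(high - low) / 6`.
#'
#' @param median,low,high Reported median and inclusive range limits, in the
#'   variable's units. Must satisfy `low <= median <= high`.
#' @param n Group size (positive integer). Selects the SD branch.
#' @return A tibble with columns `mean` and `sd`, one row per input
#'   (length-1 inputs recycle).
#' @export
#' @examples
#' median_range_to_mean_sd(median = 5, low = 0, high = 10, n = 100)
median_range_to_mean_sd <- function(median, low, high, n) {
  d <- tibble::tibble(median = median, low = low, high = high, n = n)
  if (any(d$n < 1 | d$n != as.integer(d$n))) {
    stop_domain("`n` must be a positive integer.")
  }
  bad <- which(d$median < d$low | d$median > d$high)
  if (length(bad) > 0) {
    stop_domain("median (%s) outside [low, high] = [%s, %s] at position %d.",
                format(d$median[bad[1]]), format(d$low[bad[1]]),
                format(d$high[bad[1]]), bad[1])
  }
  dplyr::transmute(
    d,
    mean = (.data$low + 2 * .data$median + .data$high) / 4,
    sd = dplyr::case_when(
      .data$n <= 15 ~ sqrt(((.data$low - 2 * .data$median + .data$high)^2 / 4 +
                              (.data$high - .data$low)^2) / 12),
      .data$n <= 70 ~ (.data$high - .data$low) / 4,
      TRUE ~ (.data$high - .data$low) / 6
    )
  )
}

#' Convert a standard error to a standard deviation
#'
#' `sd = se * sqrt(n)`. The inverse, [sd_to_se()], divides by `sqrt(n)`.
#'
#' @param se Reported standard error (non-negative), in the variable's units.
#' @param n Group size (positive integer).
#' @return The standard deviation, same length as the inputs.
#' @export
#' @examples
#' se_to_sd(2, 25)
se_to_sd <- function(se, n) {
  if (any(se < 0)) stop_domain("`se` must be non-negative.")
  if (any(n < 1)) stop_domain("`n` must be a positive integer.")
  se * sqrt(n)
}

#' @rdname se_to_sd
#' @param sd Standard deviation (non-negative).
#' @export
sd_to_se <- function(sd, n) {
  if (any(sd < 0)) stop_domain("`sd` must be non-negative.")
  if (any(n < 1)) stop_domain("`n` must be a positive integer.")
  sd / sqrt(n)
}
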