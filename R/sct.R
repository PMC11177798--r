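#' Block-randomised allocation sequence
#'
#' Generates a two-group allocation sequence (`"A"`/`"B"`) by permuted-block
#' randomisation: each block of `block_size` consecutive positions contains
#' exactly `block_size / 2` of each group, in uniformly random order. When
#' `n_total` is not a multiple of the block size, one further full block is
#' permuted and its first remaining positions are used, so overall imbalance
#' never exceeds `block_size / 2`.
#'
#' @param n_total Number of patients to allocate (at least 2).
#' @param block_size Block length; a positive even integer, default 4.
#' @param seed Optional integer seed making the sequence reproducible without
#'   disturbing the caller's RNG stream.
#' @return A character vector of length `n_total` over `c("A", "B")`.
#' @export
#' @examples
#' block_randomize(8, seed = 1)
block_randomize <- function(n_total, block_size = 4, seed = NULL) {
  if (!is_count(n_total) || n_total < 2) {
    stop_domain("`n_total` must be an integer >= 2, got %s.", format(n_total))
  }
  if (!is_count(block_size) || block_size < 2 || block_size %% 2 != 0) {
    stop_domain("`block_size` must be a positive even integer, got %s.",
                format(block_size))
  }
  with_seed_opt(seed, {
    n_blocks <- ceiling(n_total / block_size)
    half <- block_size / 2
    blocks <- replicate(n_blocks,
                        sample(rep(c("A", "B"), each = half)),
                        simplify = FALSE)
    unlist(blocks)[seq_len(n_total)]
  })
}

#' Sample sorted integer baseline values
#'
#' Draws `n_total` integers independently and uniformly (with replacement)
#' from the inclusive range `[range_low, range_high]` and returns them sorted
#' ascending — the value column of a simulated comparator trial.
#'
#' @param range_low,range_high Inclusive integer limits; `range_low` must not
#'   exceed `range_high` (equal limits give a constant column).
#' @param n_total Number of values to draw (at least 1).
#' @inheritParams block_randomize
#' @return An ascending integer vector of length `n_total`.
#' @export
sample_baseline_values <- function(range_low, range_high, n_total, seed = NULL) {
  if (!is_count(range_low) || !is_count(range_high) || range_low > range_high) {
    stop_domain("invalid range [%s, %s]: limits must be integers with low <= high.",
                format(range_low), format(range_high))
  }
  if (!is_count(n_total) || n_total < 1) {
    stop_domain("`n_total` must be an integer >= 1, got %s.", format(n_total))
  }
  with_seed_opt(seed, {
    vals <- range_low + sample.int(range_high - range_low + 1L,
                                   n_total, replace = TRUE) - 1L
    sort(as.integer(vals))
  })
}

#' Build a simulated comparator trial (SCT)
#'
#' An SCT is an artificial two-arm trial representing ideal randomisation:
#' three parallel columns of length `n_total` — an ascending patient ID, a
#' block-randomised allocation to groups A and B, and uniformly sampled
#' integer baseline values sorted ascending — paired row by row, with arm
#' summaries (n, mean, sample SD) computed per group. Pooling two such
#' trials in a fixed-effect meta-analysis is expected to show zero
#' heterogeneity, which is what makes the pair usable as a null reference
#' for bias testing.
#'
#' One seeded stream drives the whole build, allocation drawn before values.
#'
#' @inheritParams sample_baseline_values
#' @inheritParams block_randomize
#' @param n_total Combined patient number of the trial under test (at
#'   least 4); fixes the length of all three columns.
#' @return An object of class `sct`: a list with `data` (tibble with columns
#'   `patient_id`, `allocation`, `value`), `arm_summaries` (tibble with
#'   columns `arm`, `n`, `mean`, `sd`), and the generating parameters.
#' @seealso [summarize_groups()], [make_null_pair()]
#' @export
#' @examples
#' sct <- build_sct(82, 75, 95, seed = 1)
#' sct$arm_summaries
build_sct <- function(n_total, range_low, range_high, block_size = 4,
                      seed = NULL) {
  if (!is_count(n_total) || n_total < 4) {
    stop_domain("`n_total` must be an integer >= 4, got %s.", format(n_total))
  }
  with_seed_opt(seed, {
    allocation <- block_randomize(n_total, block_size)
    values <- sample_baseline_values(range_low, range_high, n_total)
    data <- tibble::tibble(
      patient_id = seq_len(n_total),
      allocation = allocation,
      value = values
    )
    structure(
      list(
        data = data,
        arm_summaries = summarize_groups(data),
        n_total = as.integer(n_total),
        range_low = as.integer(range_low),
        range_high = as.integer(range_high),
        block_size = as.integer(block_size),
        seed = seed
      ),
      class = "sct"
    )
  })
}

#' Per-group summary statistics of a simulated comparator trial
#'
#' Computes, for each allocation group, the member count, arithmetic mean,
#' and sample standard deviation (n - 1 denominator) of the value column.
#' The summaries are invariant to row order, so sorting the trial by group
#' first changes nothing.
#'
#' @param x An `sct` object from [build_sct()], or a data frame with columns
#'   `allocation` and `value`.
#' @return A tibble with columns `arm`, `n`, `mean`, `sd`, one row per group,
#'   ordered by arm label.
#' @export
summarize_groups <- function(x) {
  data <- if (inherits(x, "sct")) x$data else tibble::as_tibble(x)
  if (!all(c("allocation", "value") %in% names(data))) {
    stop_schema("need columns 'allocation' and 'value' to summarise groups.")
  }
  out <- data |>
    dplyr::group_by(arm = .data$allocation) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$arm)
  if (any(out$n < 2)) {
    stop_domain("every allocation group needs at least 2 members (sample SD undefined below that); group sizes: %s.",
                paste(out$n, collapse = "/"))
  }
  out
}

#' @export
print.sct <- function(x, ...) {
  cat(sprintf(
    "<simulated comparator trial: %d patients, values in [%d, %d], block size %d>\n",
    x$n_total, x$range_low, x$range_high, x$block_size
  ))
  print(x$arm_summaries)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.sct <- function(x, ...) {
  x$data
}

#' Plot the baseline-value distribution of an SCT by allocation group
#'
#' @param object An `sct` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sct <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$value, fill = .data$allocation)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5,
                            binwidth = 1, boundary = 0.5) +
    ggplot2::labs(
      x = "baseline value", y = "patients", fill = "group",
      title = sprintf("Simulated comparator trial (n = %d)", object$n_total)
    ) +
    ggplot2::theme_minimal()
}
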