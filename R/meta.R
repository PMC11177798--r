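#' Mean-difference effect of two trial arms
#'
#' For continuous baseline data summarised per arm as mean, SD and n, the
#' study effect is the raw mean difference `md = mean_1 - mean_2` with
#' variance `sd_1^2 / n_1 + sd_2^2 / n_2`. All arguments are vectorised so a
#' column of studies can be converted at once.
#'
#' @param mean_1,sd_1,n_1 Summary of the first arm (the test / group-A arm
#'   under this package's direction convention).
#' @param mean_2,sd_2,n_2 Summary of the second arm.
#' @return A tibble with columns `md` and `variance`.
#' @export
#' @examples
#' mean_difference(64.22, 12, 31, 50.73, 14, 30)
mean_difference <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2) {
  if (any(n_1 < 1) || any(n_2 < 1)) {
    stop_domain("arm sizes must be >= 1.")
  }
  if (any(sd_1 < 0) || any(sd_2 < 0)) {
    stop_domain("arm standard deviations must be non-negative.")
  }
  variance <- sd_1^2 / n_1 + sd_2^2 / n_2
  if (any(variance == 0)) {
    stop_domain("degenerate study: both arm SDs are zero, so the effect variance is zero and the study cannot be weighted.")
  }
  tibble::tibble(md = mean_1 - mean_2, variance = variance)
}

#' I-squared heterogeneity from Cochran's Q
#'
#' `I2 = max(0, 100 * (Q - df) / Q)`, in percent: the proportion of
#' variability across pooled studies attributable to heterogeneity rather
#' than chance. Truncated to 0 whenever `Q <= df` (including `Q = 0`), so
#' the estimate always lies in `[0, 100)`.
#'
#' @param q Cochran's Q statistic (non-negative); vectorised.
#' @param df Degrees of freedom, the number of studies minus one (>= 1).
#' @return I-squared in percent.
#' @export
#' @examples
#' i_squared(6.895, 2)
i_squared <- function(q, df) {
  if (any(q < 0)) stop_domain("`q` must be non-negative.")
  if (any(df < 1)) stop_domain("`df` must be >= 1.")
  ifelse(q <= df, 0, 100 * (q - df) / q)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study effects with weights equal to their inverse variances:
#' `w_i = 1 / v_i`, pooled effect `sum(w_i * md_i) / sum(w_i)`, pooled
#' standard error `sqrt(1 / sum(w_i))`, Cochran's
#' `Q = sum(w_i * (md_i - pooled)^2)` on `k - 1` degrees of freedom, and the
#' I-squared point estimate from [i_squared()]. I-squared is computed at
#' full precision and only the displayed value is rounded (half away from
#' zero) to an integer percent.
#'
#' @param effects A data frame with numeric columns `md` and `variance`
#'   (strictly positive), optionally `study_id`; one row per study, at
#'   least two rows. See [mean_difference()].
#' @return An object of class `meta_fixed` with elements `pooled_md`,
#'   `pooled_se`, `q`, `df`, `i_squared`, `i_squared_rounded`, `k`, and a
#'   per-study tibble `studies` (effect, variance, weight, percent weight,
#'   95% CI). Use [tidy()] / [glance()] for tibble views and
#'   [autoplot.meta_fixed()] for a forest plot.
#' @export
#' @examples
#' effects <- mean_difference(c(0, 1, 2), 1, 100, 0, 1, 100)
#' pool_fixed(effects)
pool_fixed <- function(effects) {
  if (!is.data.frame(effects)) {
    stop_domain("`effects` must be a data frame with columns 'md' and 'variance'.")
  }
  if (!all(c("md", "variance") %in% names(effects))) {
    stop_schema("`effects` needs columns 'md' and 'variance'.")
  }
  k <- nrow(effects)
  if (k < 2) {
    stop_domain("at least 2 studies are required to pool; got %d.", k)
  }
  md <- effects$md
  v <- effects$variance
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop_domain("every study variance must be finite and strictly positive.")
  }
  study_id <- if ("study_id" %in% names(effects)) {
    as.character(effects$study_id)
  } else {
    sprintf("study_%d", seq_len(k))
  }

  w <- 1 / v
  pooled_md <- sum(w * md) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  q <- sum(w * (md - pooled_md)^2)
  df <- k - 1L
  i2 <- i_squared(q, df)

  studies <- tibble::tibble(
    study_id = study_id,
    md = md,
    variance = v,
    weight = w,
    weight_pct = 100 * w / sum(w),
    conf_low = md - 1.96 * sqrt(v),
    conf_high = md + 1.96 * sqrt(v)
  )

  structure(
    list(
      pooled_md = pooled_md,
      pooled_se = pooled_se,
      conf_low = pooled_md - 1.96 * pooled_se,
      conf_high = pooled_md + 1.96 * pooled_se,
      q = q,
      df = df,
      i_squared = i2,
      i_squared_rounded = as.integer(round_half_up(i2)),
      k = k,
      studies = studies
    ),
    class = "meta_fixed"
  )
}

#' @export
print.meta_fixed <- function(x, ...) {
  cat(sprintf("Fixed-effect inverse-variance meta-analysis (%d studies)\n\n", x$k))
  tab <- x$studies
  cat(sprintf("%-12s %8s %8s %18s %8s\n",
              "study", "MD", "SE", "95% CI", "weight"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-12s %8.2f %8.3f [%7.2f, %7.2f] %7.1f%%\n",
                tab$study_id[i], tab$md[i], sqrt(tab$variance[i]),
                tab$conf_low[i], tab$conf_high[i], tab$weight_pct[i]))
  }
  cat(sprintf("\n%-12s %8.2f %8.3f [%7.2f, %7.2f]\n",
              "pooled", x$pooled_md, x$pooled_se, x$conf_low, x$conf_high))
  cat(sprintf("\nHeterogeneity: Q = %.3f, df = %d, I^2 = %.1f%% (displayed: %d%%)\n",
              x$q, x$df, x$i_squared, x$i_squared_rounded))
  invisible(x)
}

#' Tidy a fixed-effect meta-analysis
#'
#' @param x A `meta_fixed` object.
#' @param ... Unused.
#' @return `tidy()`: the per-study tibble (effect, variance, weight, CI).
#'   `glance()`: a one-row tibble with the pooled estimate, its SE and CI,
#'   Q, df, I-squared (raw and rounded), and the study count.
#' @exportS3Method generics::tidy
tidy.meta_fixed <- function(x, ...) {
  x$studies
}

#' @rdname tidy.meta_fixed
#' @exportS3Method generics::glance
glance.meta_fixed <- function(x, ...) {
  tibble::tibble(
    pooled_md = x$pooled_md,
    pooled_se = x$pooled_se,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    q = x$q,
    df = x$df,
    i_squared = x$i_squared,
    i_squared_rounded = x$i_squared_rounded,
    k = x$k
  )
}

#' Forest plot of a fixed-effect meta-analysis
#'
#' Per-study mean differences with 95% intervals, square size proportional
#' to weight, and the pooled estimate beneath.
#'
#' @param object A `meta_fixed` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meta_fixed <- function(object, ...) {
  studies <- object$studies
  rows <- dplyr::bind_rows(
    dplyr::transmute(studies,
                     label = .data$study_id, md = .data$md,
                     conf_low = .data$conf_low, conf_high = .data$conf_high,
                     weight_pct = .data$weight_pct, pooled = FALSE),
    tibble::tibble(label = "pooled", md = object$pooled_md,
                   conf_low = object$conf_low, conf_high = object$conf_high,
                   weight_pct = 100, pooled = TRUE)
  )
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$md, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$weight_pct, shape = .data$pooled)
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_area(max_size = 5, guide = "none") +
    ggplot2::labs(
      x = "mean difference", y = NULL,
      title = sprintf("Fixed-effect meta-analysis: Q = %.2f, df = %d, I² = %d%%",
                      object$q, object$df, object$i_squared_rounded)
    ) +
    ggplot2::theme_minimal()
}
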