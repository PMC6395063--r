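# ggplot2 visualisations for the main result objects.

#' Plot the entropy trace of a belief series
#'
#' One line per run; reward omissions can be overlaid by joining the trial
#' table beforehand.
#'
#' @param object A `belief_series` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.belief_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$entropy)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~run, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial", y = "model entropy (nats)",
                  title = "Ideal-observer entropy over hypotheses") +
    ggplot2::theme_minimal()
}

#' Plot a representation-strength series
#'
#' @param object A `rep_strength_series` tibble from [decode_patterns()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rep_strength_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial_index,
                                       y = .data$rep_strength)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accurate), size = 0.8) +
    ggplot2::labs(x = "trial", y = "representation strength (log odds ratio)",
                  colour = "decoded correctly") +
    ggplot2::theme_minimal()
}

#' Plot per-subject effects behind a group test
#'
#' @param object A `group_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_result <- function(object, ...) {
  df <- tibble::tibble(subject = seq_along(object$estimates),
                       estimate = object$estimates)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.7) +
    ggplot2::annotate("pointrange", x = 1, y = object$mean,
                      ymin = object$conf.int[1], ymax = object$conf.int[2],
                      colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "per-subject effect",
                  title = object$label %||% "group effect",
                  subtitle = sprintf("t(%d) = %.2f, p = %.3g",
                                     object$df, object$t, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot the null distribution of a voxel-shuffle bias check
#'
#' @param object A `shuffle_bias`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shuffle_bias <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$null),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = "statistic under voxel shuffling", y = "count",
                  title = "Pipeline bias check",
                  subtitle = sprintf("observed = %.3f, two-sided p = %.3g",
                                     object$observed, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic or recorded pupil trace
#'
#' @param pupil A `pupil_raw` object (or list with a `trace` tibble).
#' @param run Which run to show (default first).
#' @return A ggplot.
#' @export
plot_pupil_trace <- function(pupil, run = NULL) {
  tr <- pupil$trace
  run <- run %||% min(tr$run)
  tr <- tr[tr$run == run, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_ms / 1000, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "steelblue4") +
    ggplot2::geom_rug(data = tr[tr$is_missing, ], sides = "b",
                      colour = "firebrick", alpha = 0.5) +
    ggplot2::labs(x = "time (s)", y = "pupil size (a.u.)",
                  title = sprintf("Pupil trace, run %s (rug: missing samples)", run)) +
    ggplot2::theme_minimal()
}
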