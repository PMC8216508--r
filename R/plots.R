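# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_vline
#'   facet_wrap labs theme_minimal sec_axis scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot transient traces
#'
#' Active area, cumulative, mean and maximal amplitude against time, with
#' stimulus onsets marked.
#'
#' @param object a `bq_traces` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bq_traces <- function(object, ...) {
  stims <- attr(object, "stimulus_times")
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time", trace_measures)],
    cols = dplyr::all_of(trace_measures),
    names_to = "measure", values_to = "value")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    geom_vline(xintercept = stims, linetype = "dashed", colour = "grey50") +
    facet_wrap(~ measure, scales = "free_y") +
    labs(x = "time (ms)", y = NULL,
         title = "Glutamate transient readouts") +
    theme_minimal()
}

#' Plot entropy / non-triviality time course
#'
#' @param object a `bq_pattern` tibble from [pattern_timecourse()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bq_pattern <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = c("H", "C"),
                              names_to = "stat", values_to = "value")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~ stat, scales = "free_y", ncol = 1) +
    labs(x = "time (ms)", y = NULL,
         title = "Ordinal-pattern entropy and non-triviality") +
    theme_minimal()
}

#' Coupling-distance histogram with cumulative frequency
#'
#' 20-nm binned frequency distribution per group with the cumulative
#' frequency overlaid.
#'
#' @param x a `bq_distance_set` from [aggregate_distances()].
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(x) {
  stopifnot(inherits(x, "bq_distance_set"))
  h <- x$histogram
  scale <- max(h$count)
  ggplot(h, aes(x = .data$bin_start + x$bin_width / 2)) +
    geom_col(aes(y = .data$count), width = x$bin_width * 0.9,
             fill = "grey70") +
    geom_line(aes(y = .data$cum_freq * scale)) +
    facet_wrap(~ group) +
    scale_y_continuous(
      name = "count",
      sec.axis = sec_axis(~ . / scale, name = "cumulative frequency")) +
    labs(x = "coupling distance (nm)") +
    theme_minimal()
}
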