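# ggplot2 display methods

#' Plot a dF/F trace with detected events
#'
#' @param dff Tibble with `time`, `dff` (optional `neuron_id` for
#'   faceting).
#' @param events Optional events tibble with `peak_time`.
#' @return A ggplot.
#' @export
plot_trace <- function(dff, events = NULL) {
  p <- ggplot(dff, aes(time, dff)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = expression(Delta * "F/F")) +
    theme_minimal()
  if ("neuron_id" %in% names(dff))
    p <- p + facet_wrap(~neuron_id, ncol = 1)
  if (!is.null(events) && nrow(events) > 0)
    p <- p + geom_vline(data = events, aes(xintercept = peak_time),
                        colour = "red", alpha = 0.4, linetype = 3)
  p
}

#' @describeIn build_calibration_curve Peak dF/F vs AP count with SEM bars.
#' @param object A `ca_calibration`.
#' @export
autoplot.ca_calibration <- function(object, ...) {
  cv <- object$curve
  ggplot(cv, aes(ap_count, mean_peak_dff * 100)) +
    geom_errorbar(aes(ymin = (mean_peak_dff - sem_peak_dff) * 100,
                      ymax = (mean_peak_dff + sem_peak_dff) * 100),
                  width = 0.2) +
    geom_point() +
    labs(x = "APs per transient", y = "peak ΔF/F (%)") +
    theme_minimal()
}

#' @describeIn build_lookup_table Look-up estimate with 95% corridor and
#'   the linear reference line.
#' @param object A `ca_lookup`.
#' @export
autoplot.ca_lookup <- function(object, ...) {
  g <- object$grid
  lf <- object$linear_fit
  ggplot(g, aes(support * 100, ap_estimate)) +
    geom_ribbon(aes(ymin = corridor_low, ymax = corridor_high),
                fill = "grey80") +
    geom_line() +
    ggplot2::geom_abline(slope = lf$slope / 100, intercept = lf$intercept,
                         linetype = 2, colour = "steelblue") +
    geom_point(data = object$events,
               aes(mean_dff_3s * 100, ap_count), alpha = 0.2, size = 0.6) +
    labs(x = "mean ΔF/F in 3-s window (%)", y = "AP count") +
    theme_minimal()
}

#' @describeIn cluster_isis ISI histogram colored by cluster (log time
#'   axis).
#' @param object A `ca_isi_clusters`.
#' @param ... Unused.
#' @export
autoplot.ca_isi_clusters <- function(object, ...) {
  d <- object$assignments
  ggplot(d, aes(isi, fill = factor(cluster))) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::scale_x_log10() +
    labs(x = "ISI (s)", y = "count", fill = "cluster") +
    theme_minimal()
}

#' @describeIn speed_event_histogram Occupancy-normalized event frequency
#'   per speed bin.
#' @param object A `ca_speed_hist`.
#' @param ... Unused.
#' @export
autoplot.ca_speed_hist <- function(object, ...) {
  h <- object$histogram
  ggplot(h, aes((bin_lo + bin_hi) / 2, rate, fill = size_class)) +
    geom_col(position = "dodge") +
    labs(x = "running speed (cm/s)", y = "events/min",
         fill = "size class") +
    theme_minimal()
}

#' Heatmap of a day's pairwise co-activity
#'
#' @param pair_tbl Tibble from [coactivity_pairs()].
#' @param day Day to display (default: first).
#' @return A ggplot.
#' @export
plot_coactivity_matrix <- function(pair_tbl, day = NULL) {
  d <- if ("day" %in% names(pair_tbl)) {
    dd <- day %||% min(pair_tbl$day)
    pair_tbl[pair_tbl$day == dd, ]
  } else pair_tbl
  both <- dplyr::bind_rows(
    d[, c("neuron_a", "neuron_b", "coactivity")],
    tibble(neuron_a = d$neuron_b, neuron_b = d$neuron_a,
           coactivity = d$coactivity))
  ggplot(both, aes(factor(neuron_a), factor(neuron_b),
                   fill = coactivity)) +
    ggplot2::geom_tile() +
    labs(x = "neuron", y = "neuron", fill = "co-activity") +
    theme_minimal()
}
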