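# broom-style tidiers for fitted objects

#' @describeIn build_calibration_curve Tidy the per-AP-count curve.
#' @param x A `ca_calibration`.
#' @param ... Unused.
#' @export
tidy.ca_calibration <- function(x, ...) x$curve

#' @describeIn build_calibration_curve One-row model summary.
#' @export
glance.ca_calibration <- function(x, ...) {
  one <- x$curve[x$curve$ap_count == 1L, ]
  tibble(n_events = sum(x$curve$n_events),
         n_counts = nrow(x$curve),
         single_ap_peak_dff = if (nrow(one)) one$mean_peak_dff[1]
         else NA_real_,
         single_ap_tau = if (nrow(one)) one$decay_tau[1] else NA_real_)
}

#' @describeIn build_lookup_table Tidy the look-up grid.
#' @param x A `ca_lookup`.
#' @param ... Unused.
#' @export
tidy.ca_lookup <- function(x, ...) x$grid

#' @describeIn build_lookup_table One-row summary (linear slope, GP
#'   hyperparameters).
#' @export
glance.ca_lookup <- function(x, ...) {
  tibble(n_events = x$n_events,
         linear_slope = x$linear_fit$slope,
         linear_intercept = x$linear_fit$intercept,
         gp_lengthscale = x$gp$lengthscale,
         gp_noise_var = x$gp$noise_var)
}

#' @describeIn cluster_isis Tidy the two ISI clusters.
#' @param x A `ca_isi_clusters`.
#' @param ... Unused.
#' @export
tidy.ca_isi_clusters <- function(x, ...) {
  tibble(cluster = c("intraburst", "interburst"),
         mean_s = x$cluster_means, sd_s = x$cluster_sds,
         n = x$cluster_sizes)
}

#' @describeIn cluster_isis One-row summary.
#' @export
glance.ca_isi_clusters <- function(x, ...) {
  tibble(fast_mean_ms = x$cluster_means[1] * 1000,
         slow_mean_s = x$cluster_means[2],
         n_isis = sum(x$cluster_sizes))
}

#' @describeIn large_event_incidence_null Tidy observed vs chance.
#' @param x A `ca_incidence`.
#' @param ... Unused.
#' @export
tidy.ca_incidence <- function(x, ...) {
  tibble(statistic = x$observed$statistic,
         observed = x$observed$value,
         chance = unname(x$chance),
         p_value = unname(x$p_value))
}

#' @describeIn large_event_incidence_null One-row summary.
#' @export
glance.ca_incidence <- function(x, ...) {
  tibble(n_sims = x$n_sims, n_days = nrow(x$per_day),
         n_tracked = x$per_day$n_tracked[1])
}

#' @describeIn classify_large_events Tidy the classified events.
#' @param x A `ca_event_classes`.
#' @param ... Unused.
#' @export
tidy.ca_event_classes <- function(x, ...) x$events

#' @describeIn classify_large_events One-row summary.
#' @export
glance.ca_event_classes <- function(x, ...) {
  tibble(threshold = x$threshold,
         n_anesthetized = x$n_anesthetized,
         n_awake = nrow(x$events),
         frac_large = mean(x$events$size_class == "awake_large"))
}
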