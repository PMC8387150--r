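# ground-truth calibration: juxtacellular spikes vs fluorescence

#' Detect spikes in a juxtacellular voltage trace
#'
#' Simple thresholding: the threshold is `median + threshold_sd * robust SD`
#' (MAD-based) of the voltage; each suprathreshold segment contributes its
#' maximum as the spike time, and accepted spikes are separated by at least
#' the refractory period.
#'
#' @param voltage Tibble with `time`, `value` (sampling rate >= 1 kHz).
#' @param threshold_sd Threshold in robust SDs above the median.
#' @param refractory Minimal spike separation (s).
#' @param sampling_rate Optional; inferred from `time` when omitted.
#' @return Tibble with a `spike_time` column.
#' @export
detect_spikes_juxta <- function(voltage, threshold_sd = 5,
                                refractory = 0.001, sampling_rate = NULL) {
  stopifnot(is.data.frame(voltage),
            all(c("time", "value") %in% names(voltage)))
  sr <- infer_rate(voltage, sampling_rate)
  if (sr < 1000) abort("juxtacellular detection needs >= 1 kHz sampling")
  x <- voltage$value
  s <- mad(x)
  if (s <= 0) {
    warn("flat voltage trace; no spikes detected")
    return(tibble(spike_time = numeric(0)))
  }
  thr <- median(x) + threshold_sd * s
  segs <- threshold_segments(x > thr)
  if (length(segs) == 0L) return(tibble(spike_time = numeric(0)))
  times <- vapply(segs, function(idx) voltage$time[idx[which.max(x[idx])]],
                  numeric(1))
  times <- sort(times)
  keep <- c(TRUE, diff(times) >= refractory)
  tibble(spike_time = times[keep])
}

# profiled single-exponential decay fit: y = offset + A * exp(-(t - t0)/tau).
# For fixed tau the (offset, A) pair is a linear LS problem, so tau is found
# by 1-D minimization of the profiled RSS; never fails to converge.
fit_exp_decay <- function(t, y, t0 = t[1], tau_range = c(0.03, 3),
                          offset = TRUE) {
  rss <- function(tau) {
    e <- exp(-(t - t0) / tau)
    fit <- if (offset) stats::lm.fit(cbind(1, e), y)
    else stats::lm.fit(cbind(e), y)
    sum(fit$residuals^2)
  }
  opt <- optimize(rss, tau_range)
  tau <- opt$minimum
  e <- exp(-(t - t0) / tau)
  fit <- if (offset) stats::lm.fit(cbind(1, e), y)
  else stats::lm.fit(cbind(e), y)
  co <- fit$coefficients
  list(tau = tau,
       amplitude = unname(if (offset) co[2] else co[1]),
       offset = unname(if (offset) co[1] else 0),
       rss = opt$objective)
}

#' Select isolated transients from a ground-truth pair
#'
#' An isolated transient is a group of APs that (i) is preceded by at least
#' `pre_silence` seconds without spiking before its first AP and (ii) spans
#' at most `max_span` seconds (first to last AP); such quasi-impulse events
#' support per-AP-count calibration. dF/F segments from `segment_before`
#' before to `segment_after` after the first AP are excised and aligned to
#' the first AP. The time of the next AP after the group is reported so
#' downstream fits can restrict themselves to uncontaminated frames.
#'
#' Segments are expressed as dF/F relative to the local pre-event baseline
#' (median background-subtracted fluorescence over the silent second before
#' the first AP): unlike the sliding-percentile F0 used for population
#' detection, the local baseline is unbiased on these activity-dense
#' calibration traces, because the isolation rule guarantees it is sampled
#' from a silent period.
#'
#' @param pair A `ca_ground_truth` object (or list with `spikes`,
#'   `fluorescence`, optionally `background`).
#' @param background Scalar background override; defaults to
#'   [estimate_background()] of `pair$background`.
#' @param pre_silence Required silence before the first AP (s).
#' @param max_span Maximal AP-group span (s).
#' @param group_window Window after the first AP within which APs are
#'   considered part of the same transient (s).
#' @param segment_before,segment_after Excised segment bounds relative to
#'   the first AP (s).
#' @return Tibble with `first_ap`, `last_ap`, `ap_count`, `next_spike`
#'   (`Inf` if none) and a `segment` list-column of tibbles
#'   (`t_rel`, `dff`).
#' @export
select_isolated_transients <- function(pair, background = NULL,
                                       pre_silence = 2, max_span = 0.2,
                                       group_window = 0.5,
                                       segment_before = 0.5,
                                       segment_after = 2.5) {
  st <- sort(pair$spikes$spike_time)
  fl <- pair$fluorescence
  dt <- median(diff(fl$time))
  if (length(st) > 0 &&
      (min(st) < min(fl$time) - 1e-6 || max(st) > max(fl$time) + dt))
    abort("spike times extend beyond the fluorescence span")
  if (is.null(background)) {
    if (is.null(pair$background))
      abort("no background signal available; pass `background`")
    background <- estimate_background(pair$background)
  }
  fb <- fl$value - background
  if (length(st) == 0L)
    return(tibble(first_ap = numeric(0), last_ap = numeric(0),
                  ap_count = integer(0), next_spike = numeric(0),
                  segment = list()))
  gap_before <- c(Inf, diff(st))
  firsts <- which(gap_before >= pre_silence)
  rows <- list()
  for (i in firsts) {
    grp <- st[st >= st[i] & st <= st[i] + group_window]
    span <- max(grp) - min(grp)
    if (span > max_span) next
    nxt <- st[st > max(grp) + 1e-12]
    nxt <- if (length(nxt)) nxt[1] else Inf
    seg_idx <- which(fl$time >= st[i] - segment_before &
                       fl$time <= st[i] + segment_after)
    if (length(seg_idx) < 5L) next
    base_idx <- which(fl$time >= st[i] - 1 & fl$time < st[i] - 0.02)
    if (length(base_idx) < 3L) next
    base <- median(fb[base_idx])
    if (base <= 0) next
    rows[[length(rows) + 1L]] <- tibble(
      first_ap = st[i], last_ap = max(grp), ap_count = length(grp),
      next_spike = nxt,
      segment = list(tibble(t_rel = fl$time[seg_idx] - st[i],
                            dff = fb[seg_idx] / base - 1)))
  }
  if (length(rows) == 0L)
    return(tibble(first_ap = numeric(0), last_ap = numeric(0),
                  ap_count = integer(0), next_spike = numeric(0),
                  segment = list()))
  dplyr::bind_rows(rows)
}

# clean decay frames of one event: from the last AP of the group to the
# next AP (or fit_max), with the event's dF/F offset estimated from its
# pre-event silent baseline and subtracted. Returns NULL when too short.
event_decay_frames <- function(ev_first, ev_last, ev_next, seg,
                               fit_max = 1.5) {
  rel_last <- ev_last - ev_first
  rel_end <- min(ev_next - ev_first - 1e-9, rel_last + fit_max)
  idx <- which(seg$t_rel >= rel_last & seg$t_rel <= rel_end)
  if (length(idx) < 5L) return(NULL)
  base_idx <- which(seg$t_rel >= -0.5 & seg$t_rel < -0.02)
  offset <- if (length(base_idx) >= 2) median(seg$dff[base_idx]) else 0
  tibble(t_dec = seg$t_rel[idx] - rel_last,
         y = seg$dff[idx] - offset)
}

# amplitude at the transient peak (the last AP) for one event, with the
# decay constant fixed: a single linear LS coefficient, unbiased at any
# noise level
event_amplitude <- function(frames, tau) {
  e <- exp(-frames$t_dec / tau)
  sum(frames$y * e) / sum(e^2)
}

#' Build the per-AP-count calibration curve
#'
#' For every AP count present among the isolated transients, the decay time
#' constant is fitted (profiled least squares, single exponential through
#' the origin offset) to the pooled decay frames of all the count's events
#' -- each event contributes its frames between the transient peak (the
#' last AP of the group) and the next AP, offset-corrected by its own
#' pre-event silent baseline. Per-event peak amplitudes are then linear
#' least-squares coefficients with the pooled decay constant held fixed,
#' evaluated at the last AP (which back-extrapolates the frame-sampled
#' maximum to the true transient peak). The 90% confidence interval of the
#' decay constant comes from a bootstrap over events.
#'
#' @param isolated Tibble from [select_isolated_transients()].
#' @param max_ap_count Largest AP count reported (default 10, the linear
#'   regime).
#' @param fit_max Maximal decay-fit window after the last AP (s).
#' @param n_boot Bootstrap replicates for the tau CI.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `ca_calibration`: list with `curve` (tibble
#'   `ap_count`, `n_events`, `mean_peak_dff`, `sem_peak_dff`, `decay_tau`,
#'   `tau_lo90`, `tau_hi90`) and `events` (per-event amplitudes).
#' @export
build_calibration_curve <- function(isolated, max_ap_count = 10L,
                                    fit_max = 1.5, n_boot = 200L,
                                    seed = 1L) {
  if (nrow(isolated) == 0L) abort("no isolated transients supplied")
  frames <- vector("list", nrow(isolated))
  keep <- logical(nrow(isolated))
  for (i in seq_len(nrow(isolated))) {
    f <- event_decay_frames(isolated$first_ap[i], isolated$last_ap[i],
                            isolated$next_spike[i], isolated$segment[[i]],
                            fit_max)
    if (is.null(f) || isolated$ap_count[i] > max_ap_count) next
    frames[[i]] <- f
    keep[i] <- TRUE
  }
  if (!any(keep)) abort("no isolated transient could be fitted")
  counts <- isolated$ap_count

  pooled_tau <- function(event_idx) {
    pooled <- dplyr::bind_rows(frames[event_idx])
    fit_exp_decay(pooled$t_dec, pooled$y, t0 = 0, offset = FALSE)$tau
  }

  events <- list()
  curve <- with_seed(seed, {
    lapply(sort(unique(counts[keep])), function(k) {
      idx <- which(keep & counts == k)
      tau_hat <- pooled_tau(idx)
      amps <- vapply(idx, function(i)
        event_amplitude(frames[[i]], tau_hat), numeric(1))
      events[[length(events) + 1L]] <<- tibble(
        ap_count = k, event = idx, peak_dff = amps, tau = tau_hat)
      taus <- if (length(idx) >= 2) {
        vapply(seq_len(n_boot), function(b)
          pooled_tau(sample(idx, replace = TRUE)), numeric(1))
      } else rep(tau_hat, 2)
      tibble(ap_count = k, n_events = length(idx),
             mean_peak_dff = mean(amps),
             sem_peak_dff = if (length(idx) > 1)
               sd(amps) / sqrt(length(idx)) else NA_real_,
             decay_tau = tau_hat,
             tau_lo90 = unname(quantile(taus, 0.05)),
             tau_hi90 = unname(quantile(taus, 0.95)))
    })
  })
  structure(list(curve = dplyr::bind_rows(curve),
                 events = dplyr::bind_rows(events)),
            class = "ca_calibration")
}

#' Two-cluster k-means on pooled interspike intervals
#'
#' Pools the ISIs of the supplied spike trains and splits them with k-means
#' (k = 2, multiple restarts, deterministic given `seed`) into the fast
#' (intraburst) and slow (interburst) components of the bimodal ISI
#' distribution. Clusters are reported sorted ascending by mean.
#'
#' @param trains A spikes tibble (`spike_time`, optionally `neuron_id`) or a
#'   list of such tibbles / numeric vectors.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return Object of class `ca_isi_clusters`: `cluster_means` (s, ascending),
#'   `cluster_sds`, `cluster_sizes`, `assignments` tibble (`isi`, `cluster`).
#' @export
cluster_isis <- function(trains, seed = 1L, nstart = 10L) {
  pool_one <- function(x) {
    st <- if (is.data.frame(x)) x$spike_time else as.numeric(x)
    if ("neuron_id" %in% names(as.data.frame(x))) {
      unlist(lapply(split(x$spike_time, x$neuron_id),
                    function(s) diff(sort(s))))
    } else diff(sort(st))
  }
  isis <- if (is.data.frame(trains) || is.numeric(trains)) pool_one(trains)
  else unlist(lapply(trains, pool_one))
  isis <- isis[is.finite(isis)]
  if (length(isis) < 10L) abort("need at least 10 ISIs to cluster")
  if (length(unique(isis)) < 2L) abort("need at least 2 distinct ISI values")
  km <- with_seed(seed, kmeans(isis, centers = 2L, nstart = nstart))
  ord <- order(km$centers)
  cl <- match(km$cluster, ord)
  means <- vapply(1:2, function(k) mean(isis[cl == k]), numeric(1))
  sds <- vapply(1:2, function(k) sd(isis[cl == k]), numeric(1))
  structure(list(cluster_means = means, cluster_sds = sds,
                 cluster_sizes = tabulate(cl, 2L),
                 assignments = tibble(isi = isis, cluster = cl)),
            class = "ca_isi_clusters")
}

#' Burst partition and per-event AP counts
#'
#' Partitions a spike train into bursts (maximal runs of ISIs below
#' `isi_cut`, default 10 ms) and reports the burst-size distribution. When
#' detected events are supplied, also reports -- per event -- the number of
#' APs inside the 3-s analysis window around the peak and the size of the
#' largest uninterrupted burst intersecting that window.
#'
#' @param spikes Spikes tibble or numeric vector of spike times.
#' @param isi_cut Burst-defining ISI cut (s).
#' @param events Optional events tibble with `peak_time`.
#' @param window_before,window_after Event analysis window (s).
#' @return List (class `ca_bursts`) with `bursts` (tibble `burst`, `size`,
#'   `start`, `end`) and, when `events` is given, `event_aps` (tibble
#'   `peak_time`, `n_aps_window`, `max_burst_size`).
#' @export
burst_statistics <- function(spikes, isi_cut = 0.010, events = NULL,
                             window_before = 1, window_after = 2) {
  st <- sort(if (is.data.frame(spikes)) spikes$spike_time
             else as.numeric(spikes))
  if (length(st) == 0L) {
    bursts <- tibble(burst = integer(0), size = integer(0),
                     start = numeric(0), end = numeric(0))
  } else {
    bid <- cumsum(c(1L, as.integer(diff(st) >= isi_cut)))
    bursts <- tibble(burst = bid, spike_time = st) |>
      group_by(burst) |>
      summarise(size = n(), start = min(spike_time), end = max(spike_time),
                .groups = "drop")
  }
  out <- list(bursts = bursts)
  if (!is.null(events)) {
    ev <- lapply(events$peak_time, function(pt) {
      lo <- pt - window_before; hi <- pt + window_after
      n_win <- sum(st >= lo & st <= hi)
      touching <- bursts[bursts$end >= lo & bursts$start <= hi, ]
      tibble(peak_time = pt, n_aps_window = n_win,
             max_burst_size = if (nrow(touching)) max(touching$size) else 0L)
    })
    out$event_aps <- dplyr::bind_rows(ev)
  }
  structure(out, class = "ca_bursts")
}
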