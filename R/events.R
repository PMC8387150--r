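# calcium transient detection, per-event statistics, size classification

#' Robust noise SD of a dF/F trace
#'
#' Median-absolute-deviation estimate (scaled by 1.4826 for Gaussian
#' consistency) of the dF/F noise, computed over the full trace. The MAD is
#' insensitive to sparse transients, so the estimate tracks the noise floor
#' rather than the signal.
#'
#' @param dff Tibble with a `dff` column (or numeric vector).
#' @param min_frames Minimum trace length.
#' @return A list with `sd` and `method` (class `ca_noise`).
#' @export
estimate_noise_sd <- function(dff, min_frames = 50L) {
  x <- if (is.data.frame(dff)) dff$dff else as.numeric(dff)
  assert_finite(x, "dff")
  if (length(x) < min_frames)
    abort(paste0("need at least ", min_frames, " frames to estimate noise"))
  s <- mad(x)
  if (s <= 0) abort("degenerate trace: noise SD estimate is 0")
  structure(list(sd = s, method = "mad"), class = "ca_noise")
}

noise_sd_value <- function(noise) {
  if (inherits(noise, "ca_noise")) noise$sd
  else if (is.numeric(noise) && length(noise) == 1 && noise > 0) noise
  else abort("noise must be a ca_noise object or a positive scalar")
}

sd_multiplier <- function(condition) {
  switch(condition,
         anesthetized = 3,
         awake = , rest = , run = 4,
         abort(paste0("unknown condition '", condition, "'")))
}

#' Detect calcium transients in a dF/F trace
#'
#' Frames exceeding `k * sd` (k = 3 for anesthetized, 4 for awake
#' conditions) define threshold-crossing segments; within each segment the
#' first local maximum with topographic prominence of at least
#' `min_prominence` (default 20% dF/F) and at least `min_separation`
#' (default 1.5 s) from any previously accepted peak becomes the event peak.
#' Detection runs per trial and, when `day`/`neuron_id` columns are present,
#' per neuron and day.
#'
#' @param dff Tibble with columns `time`, `dff`, optionally `trial`,
#'   `neuron_id`, `day`.
#' @param noise A `ca_noise` object, a positive scalar SD, or `NULL` to
#'   estimate per neuron via [estimate_noise_sd()].
#' @param condition `"anesthetized"`, `"rest"`, `"run"` or `"awake"`.
#' @param min_prominence Minimal peak prominence (dF/F fraction).
#' @param min_separation Minimal peak separation (s).
#' @return Tibble of events: grouping columns, `trial`, `peak_time`,
#'   `peak_dff`, `condition`.
#' @export
detect_events <- function(dff, noise = NULL, condition = "awake",
                          min_prominence = 0.20, min_separation = 1.5) {
  k <- sd_multiplier(condition)
  keys <- intersect(c("day", "neuron_id"), names(dff))
  grp <- if (length(keys)) interaction(dff[keys], drop = TRUE)
  else factor(rep(1, nrow(dff)))
  out <- lapply(split(seq_len(nrow(dff)), grp), function(gidx) {
    sub <- dff[gidx, ]
    s <- if (is.null(noise)) estimate_noise_sd(sub)$sd
    else noise_sd_value(noise)
    thr <- k * s
    trl <- trial_col(sub)
    acc <- numeric(0)
    ev <- lapply(unique(trl), function(tr) {
      idx <- which(trl == tr)
      x <- sub$dff[idx]; tt <- sub$time[idx]
      segs <- threshold_segments(x > thr)
      pk <- segment_peaks(x, tt, segs, min_prominence, min_separation, acc)
      if (length(pk) == 0L) return(NULL)
      acc <<- c(acc, tt[pk])
      res <- tibble(trial = tr, peak_time = tt[pk], peak_dff = x[pk])
      for (kcol in keys) res[[kcol]] <- sub[[kcol]][1]
      res
    })
    dplyr::bind_rows(ev)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L)
    res <- tibble(trial = integer(0), peak_time = numeric(0),
                  peak_dff = numeric(0))
  res$condition <- rep(condition, nrow(res))
  dplyr::arrange(res, peak_time)[, c(intersect(c("day", "neuron_id"),
                                               names(res)),
                                     "trial", "peak_time", "peak_dff",
                                     "condition")]
}

# linear-interpolated crossing time of level y0 between frames
cross_time <- function(t1, t2, y1, y2, y0) {
  if (y2 == y1) return(t1)
  t1 + (y0 - y1) / (y2 - y1) * (t2 - t1)
}

# FWHM of one event: width at half of (peak - local baseline), with the
# baseline taken as the median over 1 s before the event and crossings
# linearly interpolated between frames; NA when the half level is not
# reached inside the trial
event_fwhm <- function(x, tt, pk, baseline_window = 1) {
  base_idx <- which(tt >= tt[pk] - baseline_window & tt < tt[pk])
  base <- if (length(base_idx) >= 1) median(x[base_idx]) else 0
  half <- base + (x[pk] - base) / 2
  n <- length(x)
  li <- pk
  while (li > 1L && x[li - 1] > half) li <- li - 1L
  ri <- pk
  while (ri < n && x[ri + 1] > half) ri <- ri + 1L
  if (li == 1L && x[1] > half) return(NA_real_)
  if (ri == n && x[n] > half) return(NA_real_)
  tl <- if (li == 1L) tt[1] else cross_time(tt[li - 1], tt[li],
                                            x[li - 1], x[li], half)
  tr <- if (ri == n) tt[n] else cross_time(tt[ri], tt[ri + 1],
                                           x[ri], x[ri + 1], half)
  tr - tl
}

#' Per-event statistics: window mean, FWHM, interevent intervals
#'
#' For every detected event computes the mean dF/F over the 3-s window from
#' 1 s before to 2 s after the peak (the integral-activity measure; windows
#' clipped at trial bounds are flagged), the full width at half maximum
#' (half of peak minus the local pre-event baseline, linearly interpolated
#' between frames), and per-neuron interevent intervals (successive peak
#' times in absolute session time).
#'
#' @param dff dF/F tibble the events were detected on.
#' @param events Tibble from [detect_events()].
#' @param window_before,window_after Analysis window around the peak (s).
#' @return `events` with columns `mean_dff_3s`, `fwhm`, `window_clipped`,
#'   `iei` (NA for each neuron's first event).
#' @export
event_stats <- function(dff, events, window_before = 1, window_after = 2) {
  if (nrow(events) == 0L)
    return(mutate(events, mean_dff_3s = numeric(0), fwhm = numeric(0),
                  window_clipped = logical(0), iei = numeric(0)))
  keys <- intersect(c("day", "neuron_id"), names(dff))
  gd <- if (length(keys)) interaction(dff[keys], drop = TRUE)
  else factor(rep(1, nrow(dff)))
  ge <- if (length(keys)) interaction(events[keys], drop = TRUE)
  else factor(rep(1, nrow(events)))
  events$mean_dff_3s <- NA_real_
  events$fwhm <- NA_real_
  events$window_clipped <- NA
  for (g in levels(ge)) {
    eidx <- which(ge == g)
    didx <- which(gd == g)
    sub <- dff[didx, ]
    trl <- trial_col(sub)
    for (i in eidx) {
      tr_idx <- which(trl == events$trial[i])
      x <- sub$dff[tr_idx]; tt <- sub$time[tr_idx]
      pk <- which.min(abs(tt - events$peak_time[i]))
      lo <- events$peak_time[i] - window_before
      hi <- events$peak_time[i] + window_after
      win <- which(tt >= lo - 1e-9 & tt <= hi + 1e-9)
      events$mean_dff_3s[i] <- mean(x[win])
      events$window_clipped[i] <- tt[1] > lo + 1e-9 ||
        tt[length(tt)] < hi - 1e-9
      events$fwhm[i] <- event_fwhm(x, tt, pk)
    }
  }
  grp_cols <- intersect(c("day", "neuron_id"), names(events))
  events <- dplyr::arrange(events,
                           !!!rlang::syms(c(grp_cols, "peak_time")))
  if (length(grp_cols)) {
    events <- events |>
      group_by(across(all_of(grp_cols))) |>
      mutate(iei = c(NA_real_, diff(peak_time))) |>
      ungroup()
  } else {
    events$iei <- c(NA_real_, diff(events$peak_time))
  }
  events
}

#' Classify awake events as small or large
#'
#' The size threshold is the 95th percentile of the pooled anesthetized
#' `mean_dff_3s` distribution (linear-interpolation percentile convention);
#' awake events above it are labeled `awake_large`, the rest `awake_small`.
#' Anesthetized events are never split by size.
#'
#' @param awake_events Events tibble with `mean_dff_3s` (awake condition).
#' @param anesthetized_events Events tibble with `mean_dff_3s`.
#' @param percentile Threshold percentile (0-100).
#' @param min_anesthetized Events required for a reliable threshold (warn
#'   below).
#' @return List (class `ca_event_classes`) with `events` (awake events plus
#'   `size_class`), `threshold` and `n_anesthetized`.
#' @export
classify_large_events <- function(awake_events, anesthetized_events,
                                  percentile = 95, min_anesthetized = 20L) {
  a <- anesthetized_events$mean_dff_3s
  a <- a[is.finite(a)]
  if (length(a) == 0L) abort("no anesthetized events to set the threshold")
  if (length(a) < min_anesthetized)
    warn(paste0("only ", length(a),
                " anesthetized events; size threshold is unreliable"))
  thr <- pctl(a, percentile)
  ev <- awake_events
  ev$size_class <- ifelse(is.na(ev$mean_dff_3s), "unclassified",
                          ifelse(ev$mean_dff_3s > thr,
                                 "awake_large", "awake_small"))
  structure(list(events = ev, threshold = thr, n_anesthetized = length(a)),
            class = "ca_event_classes")
}
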