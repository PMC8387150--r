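# behavioral-state segmentation and state-resolved event statistics

#' Downsample wheel speed to imaging frame times
#'
#' Averages the 40-Hz speed samples falling into each imaging frame
#' interval `[t, t + 1/frame_rate)`.
#'
#' @param speed Tibble with `time`, `speed` (encoder rate, e.g. 40 Hz).
#' @param frame_times Numeric vector of imaging frame start times (s).
#' @param frame_rate Imaging frame rate (Hz); inferred from `frame_times`
#'   when omitted.
#' @return Tibble with `time` (= `frame_times`) and `speed`.
#' @export
downsample_speed <- function(speed, frame_times, frame_rate = NULL) {
  stopifnot(is.data.frame(speed), all(c("time", "speed") %in% names(speed)))
  if (length(frame_times) == 0L) abort("no frame times supplied")
  fr <- frame_rate %||% (1 / median(diff(sort(unique(frame_times)))))
  ft <- frame_times
  out <- vapply(ft, function(t0) {
    idx <- which(speed$time >= t0 - 1e-9 & speed$time < t0 + 1 / fr - 1e-9)
    if (length(idx) == 0L)
      abort(paste0("no speed samples cover the frame at t = ", t0))
    mean(speed$speed[idx])
  }, numeric(1))
  tibble(time = ft, speed = out)
}

#' Label frames as rest or run
#'
#' A frame is `run` iff its speed strictly exceeds `threshold`
#' (default 0.5 cm/s); speeds at or below the threshold are `rest`.
#'
#' @param speed10 Tibble with `time`, `speed` at the imaging rate.
#' @param threshold Run threshold (cm/s).
#' @return The tibble with a `state` column added.
#' @export
segment_states <- function(speed10, threshold = 0.5) {
  stopifnot(is.data.frame(speed10),
            all(c("time", "speed") %in% names(speed10)))
  if (any(speed10$speed < 0)) abort("speeds must be nonnegative")
  mutate(speed10, state = ifelse(speed > threshold, "run", "rest"))
}

#' Maximal same-state bouts
#'
#' @param states Tibble from [segment_states()] (`time`, `state`).
#' @return Tibble with `start`, `end` (time of last frame in the bout),
#'   `state`, `n_frames`.
#' @export
state_bouts <- function(states) {
  r <- rle(states$state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  tibble(start = states$time[starts], end = states$time[ends],
         state = r$values, n_frames = r$lengths)
}

#' Event rates per behavioral state
#'
#' Assigns each event to the state of its peak frame and reports per-neuron
#' rates (events/min) as count divided by the state's dwell time. States
#' with zero dwell time get `NA` rates (flagged). When a `size_class`
#' column is present, rates are additionally split by size class.
#'
#' @param events Events tibble (needs `peak_time`; optional `neuron_id`,
#'   `size_class`).
#' @param states Tibble from [segment_states()] at the imaging rate.
#' @param frame_rate Imaging frame rate (Hz); inferred when omitted.
#' @return Tibble with `neuron_id` (if present), `state`, `size_class` (if
#'   present), `n_events`, `dwell_min`, `rate` (events/min).
#' @export
event_rates_by_state <- function(events, states, frame_rate = NULL) {
  fr <- frame_rate %||% (1 / median(diff(states$time)))
  dwell <- states |>
    group_by(state) |>
    summarise(dwell_min = n() / fr / 60, .groups = "drop")
  all_states <- unique(states$state)
  ev <- events
  ev$state <- states$state[
    vapply(ev$peak_time, function(pt) which.min(abs(states$time - pt)),
           integer(1))]
  keys <- intersect(c("neuron_id", "size_class"), names(ev))
  groups <- c(keys, "state")
  counts <- ev |>
    group_by(across(all_of(groups))) |>
    summarise(n_events = n(), .groups = "drop")
  # complete the state (and class) grid so zero-count cells appear
  grid <- expand.grid(state = all_states, stringsAsFactors = FALSE)
  if ("size_class" %in% keys)
    grid <- merge(grid, data.frame(size_class =
                                     unique(ev$size_class)))
  if ("neuron_id" %in% keys)
    grid <- merge(grid, data.frame(neuron_id = unique(ev$neuron_id)))
  out <- left_join(as_tibble(grid), counts, by = groups) |>
    mutate(n_events = ifelse(is.na(n_events), 0L, n_events)) |>
    left_join(dwell, by = "state") |>
    mutate(dwell_min = ifelse(is.na(dwell_min), 0, dwell_min),
           rate = ifelse(dwell_min > 0, n_events / dwell_min, NA_real_))
  dplyr::arrange(out, across(all_of(groups)))
}

#' Compare state-resolved rates with a one-way ANOVA
#'
#' Standard one-way ANOVA of per-neuron rates across states (the package
#' calls [stats::aov()]; it does not re-derive the test).
#'
#' @param rates Tibble from [event_rates_by_state()] with `neuron_id`.
#' @return The `aov` fit.
#' @export
compare_state_rates <- function(rates) {
  rates <- rates[!is.na(rates$rate), ]
  aov(rate ~ state, data = rates)
}

#' Occupancy-normalized event frequency across running speeds
#'
#' Counts events by the speed at their peak frame, bins them, and divides by
#' the dwell time in each speed bin (events/min). Bins without occupancy get
#' `NA` (flagged). When a `size_class` column is present the histogram is
#' computed per class, and a two-sample Kolmogorov-Smirnov test compares the
#' per-event peak-speed distributions of the first two classes.
#'
#' @param events Events tibble with `peak_time` (optional `size_class`).
#' @param speed10 Tibble with `time`, `speed` at the imaging rate.
#' @param breaks Numeric vector of speed-bin edges covering the observed
#'   speeds.
#' @param frame_rate Imaging frame rate (Hz); inferred when omitted.
#' @return List (class `ca_speed_hist`) with `histogram` (tibble `bin_lo`,
#'   `bin_hi`, `size_class`, `n_events`, `dwell_min`, `rate`), `ks` (the
#'   KS test, or `NULL`), and per-event `event_speeds`.
#' @export
speed_event_histogram <- function(events, speed10, breaks,
                                  frame_rate = NULL) {
  fr <- frame_rate %||% (1 / median(diff(speed10$time)))
  if (min(speed10$speed) < min(breaks) || max(speed10$speed) > max(breaks))
    abort("breaks must cover the observed speeds")
  ev_speed <- speed10$speed[
    vapply(events$peak_time, function(pt)
      which.min(abs(speed10$time - pt)), integer(1))]
  cls <- if ("size_class" %in% names(events)) events$size_class
  else rep("all", nrow(events))
  nb <- length(breaks) - 1L
  occ_bin <- pmin(pmax(findInterval(speed10$speed, breaks,
                                    rightmost.closed = TRUE), 1L), nb)
  dwell <- tabulate(occ_bin, nb) / fr / 60
  rows <- lapply(unique(cls), function(cl) {
    eb <- pmin(pmax(findInterval(ev_speed[cls == cl], breaks,
                                 rightmost.closed = TRUE), 1L), nb)
    cnt <- tabulate(eb, nb)
    tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
           size_class = cl, n_events = cnt, dwell_min = dwell,
           rate = ifelse(dwell > 0, cnt / dwell, NA_real_))
  })
  ks <- NULL
  classes <- unique(cls)
  if (length(classes) >= 2) {
    a <- ev_speed[cls == classes[1]]
    b <- ev_speed[cls == classes[2]]
    if (length(a) >= 3 && length(b) >= 3)
      ks <- suppressWarnings(ks.test(a, b))
  }
  structure(list(histogram = dplyr::bind_rows(rows), ks = ks,
                 event_speeds = tibble(size_class = cls, speed = ev_speed)),
            class = "ca_speed_hist")
}
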