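# pairwise and population co-activity with shuffle nulls

# window anchoring family: 0.1 s = the peak frame only; windows up to 2 s
# start 0.5 s before the peak; windows of 3 s or more start 1 s before
window_bounds <- function(window, frame_rate = 10) {
  half_frame <- 0.5 / frame_rate
  if (window <= 2 * half_frame + 1e-9)
    return(c(-half_frame, half_frame))
  if (window <= 2 + 1e-9) return(c(-0.5, window - 0.5))
  if (window >= 3 - 1e-9) return(c(-1, window - 1))
  abort("unknown window: use <= 2 s or >= 3 s (or one frame)")
}

# for each ref time, does `other` contain a peak in [ref+lo, ref+hi]?
# (closed interval)
has_peak_in <- function(ref, other, lo, hi) {
  if (length(other) == 0L)
    return(rep(FALSE, length(ref)))
  os <- sort(other)
  findInterval(ref + hi + 1e-9, os) - findInterval(ref + lo - 1e-9, os) > 0
}

#' Fraction of co-active neurons per event
#'
#' For every detected event, the fraction of all other analyzed neurons in
#' the field of view that show a transient peak within the co-activity
#' window around the reference peak (default 1 s: 0.5 s before to 0.5 s
#' after, edges inclusive). Computed per day when a `day` column is present.
#'
#' @param events Events tibble with `neuron_id`, `peak_time` (optional
#'   `day`).
#' @param window Window length (s); anchoring follows the window family
#'   (see Details in [pairwise_coactivity()]).
#' @param frame_rate Imaging frame rate (Hz), used for the one-frame window.
#' @return `events` with a `coactive_frac` column.
#' @export
coactive_fraction_per_event <- function(events, window = 1,
                                        frame_rate = 10) {
  stopifnot(all(c("neuron_id", "peak_time") %in% names(events)))
  b <- window_bounds(window, frame_rate)
  days <- if ("day" %in% names(events)) unique(events$day) else NA
  out <- events
  out$coactive_frac <- NA_real_
  for (d in days) {
    idx <- if (is.na(d[1])) seq_len(nrow(events))
    else which(events$day == d)
    sub <- events[idx, ]
    ids <- unique(sub$neuron_id)
    if (length(ids) < 2L) abort("co-activity needs at least 2 neurons")
    times_by <- split(sub$peak_time, factor(sub$neuron_id, levels = ids))
    frac <- numeric(nrow(sub))
    for (nid in ids) {
      ei <- which(sub$neuron_id == nid)
      others <- ids[ids != nid]
      m <- matrix(vapply(others, function(o)
        has_peak_in(sub$peak_time[ei], times_by[[as.character(o)]],
                    b[1], b[2]), logical(length(ei))), nrow = length(ei))
      frac[ei] <- rowSums(m) / length(others)
    }
    out$coactive_frac[idx] <- frac
  }
  out
}

#' Symmetric pairwise co-activity
#'
#' The co-activity of neurons A and B is the mean of (i) the fraction of
#' A's events with a B peak inside the window around them and (ii) the same
#' with roles swapped. The default 1-s window spans 0.5 s before to 0.5 s
#' after the reference peak (closed interval). Windows of one frame require
#' the peaks to share a frame; longer windows follow the anchoring family:
#' up to 2 s they start 0.5 s before the peak, from 3 s on they start 1 s
#' before.
#'
#' @param events_a,events_b Event times: numeric vectors or tibbles with
#'   `peak_time`.
#' @param window Window length (s).
#' @param frame_rate Imaging frame rate (Hz).
#' @return Scalar fraction in `[0, 1]`, or `NA` (with a warning) when
#'   either neuron has no events.
#' @export
pairwise_coactivity <- function(events_a, events_b, window = 1,
                                frame_rate = 10) {
  a <- if (is.data.frame(events_a)) events_a$peak_time
  else as.numeric(events_a)
  bt <- if (is.data.frame(events_b)) events_b$peak_time
  else as.numeric(events_b)
  if (length(a) == 0L || length(bt) == 0L) {
    warn("pair with an event-free neuron; co-activity undefined")
    return(NA_real_)
  }
  w <- window_bounds(window, frame_rate)
  mean(c(mean(has_peak_in(a, bt, w[1], w[2])),
         mean(has_peak_in(bt, a, w[1], w[2]))))
}

#' Co-activity of all neuron pairs
#'
#' [pairwise_coactivity()] for every unordered neuron pair, per day when a
#' `day` column is present. Pairs where either neuron has no events on that
#' day get `NA`.
#'
#' @param events Events tibble with `neuron_id`, `peak_time` (optional
#'   `day`).
#' @param neuron_ids Neurons to include (default: all present in `events`).
#' @param window Window length (s).
#' @param frame_rate Imaging frame rate (Hz).
#' @return Tibble with `day` (if present), `neuron_a`, `neuron_b`,
#'   `coactivity`, `n_a`, `n_b`.
#' @export
coactivity_pairs <- function(events, neuron_ids = NULL, window = 1,
                             frame_rate = 10) {
  stopifnot(all(c("neuron_id", "peak_time") %in% names(events)))
  ids <- sort(neuron_ids %||% unique(events$neuron_id))
  if (length(ids) < 2L) abort("co-activity needs at least 2 neurons")
  days <- if ("day" %in% names(events)) sort(unique(events$day)) else NA
  rows <- list()
  for (d in days) {
    sub <- if (is.na(d[1])) events else events[events$day == d, ]
    times_by <- split(sub$peak_time, factor(sub$neuron_id, levels = ids))
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      ta <- times_by[[i]]; tb <- times_by[[j]]
      co <- if (length(ta) == 0L || length(tb) == 0L) NA_real_
      else suppressWarnings(pairwise_coactivity(ta, tb, window, frame_rate))
      row <- tibble(neuron_a = ids[i], neuron_b = ids[j], coactivity = co,
                    n_a = length(ta), n_b = length(tb))
      if (!is.na(d[1])) row <- mutate(row, day = d, .before = 1)
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

# uniform redraw of n peak times inside [start, end] with a minimal
# separation: exact via the order-statistics "gap" construction
draw_separated <- function(n, start, end, min_sep) {
  L <- end - start
  slack <- L - (n - 1) * min_sep
  if (n > 1 && slack <= 0)
    abort("separation constraint unsatisfiable: too many events per trial")
  if (n == 0L) return(numeric(0))
  u <- sort(runif(n, 0, if (n > 1) slack else L))
  start + u + (seq_len(n) - 1L) * min_sep * (n > 1)
}

#' Shuffle event peak times within trials
#'
#' Redraws every neuron's peak times uniformly within their own trials,
#' preserving per-neuron-per-trial event counts and the minimal 1.5-s peak
#' separation (the detector's constraint). Deterministic given `seed`.
#'
#' @param events Events tibble with `neuron_id`, `trial`, `peak_time`
#'   (optional `day`).
#' @param trials Tibble with `trial`, `start`, `end` (s) giving the valid
#'   time range of each trial.
#' @param min_separation Minimal separation between redrawn peaks (s).
#' @param seed RNG seed.
#' @return `events` with `peak_time` replaced by shuffled times.
#' @export
shuffle_events <- function(events, trials, min_separation = 1.5,
                           seed = NULL) {
  stopifnot(all(c("neuron_id", "trial", "peak_time") %in% names(events)))
  with_seed(seed, {
    out <- events
    keys <- intersect(c("day", "neuron_id", "trial"), names(events))
    grp <- interaction(events[keys], drop = TRUE)
    for (g in levels(grp)) {
      idx <- which(grp == g)
      tr <- events$trial[idx[1]]
      ti <- trials[trials$trial == tr, ]
      if (nrow(ti) == 0L) abort(paste0("trial ", tr, " not in trials table"))
      out$peak_time[idx] <- sort(draw_separated(length(idx), ti$start,
                                                ti$end, min_separation))
    }
    out
  })
}

#' Shuffle-null co-activity
#'
#' Null distribution of co-activity obtained by randomizing peak times
#' (via [shuffle_events()]) `n_shuffles` times and averaging. Two
#' statistics are available: `"pairwise"` returns, per neuron pair, the
#' mean over shuffles of the symmetric co-activity between each neuron's
#' real events and the other's shuffled events; `"per_event"` returns, per
#' real event, the mean fraction of other neurons with a shuffled peak in
#' the window.
#'
#' @param events Events tibble (`neuron_id`, `trial`, `peak_time`,
#'   optional `day`).
#' @param trials Trials table (see [shuffle_events()]).
#' @param window Window length (s).
#' @param n_shuffles Number of randomizations.
#' @param seed RNG seed (deterministic null).
#' @param statistic `"pairwise"` or `"per_event"`.
#' @param frame_rate Imaging frame rate (Hz).
#' @return For `"pairwise"`: tibble like [coactivity_pairs()] with a
#'   `null_coactivity` column. For `"per_event"`: `events` with a
#'   `null_frac` column.
#' @export
shuffle_null <- function(events, trials, window = 1, n_shuffles = 100L,
                         seed = 1L, statistic = c("pairwise", "per_event"),
                         frame_rate = 10) {
  statistic <- match.arg(statistic)
  b <- window_bounds(window, frame_rate)
  ids <- sort(unique(events$neuron_id))
  days <- if ("day" %in% names(events)) sort(unique(events$day)) else NA

  if (statistic == "pairwise") {
    base <- coactivity_pairs(events, window = window,
                             frame_rate = frame_rate)
    acc <- rep(0, nrow(base)); nacc <- rep(0L, nrow(base))
    for (s in seq_len(n_shuffles)) {
      shuf <- shuffle_events(events, trials, seed = derive_seed(seed, s))
      for (d in days) {
        sub <- if (is.na(d[1])) events else events[events$day == d, ]
        ssub <- if (is.na(d[1])) shuf else shuf[shuf$day == d, ]
        real_by <- split(sub$peak_time, factor(sub$neuron_id, levels = ids))
        shuf_by <- split(ssub$peak_time, factor(ssub$neuron_id,
                                                levels = ids))
        rsel <- if (is.na(d[1])) seq_len(nrow(base))
        else which(base$day == d)
        for (r in rsel) {
          ta <- real_by[[as.character(base$neuron_a[r])]]
          tb <- real_by[[as.character(base$neuron_b[r])]]
          sa <- shuf_by[[as.character(base$neuron_a[r])]]
          sb <- shuf_by[[as.character(base$neuron_b[r])]]
          if (length(ta) == 0L || length(tb) == 0L) next
          v <- mean(c(mean(has_peak_in(ta, sb, b[1], b[2])),
                      mean(has_peak_in(tb, sa, b[1], b[2]))))
          acc[r] <- acc[r] + v
          nacc[r] <- nacc[r] + 1L
        }
      }
    }
    base$null_coactivity <- ifelse(nacc > 0, acc / nacc, NA_real_)
    base
  } else {
    out <- events
    acc <- rep(0, nrow(events))
    for (s in seq_len(n_shuffles)) {
      shuf <- shuffle_events(events, trials, seed = derive_seed(seed, s))
      for (d in days) {
        idx <- if (is.na(d[1])) seq_len(nrow(events))
        else which(events$day == d)
        sub <- events[idx, ]
        ssub <- if (is.na(d[1])) shuf else shuf[shuf$day == d, ]
        shuf_by <- split(ssub$peak_time, factor(ssub$neuron_id,
                                                levels = ids))
        for (nid in ids) {
          ei <- idx[sub$neuron_id == nid]
          others <- ids[ids != nid]
          if (length(ei) == 0L) next
          m <- matrix(vapply(others, function(o)
            has_peak_in(events$peak_time[ei],
                        shuf_by[[as.character(o)]], b[1], b[2]),
            logical(length(ei))), nrow = length(ei))
          acc[ei] <- acc[ei] + rowSums(m) / length(others)
        }
      }
    }
    out$null_frac <- acc / n_shuffles
    out
  }
}
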