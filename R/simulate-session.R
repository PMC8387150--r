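# composition: paired ground truth and multi-day population sessions

#' Simulate a paired ground-truth recording
#'
#' Emulates a simultaneous juxtacellular + imaging experiment under
#' anesthesia: one spike train from the bursty model (anesthetized state,
#' no locomotion, no large events) with fluorescence rendered by the forward
#' model at `frame_rate` (default 20 Hz, the zoomed-in calibration rate).
#'
#' @param stm A [spike_train_model()].
#' @param fm A [forward_model()].
#' @param duration Recording duration (s).
#' @param seed Optional RNG seed.
#' @param frame_rate Imaging rate (Hz).
#' @return An object of class `ca_ground_truth`: list with `spikes` (tibble),
#'   `fluorescence` (tibble `time`, `value`), `model`, `frame_rate`,
#'   `duration`.
#' @export
simulate_ground_truth <- function(stm, fm, duration, seed = NULL,
                                  frame_rate = 20) {
  if (!is.numeric(duration) || duration <= 0)
    abort("duration must be a positive number of seconds")
  sched <- tibble(start = 0, end = duration, state = "anesthetized")
  spikes <- simulate_spike_train(stm, duration, sched,
                                 seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, 1))
  fl <- simulate_fluorescence(spikes, fm, frame_rate, duration,
                              seed = if (is.null(seed)) NULL
                              else derive_seed(seed, 2))
  # emitted off-cell background measurement (shot noise around the offset)
  bg <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 3),
                  tibble(time = fl$time,
                         value = fm$background_offset +
                           rnorm(nrow(fl), 0, 0.02 * fm$background_offset)))
  structure(list(spikes = spikes, fluorescence = fl, background = bg,
                 model = fm,
                 spike_model = stm, frame_rate = frame_rate,
                 duration = duration),
            class = "ca_ground_truth")
}

# trial start times for a session day
trial_starts <- function(spec) {
  (seq_len(spec$n_trials) - 1L) * (spec$trial_length + spec$inter_trial_gap)
}

session_span <- function(spec) {
  spec$n_trials * spec$trial_length +
    (spec$n_trials - 1L) * spec$inter_trial_gap
}

# assign frames to trials; frames in gaps get NA
frame_trial <- function(time, spec) {
  starts <- trial_starts(spec)
  i <- findInterval(time, starts)
  i[i < 1L] <- NA_integer_
  off <- time - starts[pmax(i, 1L)]
  i[!is.na(i) & off >= spec$trial_length - 1e-9] <- NA_integer_
  i
}

draw_centroids <- function(spec) {
  pts <- matrix(numeric(0), ncol = 2)
  guard <- 0L
  while (nrow(pts) < spec$n_neurons) {
    cand <- runif(2) * spec$fov_um
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2,
                                       byrow = TRUE))^2))) >=
        spec$centroid_min_dist) {
      pts <- rbind(pts, cand)
    }
    guard <- guard + 1L
    if (guard > 10000L) abort("could not place centroids; lower n or spacing")
  }
  tibble(neuron_id = seq_len(spec$n_neurons),
         x_um = unname(pts[, 1]), y_um = unname(pts[, 2]))
}

#' Simulate a multi-day population imaging session
#'
#' Generates, for every day, wheel-speed behavior, per-neuron spike trains
#' and raw fluorescence traces organized in 30-s trials with inter-trial gaps
#' that contain no samples. Neuron identities, centroids, per-neuron
#' amplitude scaling, co-activity group memberships and the large-event
#' neuron subset persist across days. Members of a co-activity group receive
#' shared burst-event times with the group's `p_shared` probability on top of
#' their independent background activity. The whole session is a pure
#' function of `spec$seed`.
#'
#' @param spec A [session_spec()].
#' @param stm A [spike_train_model()].
#' @param fm A [forward_model()].
#' @return An object of class `ca_session`: list with `spec`, `traces`
#'   (tibble `day`, `neuron_id`, `trial`, `time`, `value`), `spikes` (tibble
#'   `day`, `neuron_id`, `spike_time`, `origin`), `behavior` (tibble `day`,
#'   `time`, `speed`), `centroids`, `large_event_neurons`,
#'   `amplitude_scale`.
#' @export
simulate_session <- function(spec, stm = spike_train_model(),
                             fm = forward_model()) {
  stopifnot(inherits(spec, "session_spec"),
            inherits(stm, "spike_train_model"),
            inherits(fm, "forward_model"))
  span <- session_span(spec)
  starts <- trial_starts(spec)

  persistent <- with_seed(spec$seed, {
    cents <- draw_centroids(spec)
    amp <- if (spec$amplitude_scale_sd > 0)
      rlnorm(spec$n_neurons, -spec$amplitude_scale_sd^2 / 2,
             spec$amplitude_scale_sd) else rep(1, spec$n_neurons)
    n_large <- round(spec$large_event_fraction * spec$n_neurons)
    large_set <- if (n_large > 0)
      sort(sample(spec$n_neurons, n_large)) else integer(0)
    list(cents = cents, amp = amp, large_set = large_set)
  })

  traces <- list(); spikes <- list(); behavior <- list()
  background <- list()
  for (d in seq_len(spec$n_days)) {
    if (spec$condition == "awake") {
      beh <- simulate_behavior(span, seed = derive_seed(spec$seed, 90000 + d))
      r <- rle(beh$state)
      ends <- cumsum(r$lengths)
      sched <- tibble(
        start = beh$time[c(1L, head(ends, -1) + 1L)],
        end = c(beh$time[ends[-length(ends)] + 1L], span),
        state = r$values)
    } else {
      beh <- tibble(time = (seq_len(floor(span * 40)) - 1L) / 40,
                    speed = 0, state = "rest")
      sched <- tibble(start = 0, end = span, state = "anesthetized")
    }
    behavior[[d]] <- mutate(beh[c("time", "speed")], day = d)
    bg_t <- (seq_len(floor(span * spec$frame_rate)) - 1L) / spec$frame_rate
    background[[d]] <- with_seed(derive_seed(spec$seed, 95000 + d), tibble(
      day = d, time = bg_t,
      value = fm$background_offset +
        rnorm(length(bg_t), 0, 0.02 * fm$background_offset)))

    # planted group events for this day (times drawn inside trials)
    group_spikes <- vector("list", spec$n_neurons)
    for (gi in seq_along(spec$coactivity_groups)) {
      g <- spec$coactivity_groups[[gi]]
      bs <- g$burst_size %||% 8L
      ev <- with_seed(derive_seed(spec$seed, 70000 + 97 * gi + d), {
        n_ev <- rpois(1L, g$rate_per_min / 60 * spec$n_trials *
                        spec$trial_length)
        if (n_ev == 0L) {
          list(times = numeric(0), member = NULL)
        } else {
          tr <- sample(spec$n_trials, n_ev, replace = TRUE)
          tt <- starts[tr] + 1 + runif(n_ev) * (spec$trial_length - 3)
          member <- matrix(runif(n_ev * length(g$neurons)) < g$p_shared,
                           nrow = n_ev)
          list(times = tt, member = member)
        }
      })
      if (length(ev$times) == 0) next
      for (k in seq_along(g$neurons)) {
        nid <- g$neurons[k]
        sel <- ev$times[ev$member[, k]]
        if (length(sel) == 0) next
        if (bs > 1L) {
          isis <- with_seed(derive_seed(spec$seed,
                                        80000 + 97 * gi + 13 * k + d),
                            draw_intraburst_isis((bs - 1L) * length(sel), stm))
          sp <- as.numeric(vapply(seq_along(sel), function(i) {
            sel[i] +
              cumsum(c(0, isis[((i - 1) * (bs - 1) + 1):((bs - 1) * i)]))
          }, numeric(bs)))
        } else {
          sp <- sel
        }
        group_spikes[[nid]] <- c(group_spikes[[nid]], sp)
      }
    }

    for (j in seq_len(spec$n_neurons)) {
      stm_j <- stm
      if (!(j %in% persistent$large_set)) stm_j$large_event_rate <- 0
      sp <- simulate_spike_train(
        stm_j, span, sched,
        seed = derive_seed(spec$seed, 1000 * d + j))
      if (!is.null(group_spikes[[j]])) {
        extra <- sort(group_spikes[[j]])
        sp <- dplyr::arrange(dplyr::bind_rows(
          sp, tibble(spike_time = extra, burst = NA_integer_,
                     origin = "group")), spike_time)
      }
      fm_j <- fm
      fm_j$amplitude_per_ap <- fm$amplitude_per_ap * persistent$amp[j]
      fm_j$single_ap_amplitude <- fm$single_ap_amplitude * persistent$amp[j]
      fl <- simulate_fluorescence(sp, fm_j, spec$frame_rate, span,
                                  seed = derive_seed(spec$seed,
                                                     5000 * d + 101 * j))
      fl$trial <- frame_trial(fl$time, spec)
      fl <- fl[!is.na(fl$trial), c("time", "trial", "value")]
      traces[[length(traces) + 1L]] <- mutate(fl, day = d, neuron_id = j)
      spikes[[length(spikes) + 1L]] <-
        mutate(sp[c("spike_time", "origin")], day = d, neuron_id = j)
    }
  }

  structure(list(
    spec = spec,
    traces = dplyr::bind_rows(traces)[, c("day", "neuron_id", "trial",
                                          "time", "value")],
    spikes = dplyr::bind_rows(spikes)[, c("day", "neuron_id", "spike_time",
                                          "origin")],
    behavior = dplyr::bind_rows(behavior)[, c("day", "time", "speed")],
    background = dplyr::bind_rows(background)[, c("day", "time", "value")],
    centroids = persistent$cents,
    large_event_neurons = persistent$large_set,
    amplitude_scale = persistent$amp
  ), class = "ca_session")
}

#' @export
print.ca_session <- function(x, ...) {
  cat("<ca_session> ", x$spec$n_neurons, " neurons, ", x$spec$n_days,
      " day(s), ", x$spec$n_trials, " trials/day, condition=",
      x$spec$condition, "\n", sep = "")
  invisible(x)
}
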