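# wheel-speed generation: alternating rest/run bouts sampled at 40 Hz

#' Bout model for simulated locomotion
#'
#' Rest and run bouts alternate with exponentially distributed durations;
#' run-bout speeds follow a lognormal profile smoothed over ~0.5 s. The
#' expected fraction of time spent running is
#' `run_mean_s / (run_mean_s + rest_mean_s)`.
#'
#' @param rest_mean_s Mean rest-bout duration (s).
#' @param run_mean_s Mean run-bout duration (s).
#' @param run_speed_mean Mean running speed (cm/s) within run bouts.
#' @param run_speed_sd SD of running speed (cm/s) across run bouts.
#' @param rest_speed_sd Residual sensor jitter (cm/s) during rest.
#' @return An object of class `bout_model`.
#' @export
bout_model <- function(rest_mean_s = 40, run_mean_s = 20,
                       run_speed_mean = 8, run_speed_sd = 3,
                       rest_speed_sd = 0.05) {
  stopifnot(rest_mean_s > 0, run_mean_s > 0, run_speed_mean >= 0,
            run_speed_sd >= 0, rest_speed_sd >= 0)
  structure(list(rest_mean_s = rest_mean_s, run_mean_s = run_mean_s,
                 run_speed_mean = run_speed_mean,
                 run_speed_sd = run_speed_sd,
                 rest_speed_sd = rest_speed_sd),
            class = "bout_model")
}

#' Simulate a wheel-speed trace
#'
#' Generates a nonnegative speed trace at `sampling_rate` (default 40 Hz, the
#' rotary-encoder rate) from alternating rest and run bouts. Degenerate bout
#' models are supported: `run_mean_s` effectively infinite relative to
#' duration yields continuous running and vice versa.
#'
#' @param duration Duration (s).
#' @param model A [bout_model()].
#' @param seed Optional RNG seed.
#' @param sampling_rate Samples per second (Hz).
#' @param start_state `"rest"`, `"run"`, or `"random"` (stationary
#'   probabilities).
#' @return A tibble with columns `time` (s) and `speed` (cm/s), plus a
#'   `state` column (`"rest"`/`"run"`) giving the generating bout label.
#' @export
simulate_behavior <- function(duration, model = bout_model(), seed = NULL,
                              sampling_rate = 40, start_state = "random") {
  if (!is.numeric(duration) || duration <= 0)
    abort("duration must be a positive number of seconds")
  stopifnot(inherits(model, "bout_model"))
  with_seed(seed, {
    n <- floor(duration * sampling_rate + 1e-9)
    tt <- (seq_len(n) - 1L) / sampling_rate
    p_run <- model$run_mean_s / (model$run_mean_s + model$rest_mean_s)
    state0 <- switch(start_state,
                     rest = "rest", run = "run",
                     random = if (runif(1) < p_run) "run" else "rest")
    # draw alternating bout intervals covering the duration
    bouts <- list(); t0 <- 0; s <- state0
    while (t0 < duration) {
      len <- stats::rexp(1, 1 / if (s == "run") model$run_mean_s else
        model$rest_mean_s)
      bouts[[length(bouts) + 1L]] <- tibble(
        start = t0, end = min(t0 + len, duration), state = s)
      t0 <- t0 + len
      s <- if (s == "run") "rest" else "run"
    }
    sched <- dplyr::bind_rows(bouts)
    lab <- state_at(sched, tt)
    speed <- abs(rnorm(n, 0, model$rest_speed_sd))
    run_idx <- which(lab == "run")
    if (length(run_idx) > 0) {
      # per-bout target speed, smoothed within the bout
      run_bouts <- sched[sched$state == "run", , drop = FALSE]
      for (i in seq_len(nrow(run_bouts))) {
        idx <- which(tt >= run_bouts$start[i] & tt < run_bouts$end[i])
        if (length(idx) == 0) next
        if (model$run_speed_sd == 0) {
          speed[idx] <- model$run_speed_mean
        } else {
          m <- model$run_speed_mean
          sig2 <- log(1 + (model$run_speed_sd / m)^2)
          target <- rlnorm(1, log(m) - sig2 / 2, sqrt(sig2))
          prof <- target + rnorm(length(idx), 0, 0.1 * target)
          if (length(idx) > 5)
            prof <- gauss_smooth(prof, sampling_rate, 0.5)
          speed[idx] <- pmax(prof, 0.6)  # running stays above the 0.5 cm/s cut
        }
      }
    }
    tibble(time = tt, speed = pmax(speed, 0), state = lab)
  })
}
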