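# spike-train generation from the bursty two-timescale ISI model

# evaluate code with a temporary RNG state (restores the caller's stream)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# derived sub-stream seeds, kept under 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * as.double(k)) %% 2147483629 + 1)
}

# truncated-geometric burst sizes on 1..max with target mean; the family
# only reaches means below the uniform limit (max + 1) / 2
truncated_geom_p <- function(mean_size, max_size) {
  if (mean_size <= 1) return(1)
  if (mean_size >= (max_size + 1) / 2)
    abort("burst_size_mean must be below (burst_size_max + 1) / 2")
  f <- function(p) {
    k <- seq_len(max_size)
    w <- p * (1 - p)^(k - 1)
    sum(k * w) / sum(w) - mean_size
  }
  stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

draw_burst_sizes <- function(n, model) {
  if (n == 0L) return(integer(0))
  p <- truncated_geom_p(model$burst_size_mean, model$burst_size_max)
  k <- seq_len(model$burst_size_max)
  w <- p * (1 - p)^(k - 1)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

# intraburst ISIs: normal truncated to bounds symmetric about the mean,
# so the truncated mean equals the nominal mean
draw_intraburst_isis <- function(n, model) {
  if (n == 0L) return(numeric(0))
  if (model$intraburst_isi_sd == 0) return(rep(model$intraburst_isi_mean, n))
  lo <- model$intraburst_floor
  hi <- 2 * model$intraburst_isi_mean - lo
  out <- numeric(0)
  while (length(out) < n) {
    cand <- rnorm(2L * (n - length(out)) + 10L,
                  model$intraburst_isi_mean, model$intraburst_isi_sd)
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

# interburst intervals: hard offset + lognormal winsorized at the cap, with
# the lognormal location solved so the capped mean hits the target;
# shape == 0 degenerates to the constant mean
capped_lnorm_mean <- function(mu, sigma, cap) {
  m <- exp(mu + sigma^2 / 2)
  excess <- m * stats::pnorm((mu + sigma^2 - log(cap)) / sigma) -
    cap * stats::pnorm((mu - log(cap)) / sigma)
  m - excess
}

interburst_mu <- function(model) {
  target <- model$interburst_isi_mean - model$interburst_offset
  if (target <= 0) abort("interburst_isi_mean must exceed interburst_offset")
  if (target >= model$interburst_cap)
    abort("interburst_isi_mean must be below offset + cap")
  sigma <- model$interburst_shape
  stats::uniroot(function(mu) capped_lnorm_mean(mu, sigma,
                                                model$interburst_cap) -
                   target, c(-12, 6), tol = 1e-10)$root
}

draw_interburst <- function(n, model) {
  if (n == 0L) return(numeric(0))
  if (model$interburst_shape == 0)
    return(rep(model$interburst_isi_mean, n))
  mu <- model$.interburst_mu %||% interburst_mu(model)
  model$interburst_offset +
    pmin(rlnorm(n, mu, model$interburst_shape), model$interburst_cap)
}

check_schedule <- function(state_schedule, duration) {
  if (!all(c("start", "end", "state") %in% names(state_schedule)))
    abort("state_schedule needs columns start, end, state")
  sched <- dplyr::arrange(state_schedule, start)
  if (nrow(sched) == 0L || sched$start[1] > 1e-9 ||
      sched$end[nrow(sched)] < duration - 1e-9 ||
      (nrow(sched) > 1 && any(sched$start[-1] > sched$end[-nrow(sched)] + 1e-9)))
    abort("state_schedule does not cover [0, duration]")
  if (any(sched$end <= sched$start)) abort("schedule intervals must have end > start")
  sched
}

state_at <- function(sched, t) {
  i <- findInterval(t, sched$start)
  i[i < 1L] <- 1L
  sched$state[i]
}

#' Simulate a bursty spike train
#'
#' Draws a spike train from a [spike_train_model()]: burst onsets separated by
#' interburst intervals (modulated per behavioral state by the model's rate
#' multipliers), burst sizes from a truncated geometric, intraburst ISIs from
#' the fast truncated-normal component, and -- during `run` state only -- rare
#' large events consisting of dense Poisson AP trains of
#' `large_event_duration` seconds. The first burst onset is placed uniformly
#' within the first drawn interval.
#'
#' @param model A [spike_train_model()].
#' @param duration Train duration (s); spikes lie in `[0, duration)`.
#' @param state_schedule Tibble with columns `start`, `end`, `state` covering
#'   `[0, duration]`; default is rest throughout.
#' @param seed Optional RNG seed (the caller's RNG state is restored).
#' @return A tibble with columns `spike_time` (sorted, s), `burst` (integer id
#'   of the background burst, `NA` for large-event APs) and `origin`
#'   (`"burst"` or `"large"`).
#' @export
simulate_spike_train <- function(model, duration,
                                 state_schedule = NULL, seed = NULL) {
  stopifnot(inherits(model, "spike_train_model"))
  if (!is.numeric(duration) || duration <= 0)
    abort("duration must be a positive number of seconds")
  if (is.null(state_schedule))
    state_schedule <- tibble(start = 0, end = duration, state = "rest")
  sched <- check_schedule(state_schedule, duration)
  states <- unique(sched$state)
  mult <- model$state_rate_multipliers
  if (!all(states %in% names(mult)))
    abort("state_schedule contains states without a rate multiplier")
  if (model$interburst_shape > 0)
    model$.interburst_mu <- interburst_mu(model)  # cache for the draw loop

  with_seed(seed, {
    onsets <- numeric(0); times <- numeric(0); burst_id <- integer(0)
    t <- 0; first <- TRUE; b <- 0L
    repeat {
      m <- unname(mult[state_at(sched, min(t, duration - 1e-12))])
      if (m == 0) {
        # zero-rate state: jump to the end of the current schedule interval
        i <- findInterval(min(t, duration - 1e-12), sched$start)
        t <- sched$end[max(i, 1L)] + 1e-12
        first <- FALSE
        if (t >= duration) break
        next
      }
      gap <- draw_interburst(1L, model) / m
      onset <- if (first) t + runif(1) * gap else t + gap
      first <- FALSE
      if (onset >= duration) break
      b <- b + 1L
      size <- draw_burst_sizes(1L, model)
      isis <- draw_intraburst_isis(size - 1L, model)
      sp <- onset + cumsum(c(0, isis))
      sp <- sp[sp < duration]
      times <- c(times, sp)
      burst_id <- c(burst_id, rep(b, length(sp)))
      t <- max(sp)
    }

    large_times <- numeric(0)
    if (model$large_event_rate > 0) {
      run_iv <- sched[sched$state == "run", , drop = FALSE]
      if (nrow(run_iv) > 0) {
        for (i in seq_len(nrow(run_iv))) {
          len <- min(run_iv$end[i], duration) - run_iv$start[i]
          if (len <= 0) next
          n_ev <- rpois(1L, model$large_event_rate / 60 * len)
          if (n_ev == 0L) next
          starts <- run_iv$start[i] + runif(n_ev) *
            max(len - model$large_event_duration, 0)
          for (s0 in starts) {
            n_ap <- rpois(1L, model$large_event_ap_count)
            ap <- s0 + sort(runif(n_ap)) * model$large_event_duration
            large_times <- c(large_times, ap[ap < duration])
          }
        }
      }
    }

    out <- tibble(
      spike_time = c(times, large_times),
      burst = c(burst_id, rep(NA_integer_, length(large_times))),
      origin = c(rep("burst", length(times)),
                 rep("large", length(large_times)))
    )
    dplyr::arrange(out, spike_time)
  })
}
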