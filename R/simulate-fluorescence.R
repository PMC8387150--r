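# forward model: spikes -> raw fluorescence

# burst-size-dependent decay time constant: linear interpolation in AP count
# between the single-AP and the large-burst limit
decay_tau_for_count <- function(fm, n_aps) {
  frac <- pmin(pmax(n_aps - 1L, 0L), fm$linear_max_aps - 1L) /
    (fm$linear_max_aps - 1L)
  fm$decay_tau_single + frac * (fm$decay_tau_max - fm$decay_tau_single)
}

# per-AP kernel amplitudes within a burst of size n
ap_amplitudes <- function(fm, n) {
  j <- seq_len(n)
  a <- rep(fm$amplitude_per_ap, n)
  a[j > fm$linear_max_aps] <- fm$amplitude_per_ap * fm$saturation_gain
  if (fm$supralinear_gain > 1 && n > fm$supralinear_threshold)
    a[j > fm$supralinear_threshold] <- a[j > fm$supralinear_threshold] *
      fm$supralinear_gain
  a
}

#' Simulate a raw fluorescence trace from a spike train
#'
#' Renders raw fluorescence as `background_offset + baseline_f * (1 + s(t))`
#' where `s(t)` is the dF/F signal: a sum of per-AP kernels with fast
#' (optionally instantaneous) rise and exponential decay. APs are grouped
#' into bursts by an ISI cut of 10 ms; each burst's APs share a decay time
#' constant interpolated between the single-AP and large-burst limits, and
#' per-AP amplitudes follow the linear/saturating gain of the forward model.
#' Additive Gaussian (and optionally Poisson-like) noise is applied in raw
#' units scaled so its dF/F-equivalent SD is `fm$noise_sd`.
#'
#' @param spikes Numeric vector of spike times (s) or a tibble with a
#'   `spike_time` column.
#' @param fm A [forward_model()].
#' @param frame_rate Sampling rate (Hz).
#' @param duration Trace duration (s).
#' @param seed Optional RNG seed for the noise.
#' @param isi_cut Burst-grouping ISI cut (s).
#' @return A tibble with columns `time` and `value` (raw fluorescence units).
#' @export
simulate_fluorescence <- function(spikes, fm, frame_rate, duration,
                                  seed = NULL, isi_cut = 0.010) {
  stopifnot(inherits(fm, "forward_model"), frame_rate > 0, duration > 0)
  st <- if (is.data.frame(spikes)) spikes$spike_time else as.numeric(spikes)
  if (length(st) > 0 && (min(st) < 0 || max(st) >= duration))
    abort("spike times must lie within [0, duration)")
  st <- sort(st)
  n_frames <- floor(duration * frame_rate + 1e-9)
  tf <- (seq_len(n_frames) - 1L) / frame_rate
  sig <- numeric(n_frames)

  if (length(st) > 0) {
    burst <- cumsum(c(TRUE, diff(st) >= isi_cut))
    for (b in unique(burst)) {
      bt <- st[burst == b]
      n <- length(bt)
      tau <- decay_tau_for_count(fm, n)
      amps <- ap_amplitudes(fm, n)
      span <- ceiling((fm$rise_time + 30 * tau) * frame_rate) + 1L
      for (j in seq_len(n)) {
        i0 <- floor(bt[j] * frame_rate) + 1L
        idx <- i0:min(i0 + span, n_frames)
        dt <- tf[idx] - bt[j]
        k <- numeric(length(idx))
        if (fm$rise_time > 0) {
          rising <- dt >= 0 & dt < fm$rise_time
          k[rising] <- amps[j] * dt[rising] / fm$rise_time
          dec <- dt >= fm$rise_time
          k[dec] <- amps[j] * exp(-(dt[dec] - fm$rise_time) / tau)
        } else {
          dec <- dt >= 0
          k[dec] <- amps[j] * exp(-dt[dec] / tau)
        }
        sig[idx] <- sig[idx] + k
      }
    }
  }

  f <- fm$background_offset + fm$baseline_f * (1 + sig)
  if (fm$noise_sd > 0 || isTRUE(fm$poisson_noise)) {
    f <- with_seed(seed, {
      out <- f
      if (fm$noise_sd > 0)
        out <- out + rnorm(n_frames, 0, fm$noise_sd * fm$baseline_f)
      if (isTRUE(fm$poisson_noise)) {
        # mean-preserving signal-dependent component; scaled so that its SD
        # at baseline equals noise_sd * baseline_f
        k <- 1 / (max(fm$noise_sd, 0.01)^2 * fm$baseline_f)
        lam <- pmax(f, 0) * k
        out <- out + (rpois(n_frames, lam) - lam) / k
      }
      out
    })
  }
  tibble(time = tf, value = f)
}
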