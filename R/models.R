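#' Bursty spike-train model for CA3-like pyramidal neurons
#'
#' Parameterizes the generative model for spike trains with the bimodal
#' interspike-interval (ISI) structure typical of hippocampal CA3 pyramidal
#' neurons: high-frequency complex-spike bursts (intraburst ISIs of a few
#' milliseconds) separated by much longer interburst intervals, plus rare
#' large prolonged firing events that occur only during locomotion.
#'
#' Intraburst ISIs are drawn from a normal distribution truncated to
#' `intraburst_floor .. 2 * intraburst_isi_mean - intraburst_floor`; the
#' symmetric bounds keep the truncated mean exactly at `intraburst_isi_mean`.
#' Interburst intervals are `interburst_offset + lognormal(shape)` winsorized
#' at `interburst_offset + interburst_cap`, with the lognormal location
#' solved so the overall mean equals `interburst_isi_mean`; the offset keeps
#' the slow ISI component separated from the fast one and the cap bounds the
#' pause tail, so that two-cluster k-means on pooled ISIs recovers both
#' component means. Burst sizes follow a geometric distribution truncated to
#' `1..burst_size_max`.
#'
#' @param intraburst_isi_mean,intraburst_isi_sd Mean and SD (s) of intraburst
#'   ISIs (defaults 5.3 ms and 7.3 ms).
#' @param intraburst_floor Refractory floor (s) on intraburst ISIs.
#' @param interburst_isi_mean Mean (s) of interburst intervals, measured
#'   last-spike-of-burst to first-spike-of-next (default 0.81 s).
#' @param interburst_shape Lognormal shape (sigma) of the interburst
#'   distribution above its offset; 0 makes intervals exactly
#'   `interburst_isi_mean` (deterministic).
#' @param interburst_cap Upper cap (s) on the lognormal part: pauses are
#'   winsorized at `interburst_offset + interburst_cap`.
#' @param interburst_offset Hard lower bound (s) on interburst intervals.
#' @param burst_size_mean Mean of the truncated-geometric burst-size
#'   distribution (APs per burst).
#' @param burst_size_max Largest burst size with support.
#' @param state_rate_multipliers Named numeric vector mapping behavioral state
#'   to a burst-rate multiplier (interburst intervals are divided by it).
#' @param large_event_rate Rate (events/min) of large prolonged firing events,
#'   inserted only during `run` state.
#' @param large_event_duration Duration (s) of a large event.
#' @param large_event_ap_count Expected AP count of one large event.
#' @return An object of class `spike_train_model`.
#' @export
spike_train_model <- function(intraburst_isi_mean = 0.0053,
                              intraburst_isi_sd = 0.0073,
                              intraburst_floor = 0.002,
                              interburst_isi_mean = 0.81,
                              interburst_shape = 1.2,
                              interburst_cap = 2.5,
                              interburst_offset = 0.5,
                              burst_size_mean = 2.13,
                              burst_size_max = 17L,
                              state_rate_multipliers = c(anesthetized = 1,
                                                         rest = 0.7,
                                                         run = 1.53),
                              large_event_rate = 2,
                              large_event_duration = 3,
                              large_event_ap_count = 40) {
  stopifnot(intraburst_isi_mean > 0, intraburst_isi_sd >= 0,
            interburst_isi_mean > 0, interburst_shape >= 0,
            interburst_cap > 0,
            intraburst_floor > 0, interburst_offset >= 0,
            burst_size_mean >= 1, burst_size_max >= 1,
            large_event_rate >= 0, large_event_duration > 0,
            large_event_ap_count > 0)
  if (intraburst_isi_mean >= interburst_isi_mean)
    abort("intraburst ISI mean must be smaller than interburst ISI mean")
  if (any(state_rate_multipliers < 0))
    abort("state rate multipliers must be >= 0")
  structure(list(
    intraburst_isi_mean = intraburst_isi_mean,
    intraburst_isi_sd = intraburst_isi_sd,
    intraburst_floor = intraburst_floor,
    interburst_isi_mean = interburst_isi_mean,
    interburst_shape = interburst_shape,
    interburst_cap = interburst_cap,
    interburst_offset = interburst_offset,
    burst_size_mean = burst_size_mean,
    burst_size_max = as.integer(burst_size_max),
    state_rate_multipliers = state_rate_multipliers,
    large_event_rate = large_event_rate,
    large_event_duration = large_event_duration,
    large_event_ap_count = large_event_ap_count
  ), class = "spike_train_model")
}

#' Spike-to-fluorescence forward model
#'
#' Describes how action potentials map to raw fluorescence: each AP adds a
#' fast-rising kernel with amplitude `single_ap_amplitude` (in dF/F units,
#' linear up to `linear_max_aps` APs per burst) that decays exponentially.
#' The decay time constant interpolates linearly with the AP count of the
#' burst from `decay_tau_single` (1 AP) to `decay_tau_max` (>= `linear_max_aps`
#' APs), reflecting slower indicator clearance after large bursts. Noise is
#' additive Gaussian per frame with `noise_sd` (dF/F-equivalent units), with
#' an optional Poisson-like, signal-dependent component.
#'
#' @param single_ap_amplitude Peak dF/F of an isolated single AP (default 0.11).
#' @param amplitude_per_ap Linear amplitude gain per AP within the linear
#'   regime (defaults to `single_ap_amplitude`).
#' @param linear_max_aps Burst size up to which amplitude grows linearly;
#'   APs beyond it contribute `saturation_gain * amplitude_per_ap`.
#' @param saturation_gain Relative gain above the linear knee.
#' @param decay_tau_single Decay time constant (s) for a single AP.
#' @param decay_tau_max Decay time constant (s) approached for large bursts.
#' @param rise_time Kernel rise time (s), sub-frame by default.
#' @param supralinear_gain Optional multiplicative amplitude factor per AP for
#'   bursts above `supralinear_threshold`; 1 disables it.
#' @param supralinear_threshold Burst size above which `supralinear_gain`
#'   applies.
#' @param noise_sd Additive Gaussian per-frame noise SD (dF/F-equivalent).
#' @param poisson_noise Logical; add a mean-preserving, signal-dependent
#'   (Poisson-like) noise component.
#' @param background_offset Raw-fluorescence background level.
#' @param baseline_f Raw-fluorescence baseline of the neuron.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(single_ap_amplitude = 0.11,
                          amplitude_per_ap = single_ap_amplitude,
                          linear_max_aps = 10L,
                          saturation_gain = 0.5,
                          decay_tau_single = 0.3,
                          decay_tau_max = 0.8,
                          rise_time = 0,
                          supralinear_gain = 1,
                          supralinear_threshold = 10L,
                          noise_sd = 0.05,
                          poisson_noise = FALSE,
                          background_offset = 10,
                          baseline_f = 100) {
  stopifnot(single_ap_amplitude >= 0, amplitude_per_ap >= 0,
            decay_tau_single > 0, decay_tau_max > 0, rise_time >= 0,
            noise_sd >= 0, supralinear_gain >= 1)
  if (decay_tau_single > decay_tau_max)
    abort("decay_tau_single must be <= decay_tau_max")
  if (!(baseline_f > background_offset && background_offset >= 0))
    abort("need baseline_f > background_offset >= 0")
  structure(list(
    single_ap_amplitude = single_ap_amplitude,
    amplitude_per_ap = amplitude_per_ap,
    linear_max_aps = as.integer(linear_max_aps),
    saturation_gain = saturation_gain,
    decay_tau_single = decay_tau_single,
    decay_tau_max = decay_tau_max,
    rise_time = rise_time,
    supralinear_gain = supralinear_gain,
    supralinear_threshold = as.integer(supralinear_threshold),
    noise_sd = noise_sd,
    poisson_noise = poisson_noise,
    background_offset = background_offset,
    baseline_f = baseline_f
  ), class = "forward_model")
}

#' Specification of a multi-day population imaging session
#'
#' Imaging follows the trial structure of head-fixed two-photon experiments:
#' up to 30 trials of 30 s at 10 Hz with 10-s inter-trial gaps (no frames are
#' acquired in the gaps), in a 325 x 325 um field of view. Neuron identities,
#' ROI centroids, per-neuron amplitude scaling, co-activity group membership
#' and large-event propensity all persist across days.
#'
#' @param n_neurons Number of neurons in the field of view.
#' @param n_days Number of consecutive imaging days.
#' @param n_trials Trials per day (<= 30).
#' @param trial_length Trial duration (s).
#' @param inter_trial_gap Gap between trials (s).
#' @param frame_rate Imaging frame rate (Hz).
#' @param condition `"anesthetized"` (rest-only, no locomotion, no large
#'   events) or `"awake"`.
#' @param coactivity_groups List of planted co-activity groups; each element a
#'   list with `neurons` (integer indices), `p_shared` (probability each member
#'   expresses a group event), `rate_per_min` (group event rate) and optional
#'   `burst_size` (APs per group event, default 8).
#' @param large_event_fraction Fraction of neurons (persistent subset) that
#'   generate large locomotion events in awake sessions.
#' @param amplitude_scale_sd SD of the per-neuron lognormal amplitude scaling
#'   (0 disables heterogeneity).
#' @param fov_um Field-of-view side length (um).
#' @param centroid_min_dist Minimum distance (um) enforced between centroids.
#' @param seed Master RNG seed for the session; per-neuron and per-day streams
#'   are derived from it.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_neurons = 12L,
                         n_days = 2L,
                         n_trials = 10L,
                         trial_length = 30,
                         inter_trial_gap = 10,
                         frame_rate = 10,
                         condition = c("awake", "anesthetized"),
                         coactivity_groups = list(),
                         large_event_fraction = 0.25,
                         amplitude_scale_sd = 0.2,
                         fov_um = 325,
                         centroid_min_dist = 5,
                         seed = 1L) {
  condition <- match.arg(condition)
  if (!(n_trials >= 1 && n_trials <= 30))
    abort("n_trials must be in 1..30")
  stopifnot(n_neurons >= 1, n_days >= 1, trial_length > 0,
            inter_trial_gap >= 0, frame_rate > 0,
            large_event_fraction >= 0, large_event_fraction <= 1)
  for (g in coactivity_groups) {
    if (is.null(g$neurons) || is.null(g$p_shared) || is.null(g$rate_per_min))
      abort("each coactivity group needs neurons, p_shared and rate_per_min")
    if (any(g$neurons < 1 | g$neurons > n_neurons))
      abort("coactivity group references unknown neuron index")
    if (g$p_shared < 0 || g$p_shared > 1)
      abort("shared-event probability must be in [0, 1]")
  }
  structure(list(
    n_neurons = as.integer(n_neurons), n_days = as.integer(n_days),
    n_trials = as.integer(n_trials), trial_length = trial_length,
    inter_trial_gap = inter_trial_gap, frame_rate = frame_rate,
    condition = condition, coactivity_groups = coactivity_groups,
    large_event_fraction = large_event_fraction,
    amplitude_scale_sd = amplitude_scale_sd,
    fov_um = fov_um, centroid_min_dist = centroid_min_dist,
    seed = as.integer(seed)
  ), class = "session_spec")
}
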