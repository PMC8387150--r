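# spike-rate inference: nonnegative kernel deconvolution stand-in

#' Deconvolve a dF/F trace into an instantaneous spike rate
#'
#' Transparent stand-in for supervised spike inference with the same
#' interface: per trial, solves a nonnegative least-squares problem against
#' the calibrated single-AP kernel (amplitude and decay time constant from a
#' [forward_model()] or a `ca_calibration`), yielding AP counts per frame,
#' which are converted to a rate (AP/s) and smoothed with a Gaussian of
#' `smoothing_fwhm` full width at half maximum (default 470 ms). Because
#' downstream consumers only see the spike-rate trace, a trained inference
#' network can be slotted in unchanged.
#'
#' @param dff Tibble with `time`, `dff`, optionally `trial`.
#' @param kernel A [forward_model()], a `ca_calibration` (its 1-AP row), or
#'   a list with `amplitude` and `tau`.
#' @param sampling_rate Optional (Hz); inferred when omitted.
#' @param smoothing_fwhm Gaussian smoothing FWHM (s).
#' @return Tibble with `time`, `trial`, `sr` (AP/s, nonnegative).
#' @export
deconvolve <- function(dff, kernel, sampling_rate = NULL,
                       smoothing_fwhm = 0.470) {
  sr_hz <- infer_rate(dff, sampling_rate)
  if (inherits(kernel, "forward_model")) {
    amp <- kernel$single_ap_amplitude
    tau <- kernel$decay_tau_single
  } else if (inherits(kernel, "ca_calibration")) {
    row <- kernel$curve[kernel$curve$ap_count == 1L, ]
    if (nrow(row) == 0L) abort("calibration has no 1-AP entry")
    amp <- row$mean_peak_dff[1]
    tau <- row$decay_tau[1]
  } else if (is.list(kernel) &&
             all(c("amplitude", "tau") %in% names(kernel))) {
    amp <- kernel$amplitude
    tau <- kernel$tau
  } else abort("kernel must be a forward_model, ca_calibration, or list")
  if (tau <= 0 || amp <= 0) abort("kernel needs positive amplitude and tau")
  if (1 / sr_hz > 4 * tau)
    abort("frame interval is too long for the kernel decay (rate mismatch)")

  trl <- trial_col(dff)
  out <- dff[intersect(c("time", "trial"), names(dff))]
  if (!"trial" %in% names(out)) out$trial <- trl
  out$sr <- NA_real_
  klen_max <- 0
  for (tr in unique(trl)) {
    idx <- which(trl == tr)
    y <- dff$dff[idx]
    n <- length(y)
    klen <- min(n, ceiling(8 * tau * sr_hz) + 1L)
    klen_max <- max(klen_max, klen)
    kern <- amp * exp(-(seq_len(klen) - 1L) / (tau * sr_hz))
    G <- matrix(0, n, n)
    for (j in seq_len(n)) {
      len <- min(klen, n - j + 1L)
      G[j:(j + len - 1L), j] <- kern[seq_len(len)]
    }
    sol <- pracma::lsqnonneg(G, y)
    counts <- sol$x
    out$sr[idx] <- gauss_smooth(counts * sr_hz, sr_hz, smoothing_fwhm)
  }
  out$sr <- pmax(out$sr, 0)
  out
}

#' Detect peaks in a spike-rate trace
#'
#' Same greedy peak machinery as dF/F event detection, with the spike-rate
#' thresholds: minimal prominence 1.5 AP/s and minimal separation 1.5 s.
#'
#' @param sr Tibble with `time`, `sr`, optionally `trial`.
#' @param min_prominence Minimal prominence (AP/s).
#' @param min_separation Minimal separation (s).
#' @return Tibble with `trial`, `peak_time`, `peak_sr`.
#' @export
detect_sr_events <- function(sr, min_prominence = 1.5,
                             min_separation = 1.5) {
  trl <- trial_col(sr)
  rows <- lapply(unique(trl), function(tr) {
    idx <- which(trl == tr)
    pk <- free_peaks(sr$sr[idx], sr$time[idx], min_prominence,
                     min_separation)
    if (length(pk) == 0L) return(NULL)
    tibble(trial = tr, peak_time = sr$time[idx][pk],
           peak_sr = sr$sr[idx][pk])
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L)
    res <- tibble(trial = integer(0), peak_time = numeric(0),
                  peak_sr = numeric(0))
  res
}

#' Correlation between inferred spike rate and ground truth
#'
#' Bins the true spike train at the spike-rate trace's frame times, smooths
#' it with the same Gaussian FWHM used for inference, and reports the
#' Pearson correlation.
#'
#' @param sr Tibble with `time`, `sr` (from [deconvolve()]).
#' @param spikes Spikes tibble or numeric vector of spike times.
#' @param smoothing_fwhm Gaussian FWHM (s) applied to the binned truth.
#' @return List with `correlation` and `n_frames`; correlation is `NA` with
#'   a warning when either trace has zero variance.
#' @export
evaluate_inference <- function(sr, spikes, smoothing_fwhm = 0.470) {
  st <- if (is.data.frame(spikes)) spikes$spike_time else as.numeric(spikes)
  rate <- infer_rate(sr)
  edges <- c(sr$time - 0.5 / rate, max(sr$time) + 0.5 / rate)
  inb <- st[st >= edges[1] & st < edges[length(edges)]]
  counts <- tabulate(findInterval(inb, edges), nbins = nrow(sr))
  truth <- gauss_smooth(counts * rate, rate, smoothing_fwhm)
  if (sd(truth) == 0 || sd(sr$sr) == 0) {
    warn("zero-variance trace; correlation undefined")
    return(list(correlation = NA_real_, n_frames = nrow(sr)))
  }
  list(correlation = cor(sr$sr, truth), n_frames = nrow(sr))
}

#' Add mean-preserving Poisson-like noise to a trace
#'
#' Matches a clean (e.g. ground-truth) trace to the noise level of a target
#' recording by adding centered, signal-dependent Poisson noise: the added
#' component has zero mean and SD `target_sd * sqrt(pmax(value, eps) /
#' mean(value))` per frame, so the mean signal is preserved while the noise
#' scales with brightness.
#'
#' @param trace Tibble with a `value` column (raw fluorescence).
#' @param target_sd Desired noise SD at the mean signal level (raw units).
#' @param seed Optional RNG seed.
#' @return The trace with noise added to `value`.
#' @export
match_noise <- function(trace, target_sd, seed = NULL) {
  stopifnot(is.data.frame(trace), "value" %in% names(trace), target_sd >= 0)
  if (target_sd == 0) return(trace)
  with_seed(seed, {
    v <- trace$value
    mu <- mean(v)
    if (mu <= 0) abort("trace mean must be positive for Poisson-like noise")
    k <- mu / target_sd^2  # events per raw unit; var = value / k
    lam <- pmax(v, 1e-9) * k
    trace$value <- v + (rpois(length(v), lam) - lam) / k
    trace
  })
}
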