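# raw fluorescence -> smoothed dF/F

#' Estimate background fluorescence
#'
#' Returns the 1st percentile (linear-interpolation convention) of the
#' supplied signal over the whole session. The signal should be a dedicated
#' background measurement (e.g. a neuropil or off-cell region); applying it
#' to the ROI's own trace is possible but warned against, because
#' self-percentile subtraction nulls part of the baseline.
#'
#' @param signal Numeric vector or a tibble with a `value` column.
#' @param percentile Percentile (0-100) to use, default 1.
#' @param self Set `TRUE` to acknowledge (and silence the warning for)
#'   estimating background from the ROI trace itself.
#' @return Scalar background level in raw fluorescence units.
#' @export
estimate_background <- function(signal, percentile = 1, self = FALSE) {
  x <- if (is.data.frame(signal)) signal$value else as.numeric(signal)
  assert_finite(x, "background signal")
  if (isTRUE(self))
    warn("estimating background from the ROI trace itself biases dF/F")
  pctl(x, percentile)
}

# brute-force centered sliding-window percentile, truncated at edges;
# x is one trial's samples
sliding_percentile <- function(x, half_frames, percentile) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_frames)
    hi <- min(n, i + half_frames)
    pctl(x[lo:hi], percentile)
  }, numeric(1))
}

#' Compute dF/F with a sliding-percentile baseline
#'
#' Subtracts the background, estimates the baseline F0 as the `percentile`th
#' percentile (default 51) of the background-subtracted signal in a centered
#' sliding window of `window` seconds (default 8 s; truncated at trial
#' edges), and returns `dff = (F - F0) / F0`. Processing is strictly per
#' trial: windows never cross inter-trial gaps.
#'
#' @param trace Tibble with columns `time`, `value` and optionally `trial`
#'   (defaults to a single trial).
#' @param background Scalar background level (raw units), e.g. from
#'   [estimate_background()].
#' @param window Sliding-window length (s).
#' @param percentile Baseline percentile (0-100).
#' @param sampling_rate Optional sampling rate (Hz); inferred from `time`
#'   when omitted.
#' @return A tibble with columns `time`, `trial`, `dff` (fraction), `f0`
#'   (raw units, background-subtracted).
#' @export
compute_dff <- function(trace, background, window = 8, percentile = 51,
                        sampling_rate = NULL) {
  stopifnot(is.data.frame(trace), all(c("time", "value") %in% names(trace)))
  assert_finite(trace$value, "fluorescence")
  sr <- infer_rate(trace, sampling_rate)
  half <- floor(window / 2 * sr + 1e-9)
  if (2 * half + 1 < 3) abort("window must span at least 3 frames")
  trl <- trial_col(trace)
  out <- lapply(split(seq_len(nrow(trace)), trl), function(idx) {
    fb <- trace$value[idx] - background
    f0 <- sliding_percentile(fb, half, percentile)
    if (any(f0 <= 1e-9))
      abort(paste0("degenerate baseline: F0 <= 0 in trial ", trl[idx[1]],
                   " (background over-subtraction?)"))
    tibble(time = trace$time[idx], trial = trl[idx],
           dff = (fb - f0) / f0, f0 = f0)
  })
  dplyr::arrange(dplyr::bind_rows(out), time)
}

# order-1 Savitzky-Golay smoothing of one vector with the package's edge
# convention: interior = 5-point moving average (the analytic identity for
# first-order fits), 3-point average at the penultimate samples, passthrough
# at the endpoints
savgol5 <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  out <- x
  out[3:(n - 2)] <- (x[1:(n - 4)] + x[2:(n - 3)] + x[3:(n - 2)] +
                       x[4:(n - 1)] + x[5:n]) / 5
  out[2] <- (x[1] + x[2] + x[3]) / 3
  out[n - 1] <- (x[n - 2] + x[n - 1] + x[n]) / 3
  out
}

#' Smooth a dF/F trace with a five-point first-order Savitzky-Golay filter
#'
#' For polynomial order 1 the Savitzky-Golay filter equals the moving
#' average, so interior samples are the 5-point running mean; the window
#' shrinks symmetrically at trial edges (3-point at the penultimate samples,
#' passthrough at the endpoints). Applied per trial. Trials shorter than
#' 5 frames are left unsmoothed with a warning.
#'
#' @param dff Tibble from [compute_dff()] (columns `time`, `trial`, `dff`).
#' @return The tibble with `dff` smoothed.
#' @export
smooth_dff <- function(dff) {
  stopifnot(is.data.frame(dff), all(c("time", "dff") %in% names(dff)))
  trl <- trial_col(dff)
  out <- dff
  for (tr in unique(trl)) {
    idx <- which(trl == tr)
    if (length(idx) < 5L) {
      warn(paste0("trial ", tr, " has fewer than 5 frames; left unsmoothed"))
      next
    }
    out$dff[idx] <- savgol5(dff$dff[idx])
  }
  out
}
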