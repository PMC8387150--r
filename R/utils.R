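# shared internal helpers

# linear-interpolation percentile (type 7), the single percentile dialect
# used across the package (background, F0, large-event threshold)
pctl <- function(x, p) {
  stats::quantile(x, p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

assert_finite <- function(x, what = "signal") {
  if (length(x) == 0L) abort(paste0(what, " is empty"))
  if (!all(is.finite(x))) abort(paste0(what, " contains non-finite values"))
  invisible(x)
}

# sampling rate of a trace tibble: explicit argument wins, otherwise the
# median time step within trials (robust to trial gaps)
infer_rate <- function(trace, sampling_rate = NULL) {
  if (!is.null(sampling_rate)) return(sampling_rate)
  if (".trial" %in% names(trace)) {
    dt <- unlist(lapply(split(trace$time, trace$.trial), function(t) diff(t)))
  } else if ("trial" %in% names(trace)) {
    dt <- unlist(lapply(split(trace$time, trace$trial), function(t) diff(t)))
  } else {
    dt <- diff(trace$time)
  }
  dt <- dt[dt > 0]
  if (length(dt) == 0L) abort("cannot infer sampling rate from a single frame")
  1 / median(dt)
}

# trial column defaulting to a single trial
trial_col <- function(df) {
  if ("trial" %in% names(df)) df$trial else rep(1L, nrow(df))
}

# Gaussian smoothing of a regularly sampled signal; fwhm in seconds.
# Kernel truncated at +/- 4 sd and renormalized at the edges.
gauss_smooth <- function(x, sampling_rate, fwhm) {
  sd_s <- fwhm / (2 * sqrt(2 * log(2)))
  sd_f <- sd_s * sampling_rate
  half <- max(1L, ceiling(4 * sd_f))
  k <- exp(-0.5 * ((-half:half) / sd_f)^2)
  n <- length(x)
  padded <- c(rep(0, half), x, rep(0, half))
  num <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- stats::filter(ones, k, sides = 2)[(half + 1):(half + n)]
  as.numeric(num / den)
}

`%||%` <- rlang::`%||%`
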