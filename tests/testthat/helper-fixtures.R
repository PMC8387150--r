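# shared fixtures, built in code

# a dF/F tibble from a plain numeric vector (10 Hz, single trial)
dff_tbl <- function(x, rate = 10, trial = 1L) {
  tibble::tibble(time = (seq_along(x) - 1) / rate, trial = trial, dff = x)
}

raw_tbl <- function(x, rate = 10) {
  tibble::tibble(time = (seq_along(x) - 1) / rate, value = x)
}

# noiseless single-AP kernel sampled at `rate`, peak `amp` at `t0`
kernel_vec <- function(times, t0, amp = 0.11, tau = 0.3) {
  ifelse(times >= t0, amp * exp(-(times - t0) / tau), 0)
}

# spike-train model with unit multipliers (no state modulation)
flat_stm <- function(...) {
  spike_train_model(state_rate_multipliers = c(anesthetized = 1, rest = 1,
                                               run = 1),
                    ...)
}

rest_schedule <- function(duration) {
  tibble::tibble(start = 0, end = duration, state = "rest")
}
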