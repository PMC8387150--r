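noiseless_dff <- function(spikes, fm, rate = 10, dur = 30) {
  fl <- simulate_fluorescence(spikes, fm, rate, dur)
  tibble::tibble(time = fl$time, trial = 1L,
                 dff = (fl$value - fm$background_offset) /
                   fm$baseline_f - 1)
}

test_that("a zero trace deconvolves to a zero spike rate", {
  d <- dff_tbl(rep(0, 100))
  sr <- deconvolve(d, forward_model())
  expect_true(all(sr$sr == 0))
})

test_that("spike-rate integrals recover AP counts in the linear regime", {
  fm <- forward_model(noise_sd = 0, decay_tau_max = 0.3)
  one <- deconvolve(noiseless_dff(5.0, fm), fm)
  expect_equal(sum(one$sr) / 10, 1, tolerance = 0.05)
  # 5 APs aligned to frame times: exact inversion
  train <- deconvolve(noiseless_dff(seq(5, 5.4, by = 0.1), fm), fm)
  expect_equal(sum(train$sr) / 10, 5, tolerance = 0.05)
  # sub-frame burst timing attenuates each AP by up to exp(-dt/tau); the
  # integral stays within that discretization loss
  burst <- 5 + cumsum(c(0, rep(0.0053, 4)))
  five <- deconvolve(noiseless_dff(burst, fm), fm)
  expect_gt(sum(five$sr) / 10, 5 * exp(-0.1 / 0.3))
  expect_lt(sum(five$sr) / 10, 5.1)
})

test_that("deconvolution is additive over separated transients", {
  fm <- forward_model(noise_sd = 0, decay_tau_max = 0.3)
  a <- deconvolve(noiseless_dff(5, fm), fm)
  b <- deconvolve(noiseless_dff(20, fm), fm)
  ab <- deconvolve(noiseless_dff(c(5, 20), fm), fm)
  expect_equal(ab$sr, a$sr + b$sr, tolerance = 1e-4)
  expect_true(all(ab$sr >= 0))
})

test_that("kernel and frame-rate mismatches are rejected", {
  d <- dff_tbl(rep(0, 100), rate = 0.5)
  expect_error(deconvolve(d, forward_model()), "mismatch")
  expect_error(deconvolve(dff_tbl(rep(0, 100)), list(amplitude = 1)),
               "kernel")
})

test_that("spike-rate peaks follow the prominence and separation rules", {
  expect_equal(nrow(detect_sr_events(
    tibble::tibble(time = (0:99) / 10, sr = rep(0, 100)))), 0L)
  tt <- (0:199) / 10
  bump <- function(t0) 3 * exp(-((tt - t0) / 0.3)^2)
  one <- detect_sr_events(tibble::tibble(time = tt, sr = bump(8)))
  expect_equal(nrow(one), 1L)
  close2 <- detect_sr_events(tibble::tibble(time = tt,
                                            sr = bump(8) + bump(9)))
  expect_equal(nrow(close2), 1L)
})

test_that("inference evaluation scores identity as 1 and independence
          near 0", {
  fm <- forward_model(noise_sd = 0, decay_tau_max = 0.3)
  st <- simulate_spike_train(flat_stm(), 120, rest_schedule(120),
                             seed = 31)
  sr <- deconvolve(noiseless_dff(st$spike_time, fm, dur = 120), fm)
  # self-correlation of the smoothed truth
  self <- evaluate_inference(
    tibble::tibble(time = sr$time,
                   sr = calico:::gauss_smooth(
                     tabulate(findInterval(
                       st$spike_time, c(sr$time - 0.05, 120)),
                       nbins = nrow(sr)) * 10, 10, 0.470)),
    st)
  expect_equal(self$correlation, 1, tolerance = 1e-9)
  # deconvolved estimate correlates strongly
  est <- evaluate_inference(sr, st)
  expect_gt(est$correlation, 0.8)
  # independent spike train correlates near zero across seeds
  null_cor <- vapply(1:5, function(i) {
    other <- simulate_spike_train(flat_stm(), 120, rest_schedule(120),
                                  seed = 400 + i)
    evaluate_inference(sr, other)$correlation
  }, numeric(1))
  expect_lt(abs(mean(null_cor)), 0.2)
  flat <- tibble::tibble(time = (0:99) / 10, sr = rep(0, 100))
  expect_warning(z <- evaluate_inference(flat, c(1, 2)), "zero-variance")
  expect_true(is.na(z$correlation))
})

test_that("noise matching preserves the mean signal", {
  tr <- raw_tbl(100 + 10 * sin((1:2000) / 50))
  noisy <- match_noise(tr, target_sd = 5, seed = 2)
  expect_equal(mean(noisy$value), mean(tr$value), tolerance = 0.005)
  expect_equal(sd(noisy$value - tr$value), 5, tolerance = 0.15)
  expect_identical(match_noise(tr, 5, seed = 2), noisy)
})
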