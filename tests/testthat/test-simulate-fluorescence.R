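test_that("empty spike train gives a constant noiseless trace", {
  fm <- forward_model(noise_sd = 0)
  fl <- simulate_fluorescence(numeric(0), fm, 10, 5)
  expect_equal(nrow(fl), 50L)
  expect_true(all(fl$value == fm$background_offset + fm$baseline_f))
})

test_that("a single AP at a frame time produces the nominal dF/F peak and
          its decay refits to the single-AP time constant", {
  fm <- forward_model(noise_sd = 0)
  fl <- simulate_fluorescence(2.0, fm, 10, 10)
  dff <- (fl$value - fm$background_offset) / fm$baseline_f - 1
  expect_equal(max(dff), 0.11, tolerance = 1e-9)
  expect_equal(fl$time[which.max(dff)], 2.0)
  post <- which(fl$time >= 2.0 & fl$time <= 3.2)
  fit <- calico:::fit_exp_decay(fl$time[post], dff[post], t0 = 2.0,
                                offset = FALSE)
  expect_equal(fit$tau, 0.3, tolerance = 1e-3)
  expect_equal(fit$amplitude, 0.11, tolerance = 1e-3)
})

test_that("noiseless forward model is additive over separated spikes", {
  fm <- forward_model(noise_sd = 0)
  a <- simulate_fluorescence(2.0, fm, 10, 20)
  b <- simulate_fluorescence(12.0, fm, 10, 20)
  ab <- simulate_fluorescence(c(2.0, 12.0), fm, 10, 20)
  base <- fm$background_offset + fm$baseline_f
  expect_equal(ab$value - base, (a$value - base) + (b$value - base),
               tolerance = 1e-9)
  # explicit summed-kernel oracle
  oracle <- base + fm$baseline_f * (kernel_vec(a$time, 2.0) +
                                      kernel_vec(a$time, 12.0))
  expect_equal(ab$value, oracle, tolerance = 1e-9)
})

test_that("burst decay interpolates between the single-AP and large-burst
          time constants", {
  fm <- forward_model(noise_sd = 0)
  expect_equal(calico:::decay_tau_for_count(fm, 1L), 0.3)
  expect_equal(calico:::decay_tau_for_count(fm, 10L), 0.8)
  expect_equal(calico:::decay_tau_for_count(fm, 25L), 0.8)
  mid <- calico:::decay_tau_for_count(fm, 5L)
  expect_true(mid > 0.3 && mid < 0.8)
  expect_equal(mid, 0.3 + (4 / 9) * 0.5)
})

test_that("spikes outside the duration are rejected", {
  fm <- forward_model()
  expect_error(simulate_fluorescence(12, fm, 10, 10), "within")
  expect_error(simulate_fluorescence(-1, fm, 10, 10), "within")
})

test_that("noise is reproducible given a seed and scales as configured", {
  fm <- forward_model(noise_sd = 0.05)
  a <- simulate_fluorescence(numeric(0), fm, 10, 100, seed = 4)
  b <- simulate_fluorescence(numeric(0), fm, 10, 100, seed = 4)
  expect_identical(a, b)
  expect_equal(sd(a$value) / fm$baseline_f, 0.05, tolerance = 0.1)
})

test_that("ground-truth pair has consistent spikes, trace and background", {
  gt <- simulate_ground_truth(flat_stm(), forward_model(), 120, seed = 2)
  expect_s3_class(gt, "ca_ground_truth")
  expect_equal(nrow(gt$fluorescence), 120 * 20)
  expect_true(all(gt$spikes$spike_time < 120))
  expect_equal(mean(gt$background$value), forward_model()$background_offset,
               tolerance = 0.05)
  expect_error(simulate_ground_truth(flat_stm(), forward_model(), 0),
               "positive")
})

test_that("33 minutes of default ground truth carries about 5000 APs", {
  tot <- 0
  for (i in 1:4) {
    tr <- simulate_spike_train(
      spike_train_model(), 495,
      tibble::tibble(start = 0, end = 495, state = "anesthetized"),
      seed = 300 + i)
    tot <- tot + nrow(tr)
  }
  expect_gt(tot, 4000)
  expect_lt(tot, 6500)
})

test_that("every spike produces a kernel onset within one frame", {
  stm <- flat_stm(burst_size_mean = 1)
  fm <- forward_model(noise_sd = 0)
  gt <- simulate_ground_truth(stm, fm, 60, seed = 9)
  dff <- (gt$fluorescence$value - fm$background_offset) / fm$baseline_f - 1
  dt <- 1 / gt$frame_rate
  for (s in gt$spikes$spike_time[gt$spikes$spike_time <=
                                 max(gt$fluorescence$time)]) {
    i <- which(gt$fluorescence$time >= s)[1]
    # the first frame at/after the spike already carries signal
    expect_gt(dff[i], 0.11 * exp(-dt / 0.3) - 1e-9)
  }
})
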