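# synthetic juxtacellular voltage: Gaussian noise plus spike templates
make_voltage <- function(spike_times, duration = 2, rate = 10000,
                         amp = 1, noise = 0.1, seed = 1) {
  set.seed(seed)
  tt <- (seq_len(duration * rate) - 1) / rate
  v <- rnorm(length(tt), 0, noise)
  for (s in spike_times) {
    idx <- which(tt >= s & tt < s + 0.001)
    v[idx] <- v[idx] + amp * exp(-((tt[idx] - s) / 3e-4)^2)
  }
  tibble::tibble(time = tt, value = v)
}

test_that("juxtacellular thresholding finds injected spikes", {
  sp <- seq(0.15, 1.95, by = 0.2)
  v <- make_voltage(sp, noise = 0.1, seed = 2)
  det <- detect_spikes_juxta(v)
  expect_equal(nrow(det), length(sp))
  expect_true(all(abs(det$spike_time - sp) <= 5e-4))
})

test_that("a noiseless template yields its exact peak and flat traces warn", {
  v <- make_voltage(1.0, noise = 1e-4, seed = 3)
  det <- detect_spikes_juxta(v)
  expect_equal(nrow(det), 1L)
  expect_equal(det$spike_time, 1.0, tolerance = 2e-4)
  flat <- tibble::tibble(time = (0:9999) / 1e4, value = rep(0, 1e4))
  expect_warning(d0 <- detect_spikes_juxta(flat), "flat")
  expect_equal(nrow(d0), 0L)
  expect_error(detect_spikes_juxta(tibble::tibble(time = (0:99) / 100,
                                                  value = rnorm(100))),
               "1 kHz")
})

test_that("pure noise yields no spikes at the default threshold", {
  fp <- vapply(1:5, function(i) {
    nrow(detect_spikes_juxta(make_voltage(numeric(0), seed = 10 + i)))
  }, numeric(1))
  expect_equal(sum(fp), 0)
})

test_that("isolation rules select exactly the qualifying AP groups", {
  fm <- forward_model(noise_sd = 0)
  # a burst at 10 s (silence since 0), a pair straddling 200 ms at 20 s,
  # and a spike at 30 s preceded by one 1.5 s earlier
  st <- c(10.0, 10.005, 10.008, 20.0, 20.25, 28.5, 30.0)
  fl <- simulate_fluorescence(st, fm, 20, 40)
  pair <- list(spikes = tibble::tibble(spike_time = st),
               fluorescence = fl, frame_rate = 20)
  iso <- select_isolated_transients(pair, background = fm$background_offset)
  expect_equal(nrow(iso), 2L)   # the 3-AP burst and the spike at 28.5
  expect_equal(iso$ap_count, c(3L, 1L))
  expect_equal(iso$first_ap, c(10.0, 28.5))
  expect_equal(iso$next_spike, c(20.0, 30.0))
})

test_that("noiseless calibration recovers the forward model exactly and
          peaks grow linearly", {
  fm <- forward_model(noise_sd = 0, decay_tau_max = 0.3)
  # constructed bursts of sizes 1..10, widely separated
  sizes <- 1:10
  st <- unlist(lapply(seq_along(sizes), function(i)
    20 * i + cumsum(c(0, rep(0.005, sizes[i] - 1)))))
  fl <- simulate_fluorescence(st, fm, 20, 220)
  pair <- list(spikes = tibble::tibble(spike_time = st),
               fluorescence = fl, frame_rate = 20)
  iso <- select_isolated_transients(pair, background = fm$background_offset)
  expect_equal(sort(iso$ap_count), sizes)
  cal <- build_calibration_curve(iso, seed = 1)
  cv <- tidy(cal)
  one <- cv[cv$ap_count == 1, ]
  expect_equal(one$mean_peak_dff, 0.11, tolerance = 0.01)
  expect_equal(one$decay_tau, 0.3, tolerance = 0.01)
  # linearity across counts (constant tau): R^2 > 0.95
  fit <- lm(mean_peak_dff ~ ap_count, data = cv)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("noisy synthetic ground truth recovers the single-AP amplitude
          within 3 SEM", {
  iso <- dplyr::bind_rows(lapply(1:2, function(i)
    select_isolated_transients(
      simulate_ground_truth(spike_train_model(), forward_model(), 400,
                            seed = 500 + i))))
  cal <- build_calibration_curve(iso, seed = 1)
  one <- tidy(cal)[tidy(cal)$ap_count == 1, ]
  expect_gt(one$n_events, 5)
  expect_lt(abs(one$mean_peak_dff - 0.11), 3 * one$sem_peak_dff + 0.01)
  expect_true(one$tau_lo90 < 0.3 + 0.05 && one$tau_hi90 > 0.3 - 0.05)
})

test_that("point-mass ISIs cluster exactly and guards trip", {
  isis <- c(rep(0.005, 50), rep(0.5, 50))
  st <- cumsum(c(0, isis))
  cl <- cluster_isis(tibble::tibble(spike_time = st), seed = 1)
  expect_equal(cl$cluster_means, c(0.005, 0.5))
  expect_equal(cl$cluster_sizes, c(50L, 50L))
  expect_error(cluster_isis(cumsum(rep(1, 5))), "at least 10")
  expect_error(cluster_isis(cumsum(rep(1, 30))), "distinct")
})

test_that("ISI clustering is invariant to input order", {
  set.seed(9)
  isis <- c(abs(rnorm(100, 0.005, 0.002)), 0.3 + rexp(100, 2))
  st1 <- cumsum(c(0, isis))
  st2 <- cumsum(c(0, sample(isis)))
  c1 <- cluster_isis(tibble::tibble(spike_time = st1), seed = 1)
  c2 <- cluster_isis(tibble::tibble(spike_time = st2), seed = 1)
  expect_equal(sort(c1$assignments$isi), sort(c2$assignments$isi))
  expect_equal(c1$cluster_means, c2$cluster_means, tolerance = 1e-12)
})

test_that("burst partition follows the ISI cut", {
  st <- cumsum(c(0, 0.005, 0.005, 0.2, 0.005))
  bs <- burst_statistics(st)
  expect_equal(bs$bursts$size, c(3L, 2L))
  all_slow <- burst_statistics(cumsum(rep(0.05, 10)))
  expect_true(all(all_slow$bursts$size == 1L))
  ev <- tibble::tibble(peak_time = 0.1)
  with_ev <- burst_statistics(st, events = ev)
  expect_equal(with_ev$event_aps$n_aps_window, 5)
  expect_equal(with_ev$event_aps$max_burst_size, 3L)
})
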