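ev_tbl <- function(...) {
  # build an events tibble from named neuron -> peak-time vectors
  args <- list(...)
  dplyr::bind_rows(lapply(seq_along(args), function(i)
    tibble::tibble(neuron_id = as.integer(names(args)[i]),
                   trial = 1L, peak_time = args[[i]])))
}

test_that("per-event co-active fractions count the other neurons", {
  ev <- ev_tbl(`1` = 5, `2` = 5, `3` = 5)
  co <- coactive_fraction_per_event(ev)
  expect_equal(co$coactive_frac, rep(1, 3))
  far <- ev_tbl(`1` = 5, `2` = 50, `3` = 100)
  expect_equal(coactive_fraction_per_event(far)$coactive_frac, rep(0, 3))
  ten <- do.call(ev_tbl, c(setNames(as.list(c(5, 5.2)), c("1", "2")),
                           setNames(as.list(seq(20, 90, by = 10)),
                                    as.character(3:10))))
  co10 <- coactive_fraction_per_event(ten)
  expect_equal(co10$coactive_frac[co10$neuron_id == 1], 1 / 9)
  expect_error(coactive_fraction_per_event(ev_tbl(`1` = 5)), "2 neurons")
})

test_that("pairwise co-activity is the symmetric mean of both directions", {
  expect_equal(pairwise_coactivity(c(1, 10), c(1, 10)), 1)
  expect_equal(pairwise_coactivity(c(1, 10), c(50, 60)), 0)
  expect_equal(pairwise_coactivity(c(1, 10), c(1.2, 20)), 0.5)
  expect_warning(v <- pairwise_coactivity(numeric(0), c(1)), "undefined")
  expect_true(is.na(v))
  # window edges are inclusive
  expect_equal(pairwise_coactivity(5, 5.5), 1)
  expect_equal(pairwise_coactivity(5, 5.5001), 0)
})

test_that("the window anchoring family behaves as specified", {
  # one-frame window: same peak frame only
  expect_equal(pairwise_coactivity(5.0, 5.04, window = 0.1), 1)
  expect_equal(pairwise_coactivity(5.0, 5.06, window = 0.1), 0)
  # 2-s window starts 0.5 s before the peak: the asymmetric interval
  # [peak - 0.5, peak + 1.5] catches the later peak but not the earlier,
  # so the symmetric measure averages to 0.5
  expect_equal(pairwise_coactivity(5, 6, window = 2), 0.5)
  expect_equal(pairwise_coactivity(5, 6.2, window = 1), 0)
  # >= 3-s windows start 1 s before the peak ([peak - 1, peak + 2])
  expect_equal(pairwise_coactivity(5, 6.9, window = 3), 0.5)
  expect_equal(pairwise_coactivity(5, 5.9, window = 3), 1)
  expect_error(pairwise_coactivity(5, 6, window = 2.5), "unknown window")
})

test_that("coincidence is nondecreasing in the window length within an
          anchor family", {
  set.seed(55)
  for (r in 1:5) {
    a <- sort(runif(8, 0, 100))
    b <- sort(runif(8, 0, 100))
    v <- vapply(c(0.5, 1, 1.5, 2), function(w)
      pairwise_coactivity(a, b, window = w), numeric(1))
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("shuffles preserve counts, trials and separation, and are
          deterministic", {
  set.seed(8)
  ev <- dplyr::bind_rows(lapply(1:4, function(n)
    tibble::tibble(neuron_id = n, trial = rep(1:3, each = 4),
                   peak_time = rep((0:2) * 40, each = 4) +
                     seq(2, 26, by = 8))))
  trials <- tibble::tibble(trial = 1:3, start = (0:2) * 40,
                           end = (0:2) * 40 + 30)
  sh <- shuffle_events(ev, trials, seed = 5)
  expect_identical(shuffle_events(ev, trials, seed = 5), sh)
  expect_equal(nrow(sh), nrow(ev))
  expect_equal(sh$trial, ev$trial)
  for (g in split(sh, list(sh$neuron_id, sh$trial))) {
    expect_true(all(diff(sort(g$peak_time)) >= 1.5))
    tr <- trials[trials$trial == g$trial[1], ]
    expect_true(all(g$peak_time >= tr$start & g$peak_time <= tr$end))
  }
  crowded <- tibble::tibble(neuron_id = 1L, trial = 1L,
                            peak_time = seq(0.1, 29.9, length.out = 25))
  expect_error(shuffle_events(crowded, trials), "unsatisfiable")
})

test_that("the shuffle null matches the analytic coincidence level for
          Poisson-like events", {
  set.seed(21)
  trials <- tibble::tibble(trial = 1L, start = 0, end = 300)
  n_ev <- 20
  ev <- dplyr::bind_rows(lapply(1:2, function(n)
    tibble::tibble(neuron_id = n, trial = 1L,
                   peak_time = sort(calico:::draw_separated(n_ev, 0, 300,
                                                            1.5)))))
  null <- shuffle_null(ev, trials, n_shuffles = 200, seed = 3)
  # expected chance coincidence for n_ev peaks in [0, 300] with a 1-s
  # window, estimated by brute-force Monte Carlo with the same redraw
  mc <- mean(replicate(300, {
    a <- sort(runif(n_ev, 0, 300))
    b <- calico:::draw_separated(n_ev, 0, 300, 1.5)
    mean(vapply(a, function(t) any(abs(b - t) <= 0.5), logical(1)))
  }))
  expect_equal(null$null_coactivity[1], mc, tolerance = 0.2)
  # ... and is in the ballpark of 1 - exp(-r w)
  expect_equal(null$null_coactivity[1], 1 - exp(-n_ev / 300 * 1),
               tolerance = 0.25)
  expect_identical(shuffle_null(ev, trials, n_shuffles = 5, seed = 9),
                   shuffle_null(ev, trials, n_shuffles = 5, seed = 9))
})

test_that("stability is 1 for identical days and near 0 for independent
          days", {
  set.seed(13)
  base <- coactivity_pairs(dplyr::bind_rows(lapply(1:5, function(n)
    tibble::tibble(neuron_id = n, trial = 1L,
                   peak_time = sort(runif(8, 0, 200)), day = 1L))))
  two <- dplyr::bind_rows(base, dplyr::mutate(base, day = 2L))
  st <- across_day_stability(two)
  expect_equal(st$rho, 1)
  # independent random matrices across seeds
  rhos <- vapply(1:8, function(i) {
    p1 <- tibble::tibble(day = 1L, neuron_a = rep(1:5, each = 5),
                         neuron_b = rep(6:10, 5),
                         coactivity = runif(25))
    p2 <- dplyr::mutate(p1, day = 2L, coactivity = runif(25))
    across_day_stability(dplyr::bind_rows(p1, p2))$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.2)
  expect_warning(
    across_day_stability(tibble::tibble(day = c(1, 2), neuron_a = 1,
                                        neuron_b = 2,
                                        coactivity = c(0.1, 0.2))),
    "common pairs")
})

test_that("centroid distances identify neighbors (3-4-5 triangle)", {
  cent <- tibble::tibble(neuron_id = 1:3, x_um = c(0, 3, 100),
                         y_um = c(0, 4, 100))
  pd <- pair_distances(cent)
  expect_equal(pd$distance[pd$neuron_a == 1 & pd$neuron_b == 2], 5)
  expect_true(pd$neighbor[1])
  expect_equal(sum(pd$neighbor), 1L)
})

test_that("neighbor exclusion is a no-op when all pairs are distant", {
  set.seed(77)
  ev <- dplyr::bind_rows(lapply(1:4, function(n) dplyr::bind_rows(
    tibble::tibble(neuron_id = n, trial = 1L, day = 1L,
                   peak_time = sort(runif(6, 0, 150))),
    tibble::tibble(neuron_id = n, trial = 1L, day = 2L,
                   peak_time = sort(runif(6, 0, 150))))))
  pairs <- coactivity_pairs(ev)
  cent <- tibble::tibble(neuron_id = 1:4, x_um = c(0, 50, 100, 150),
                         y_um = 0)
  dd <- distance_dependence(pairs, cent)
  expect_equal(dd$stability_all$rho, dd$stability_excluded$rho)
  expect_error(distance_dependence(pairs, cent[1:3, ]), "centroid")
})

test_that("day statistics correlate perfectly for identical days and the
          degenerate incidence case is handled", {
  ev1 <- tibble::tibble(neuron_id = rep(1:5, each = 3), day = 1L,
                        peak_dff = rep(c(0.2, 0.3, 0.4, 0.5, 0.6),
                                       each = 3),
                        fwhm = rep(c(0.5, 0.6, 0.7, 0.8, 0.9), each = 3),
                        iei = rep(c(2, 3, 4, 5, 6), each = 3))
  two <- dplyr::bind_rows(ev1, dplyr::mutate(ev1, day = 2L))
  st <- day_stats(two)
  expect_equal(nrow(st), 10L)
  corr <- day_stat_correlations(st)
  expect_equal(corr$rho, rep(1, 3))
})

test_that("the Monte Carlo incidence null matches the exact two-day
          hypergeometric oracle", {
  n <- 12L; k1 <- 6L; k2 <- 6L
  flags <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 1:n, day = 1L,
                   has_large = c(rep(TRUE, k1), rep(FALSE, n - k1))),
    tibble::tibble(neuron_id = 1:n, day = 2L,
                   has_large = c(rep(TRUE, k2), rep(FALSE, n - k2))))
  inc <- large_event_incidence_null(flags, n_sims = 2e4, seed = 4)
  # exact null mean of (both-days fraction among >= 1-day neurons):
  # overlap B ~ Hypergeometric(n, k1, k2)
  bb <- 0:min(k1, k2)
  pb <- dhyper(bb, k1, n - k1, k2)
  exact <- sum(pb * bb / (k1 + k2 - bb))
  expect_equal(unname(inc$chance["ge2_days"]), exact, tolerance = 0.02)
  # observed: all 6 overlap -> 6 / 6 of >= 1-day neurons have both days
  expect_equal(inc$observed$value[1], 6 / 6)
  expect_lt(inc$p_value[["ge2_days"]], 0.05)
})

test_that("perfect per-day incidence is degenerate", {
  flags <- dplyr::bind_rows(lapply(1:3, function(d)
    tibble::tibble(neuron_id = 1:5, day = d, has_large = TRUE)))
  inc <- large_event_incidence_null(flags, n_sims = 500, seed = 1)
  expect_equal(inc$observed$value, c(1, 1))
  expect_equal(unname(inc$chance), c(1, 1))
  expect_equal(unname(inc$p_value), c(1, 1))
  expect_error(large_event_incidence_null(flags[flags$day == 1, ]),
               "2 days")
})

test_that("condition ratios propagate SEM as specified", {
  r1 <- condition_ratio(1, 0.1, 1, 0.1)
  expect_equal(r1$ratio, 1)
  expect_equal(r1$sem, sqrt(0.02))
  r2 <- condition_ratio(2, 0.1, 1, 0.1)
  expect_equal(r2$ratio, 2)
  expect_equal(r2$sem, 2 * sqrt((0.1 / 2)^2 + 0.1^2))
  expect_equal(r2$sem, 0.2236, tolerance = 1e-3)
  expect_error(condition_ratio(2, 0.1, 1, 0.1, null_b = 1), "zero")
})
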