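test_that("background is the 1st percentile under the documented
          convention", {
  expect_equal(estimate_background(rep(100, 50)), 100)
  # linear-interpolation (type 7) percentile
  expect_equal(estimate_background(raw_tbl(1:100)),
               quantile(1:100, 0.01, type = 7, names = FALSE))
  expect_error(estimate_background(c(1, NaN, 3)), "non-finite")
  expect_error(estimate_background(numeric(0)), "empty")
  expect_warning(estimate_background(1:100, self = TRUE), "bias")
})

test_that("dF/F of a constant trace is zero and degenerate baselines
          error", {
  tr <- raw_tbl(rep(200, 100))
  dff <- compute_dff(tr, 100)
  expect_equal(dff$dff, rep(0, 100))
  expect_equal(dff$f0, rep(100, 100))
  expect_error(compute_dff(tr, 200), "degenerate baseline")
})

test_that("a brief plateau over a flat baseline yields 100% dF/F", {
  x <- rep(100, 100)
  x[48:52] <- 200
  dff <- compute_dff(raw_tbl(x), 0)
  # 5 elevated frames cannot move the 51st percentile of an 81-frame window
  expect_equal(max(dff$dff), 1.0, tolerance = 1e-9)
})

test_that("sliding-percentile baseline equals the brute-force oracle", {
  set.seed(31)
  x <- 100 + cumsum(rnorm(120)) + rexp(120, 1 / 5)
  dff <- compute_dff(raw_tbl(x), 10, window = 4, percentile = 51)
  half <- floor(4 / 2 * 10)
  oracle <- vapply(seq_along(x), function(i) {
    w <- (x - 10)[max(1, i - half):min(length(x), i + half)]
    quantile(w, 0.51, type = 7, names = FALSE)
  }, numeric(1))
  expect_equal(dff$f0, oracle)
  expect_equal(dff$dff, ((x - 10) - oracle) / oracle)
})

test_that("dF/F is invariant under rescaling of the net fluorescence", {
  set.seed(5)
  x <- 100 + rexp(200, 1 / 10)
  a <- compute_dff(raw_tbl(x), 20)
  b <- compute_dff(raw_tbl(3 * (x - 20) + 20), 20)
  expect_equal(a$dff, b$dff, tolerance = 1e-12)
})

test_that("baseline windows never cross trial gaps", {
  x1 <- rep(100, 50)
  x2 <- rep(300, 50)
  tr <- tibble::tibble(time = c((0:49) / 10, 40 + (0:49) / 10),
                       value = c(x1, x2),
                       trial = rep(1:2, each = 50))
  dff <- compute_dff(tr, 0, sampling_rate = 10)
  expect_equal(dff$f0, c(rep(100, 50), rep(300, 50)))
  expect_equal(dff$dff, rep(0, 100))
})

test_that("order-1 Savitzky-Golay equals the moving average and preserves
          lines", {
  s <- smooth_dff(dff_tbl(c(0, 0, 10, 0, 0)))
  expect_equal(s$dff[3], 2)
  const <- smooth_dff(dff_tbl(rep(0.4, 30)))
  expect_equal(const$dff, rep(0.4, 30))
  ramp <- smooth_dff(dff_tbl(seq(0, 1, length.out = 30)))
  expect_equal(ramp$dff[3:28], seq(0, 1, length.out = 30)[3:28],
               tolerance = 1e-12)
})

test_that("interior smoothing matches the reference Savitzky-Golay
          filter", {
  skip_if_not_installed("signal")
  set.seed(77)
  x <- rnorm(60)
  ours <- smooth_dff(dff_tbl(x))$dff
  ref <- signal::sgolayfilt(x, p = 1, n = 5)
  expect_equal(ours[3:58], ref[3:58], tolerance = 1e-10)
})

test_that("smoothing preserves the interior mean and never raises the
          max", {
  set.seed(19)
  for (i in 1:5) {
    x <- rexp(40)
    s <- smooth_dff(dff_tbl(x))$dff
    expect_lte(max(s), max(x) + 1e-12)
    expect_equal(mean(s[3:38]),
                 mean(stats::filter(x, rep(1 / 5, 5))[3:38]))
  }
})

test_that("short trials are left unsmoothed with a warning", {
  d <- dff_tbl(c(1, 2, 3))
  expect_warning(s <- smooth_dff(d), "fewer than 5")
  expect_equal(s$dff, c(1, 2, 3))
})

test_that("per-trial processing is order-equivariant", {
  set.seed(101)
  x1 <- 100 + rexp(60); x2 <- 150 + rexp(60)
  t12 <- tibble::tibble(time = c((0:59) / 10, 40 + (0:59) / 10),
                        value = c(x1, x2), trial = rep(1:2, each = 60))
  t21 <- tibble::tibble(time = c((0:59) / 10, 40 + (0:59) / 10),
                        value = c(x2, x1), trial = rep(1:2, each = 60))
  a <- compute_dff(t12, 50, sampling_rate = 10)
  b <- compute_dff(t21, 50, sampling_rate = 10)
  expect_equal(a$dff[a$trial == 1], b$dff[b$trial == 2])
  expect_equal(a$dff[a$trial == 2], b$dff[b$trial == 1])
})
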