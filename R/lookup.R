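# model-free mean-dF/F -> AP-count look-up table with a GP confidence
# corridor

#' Downsample a trace by an integer factor
#'
#' Averages consecutive groups of `factor` frames (value = group mean,
#' time = group mean time), e.g. to resample 20-Hz ground-truth imaging to
#' the 10-Hz population frame rate.
#'
#' @param trace Tibble with `time` and one signal column (`value` or `dff`).
#' @param factor Integer decimation factor.
#' @return Tibble with the same columns, downsampled.
#' @export
resample_trace <- function(trace, factor) {
  stopifnot(is.data.frame(trace), factor >= 1, factor == round(factor))
  n <- floor(nrow(trace) / factor)
  if (n < 1) abort("trace shorter than one output frame")
  idx <- rep(seq_len(n), each = factor)
  used <- seq_len(n * factor)
  out <- tibble(time = as.numeric(tapply(trace$time[used], idx, mean)))
  for (col in intersect(c("value", "dff", "speed"), names(trace)))
    out[[col]] <- as.numeric(tapply(trace[[col]][used], idx, mean))
  out
}

# ---- exact squared-exponential GP regression ----------------------------

gp_solve <- function(x, y, ell, sf2, sn2) {
  K <- sf2 * exp(-0.5 * outer(x, x, "-")^2 / ell^2)
  diag(K) <- diag(K) + sn2 + 1e-10
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  list(L = L, alpha = alpha, x = x, ell = ell, sf2 = sf2, sn2 = sn2)
}

gp_predict <- function(fit, xstar) {
  Ks <- fit$sf2 * exp(-0.5 * outer(xstar, fit$x, "-")^2 / fit$ell^2)
  mu <- as.numeric(Ks %*% fit$alpha)
  v <- backsolve(fit$L, t(Ks), transpose = TRUE)
  lat <- pmax(fit$sf2 - colSums(v^2), 0)
  list(mean = mu, var_latent = lat, var_pred = lat + fit$sn2)
}

# k-fold CV negative log predictive density for one hyperparameter setting
gp_cv_nlpd <- function(x, y, ell, sf2, sn2, folds) {
  nl <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    fit <- gp_solve(x[tr], y[tr], ell, sf2, sn2)
    pr <- gp_predict(fit, x[!tr])
    nl <- nl + sum(0.5 * log(2 * pi * pr$var_pred) +
                     (y[!tr] - pr$mean)^2 / (2 * pr$var_pred))
  }
  nl
}

#' Build the mean-dF/F to AP-count look-up table
#'
#' For every calcium transient detected in the ground-truth pairs (after
#' resampling the fluorescence to `target_rate`, anesthetized detection
#' criteria), pairs the 3-s-window mean dF/F with the true AP count in the
#' same window. Two descriptions are fitted: (a) a linear reference line on
#' points with mean dF/F below `linear_below` (default 40%), and (b) a
#' model-free smooth regression -- an exact Gaussian process with a squared-
#' exponential kernel, hyperparameters selected by k-fold cross-validated
#' predictive log density -- whose 95% predictive corridor quantifies the
#' uncertainty. The estimate is projected to be monotone nondecreasing
#' (isotonic regression) and anchored at (0, 0).
#'
#' @param pairs A `ca_ground_truth` object or list of them.
#' @param target_rate Analysis frame rate (Hz) after resampling.
#' @param linear_below Upper mean-dF/F bound (fraction) for the linear fit.
#' @param min_events Minimal number of detected ground-truth events.
#' @param n_grid Grid size of the table support.
#' @param n_max Maximal number of events used for the GP (subsampled,
#'   seeded).
#' @param n_folds Cross-validation folds.
#' @param seed RNG seed (subsampling, folds).
#' @param smooth Apply Savitzky-Golay smoothing before detection.
#' @return Object of class `ca_lookup` with elements `grid` (tibble
#'   `support`, `ap_estimate`, `corridor_low`, `corridor_high`),
#'   `linear_fit` (`slope`, `intercept`, `valid_below`), `gp`
#'   (hyperparameters), `events` (the (x, y) pairs), `n_events`.
#' @export
build_lookup_table <- function(pairs, target_rate = 10, linear_below = 0.40,
                               min_events = 100L, n_grid = 101L,
                               n_max = 400L, n_folds = 5L, seed = 1L,
                               smooth = TRUE) {
  if (inherits(pairs, "ca_ground_truth")) pairs <- list(pairs)
  xy <- list()
  for (pair in pairs) {
    fac <- round(pair$frame_rate / target_rate)
    fl <- if (fac > 1) resample_trace(pair$fluorescence, fac)
    else pair$fluorescence
    bg <- estimate_background(pair$background)
    dff <- compute_dff(fl, bg)
    if (smooth) dff <- smooth_dff(dff)
    ev <- detect_events(dff, condition = "anesthetized")
    if (nrow(ev) == 0L) next
    ev <- event_stats(dff, ev)
    st <- pair$spikes$spike_time
    cnt <- vapply(ev$peak_time, function(pt)
      sum(st >= pt - 1 & st <= pt + 2), numeric(1))
    xy[[length(xy) + 1L]] <- tibble(mean_dff_3s = ev$mean_dff_3s,
                                    ap_count = cnt)
  }
  events <- dplyr::bind_rows(xy)
  if (nrow(events) > 0)
    events <- events[is.finite(events$mean_dff_3s), ]
  if (nrow(events) < min_events)
    abort(paste0("only ", nrow(events),
                 " ground-truth events detected; need >= ", min_events))

  lin_pts <- events[events$mean_dff_3s < linear_below, ]
  lf <- stats::lm(ap_count ~ mean_dff_3s, data = lin_pts)
  linear_fit <- list(slope = unname(stats::coef(lf)[2]),
                     intercept = unname(stats::coef(lf)[1]),
                     valid_below = linear_below)

  with_seed(seed, {
    sub <- events
    if (nrow(sub) > n_max) sub <- sub[sample(nrow(sub), n_max), ]
    # (0, 0) anchor: zero integral dF/F implies zero APs
    x <- c(0, sub$mean_dff_3s)
    y <- c(0, sub$ap_count)
    folds <- sample(rep_len(seq_len(n_folds), length(x)))
    sf2 <- stats::var(y)
    res_var <- stats::var(stats::residuals(lf))
    ells <- diff(range(x)) * c(0.05, 0.1, 0.2, 0.4)
    sn2s <- res_var * c(0.5, 1, 2, 4)
    best <- NULL; best_nl <- Inf
    for (ell in ells) for (sn2 in sn2s) {
      nl <- gp_cv_nlpd(x, y, ell, sf2, sn2, folds)
      if (nl < best_nl) { best_nl <- nl; best <- c(ell = ell, sn2 = sn2) }
    }
    fit <- gp_solve(x, y, best[["ell"]], sf2, best[["sn2"]])
    support <- seq(0, max(x), length.out = n_grid)
    pr <- gp_predict(fit, support)
    est <- pmax(stats::isoreg(support, pr$mean)$yf, 0)
    est[1] <- 0
    half <- 1.96 * sqrt(pr$var_pred)
    lo <- pmax(pmin(pr$mean - half, est), 0)
    lo[1] <- 0
    hi <- pmax(pr$mean + half, est)
    structure(list(
      grid = tibble(support = support, ap_estimate = est,
                    corridor_low = lo, corridor_high = hi),
      linear_fit = linear_fit,
      gp = list(lengthscale = best[["ell"]], signal_var = sf2,
                noise_var = best[["sn2"]], n_train = length(x),
                cv_nlpd = best_nl),
      events = events, n_events = nrow(events)
    ), class = "ca_lookup")
  })
}

#' Estimate AP counts from a look-up table
#'
#' Linearly interpolates the table's estimate and 95% corridor at the
#' queried mean-dF/F values. Queries beyond the table support are
#' extrapolated along the linear reference line with the last corridor
#' width doubled, and flagged.
#'
#' @param table A `ca_lookup` object.
#' @param mean_dff_3s Numeric vector of query values (fractions, >= 0).
#' @return Tibble with `query`, `estimate`, `corridor_low`, `corridor_high`,
#'   `extrapolated`.
#' @export
estimate_ap_count <- function(table, mean_dff_3s) {
  stopifnot(inherits(table, "ca_lookup"))
  q <- as.numeric(mean_dff_3s)
  if (any(!is.finite(q)) || any(q < 0))
    abort("queries must be finite and >= 0")
  g <- table$grid
  xmax <- max(g$support)
  inside <- q <= xmax
  est <- lo <- hi <- numeric(length(q))
  if (any(inside)) {
    est[inside] <- approx(g$support, g$ap_estimate, q[inside])$y
    lo[inside] <- approx(g$support, g$corridor_low, q[inside])$y
    hi[inside] <- approx(g$support, g$corridor_high, q[inside])$y
  }
  if (any(!inside)) {
    n <- nrow(g)
    last_w <- g$corridor_high[n] - g$corridor_low[n]
    ext <- g$ap_estimate[n] + table$linear_fit$slope * (q[!inside] - xmax)
    est[!inside] <- ext
    lo[!inside] <- pmax(ext - last_w, 0)
    hi[!inside] <- ext + last_w
  }
  tibble(query = q, estimate = est, corridor_low = lo, corridor_high = hi,
         extrapolated = !inside)
}
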