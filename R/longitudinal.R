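# across-day stability, distance dependence, large-event incidence nulls

#' Trials table of a session spec
#'
#' @param spec A [session_spec()].
#' @param margin Seconds trimmed from each trial end when redrawing peaks
#'   (keeps shuffled peaks detectable within the trial).
#' @return Tibble with `trial`, `start`, `end`.
#' @export
trials_table <- function(spec, margin = 0) {
  starts <- trial_starts(spec)
  tibble(trial = seq_len(spec$n_trials), start = starts + margin,
         end = starts + spec$trial_length - margin)
}

#' Across-day stability of pairwise co-activity
#'
#' Pearson correlation of pair co-activity values on day N + 1 against day
#' N, over the pairs defined (non-`NA`) on both days. When the pair table
#' carries a `null_coactivity` column (from [shuffle_null()]), the same
#' correlation of the shuffled values is reported as the chance reference.
#'
#' @param pair_tbl Tibble from [coactivity_pairs()] (needs `day`,
#'   `neuron_a`, `neuron_b`, `coactivity`).
#' @param min_pairs Minimal number of common pairs (fewer gives `NA`, with
#'   a warning).
#' @return Tibble with `day_n`, `day_n1`, `n_pairs`, `rho` and (when
#'   available) `rho_shuffled`.
#' @export
across_day_stability <- function(pair_tbl, min_pairs = 3L) {
  stopifnot("day" %in% names(pair_tbl))
  days <- sort(unique(pair_tbl$day))
  has_null <- "null_coactivity" %in% names(pair_tbl)
  rows <- lapply(days[-length(days)], function(d) {
    a <- pair_tbl[pair_tbl$day == d, ]
    b <- pair_tbl[pair_tbl$day == d + 1, ]
    if (nrow(b) == 0L) return(NULL)
    j <- inner_join(a, b, by = c("neuron_a", "neuron_b"),
                    suffix = c("_n", "_n1"))
    j <- j[is.finite(j$coactivity_n) & is.finite(j$coactivity_n1), ]
    rho <- rho_sh <- NA_real_
    if (nrow(j) < min_pairs) {
      warn(paste0("fewer than ", min_pairs, " common pairs for days ",
                  d, "/", d + 1))
    } else if (sd(j$coactivity_n) == 0 || sd(j$coactivity_n1) == 0) {
      warn("zero variance in co-activity values; stability undefined")
    } else {
      rho <- cor(j$coactivity_n, j$coactivity_n1)
      if (has_null) {
        jn <- j[is.finite(j$null_coactivity_n) &
                  is.finite(j$null_coactivity_n1), ]
        if (nrow(jn) >= min_pairs && sd(jn$null_coactivity_n) > 0 &&
            sd(jn$null_coactivity_n1) > 0)
          rho_sh <- cor(jn$null_coactivity_n, jn$null_coactivity_n1)
      }
    }
    out <- tibble(day_n = d, day_n1 = d + 1, n_pairs = nrow(j), rho = rho)
    if (has_null) out$rho_shuffled <- rho_sh
    out
  })
  dplyr::bind_rows(rows)
}

#' Stability of co-activity as a function of the window length
#'
#' Recomputes pairwise co-activity per day for each window of the anchoring
#' family (one frame; up to 2 s starting 0.5 s before the peak; from 3 s on
#' starting 1 s before) and reports the across-day stability correlation,
#' pooled over all consecutive-day transitions.
#'
#' @param events Events tibble with `day`, `neuron_id`, `trial`,
#'   `peak_time`.
#' @param windows Window lengths (s).
#' @param frame_rate Imaging frame rate (Hz).
#' @param min_pairs Minimal common pairs per transition.
#' @return Tibble with `window`, `rho`, `n_pairs`.
#' @export
window_sweep <- function(events, windows = c(0.1, 0.5, 1, 2, 3, 4.5),
                         frame_rate = 10, min_pairs = 3L) {
  rows <- lapply(windows, function(w) {
    pt <- coactivity_pairs(events, window = w, frame_rate = frame_rate)
    days <- sort(unique(pt$day))
    pooled_x <- numeric(0); pooled_y <- numeric(0)
    for (d in days[-length(days)]) {
      a <- pt[pt$day == d, ]; b <- pt[pt$day == d + 1, ]
      if (nrow(b) == 0L) next
      j <- inner_join(a, b, by = c("neuron_a", "neuron_b"),
                      suffix = c("_n", "_n1"))
      j <- j[is.finite(j$coactivity_n) & is.finite(j$coactivity_n1), ]
      pooled_x <- c(pooled_x, j$coactivity_n)
      pooled_y <- c(pooled_y, j$coactivity_n1)
    }
    rho <- if (length(pooled_x) >= min_pairs && sd(pooled_x) > 0 &&
               sd(pooled_y) > 0) cor(pooled_x, pooled_y) else NA_real_
    tibble(window = w, rho = rho, n_pairs = length(pooled_x))
  })
  dplyr::bind_rows(rows)
}

#' Pairwise centroid distances
#'
#' @param centroids Tibble with `neuron_id`, `x_um`, `y_um`.
#' @param neighbor_dist Distance (um) at or below which a pair counts as
#'   neighboring.
#' @return Tibble with `neuron_a`, `neuron_b`, `distance`, `neighbor`.
#' @export
pair_distances <- function(centroids, neighbor_dist = 10) {
  ids <- sort(centroids$neuron_id)
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    ca <- centroids[centroids$neuron_id == ids[i], ]
    cb <- centroids[centroids$neuron_id == ids[j], ]
    d <- sqrt((ca$x_um - cb$x_um)^2 + (ca$y_um - cb$y_um)^2)
    rows[[length(rows) + 1L]] <- tibble(neuron_a = ids[i],
                                        neuron_b = ids[j], distance = d)
  }
  mutate(dplyr::bind_rows(rows), neighbor = distance <= neighbor_dist)
}

#' Pairwise Pearson correlation of dF/F traces
#'
#' @param dff Tibble with `time`, `dff`, `neuron_id` (optional `day`;
#'   correlations are computed per day and averaged).
#' @return Tibble with `neuron_a`, `neuron_b`, `trace_cor`.
#' @export
trace_correlations <- function(dff) {
  stopifnot("neuron_id" %in% names(dff))
  days <- if ("day" %in% names(dff)) sort(unique(dff$day)) else NA
  ids <- sort(unique(dff$neuron_id))
  acc <- list()
  for (d in days) {
    sub <- if (is.na(d[1])) dff else dff[dff$day == d, ]
    wide <- vapply(ids, function(i) sub$dff[sub$neuron_id == i],
                   numeric(sum(sub$neuron_id == ids[1])))
    cm <- cor(wide)
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids))
      acc[[length(acc) + 1L]] <- tibble(neuron_a = ids[i],
                                        neuron_b = ids[j],
                                        trace_cor = cm[i, j])
  }
  dplyr::bind_rows(acc) |>
    group_by(neuron_a, neuron_b) |>
    summarise(trace_cor = mean(trace_cor), .groups = "drop")
}

#' Distance dependence of co-activity and its stability
#'
#' Joins pair statistics with centroid distances, and repeats the
#' across-day stability analysis after excluding neighboring pairs
#' (distance at or below `neighbor_dist`), the control against optical
#' signal contamination between adjacent somata.
#'
#' @param pair_tbl Tibble from [coactivity_pairs()] with `day`.
#' @param centroids Tibble with `neuron_id`, `x_um`, `y_um` (all neurons in
#'   `pair_tbl` must appear).
#' @param dff Optional dF/F tibble for per-pair trace correlations.
#' @param neighbor_dist Neighbor threshold (um).
#' @return List (class `ca_distance`) with `pairs` (per-pair table with
#'   `distance`, `neighbor`, co-activity and optional `trace_cor`),
#'   `stability_all`, `stability_excluded` (tibbles from
#'   [across_day_stability()]).
#' @export
distance_dependence <- function(pair_tbl, centroids, dff = NULL,
                                neighbor_dist = 10) {
  ids <- unique(c(pair_tbl$neuron_a, pair_tbl$neuron_b))
  if (!all(ids %in% centroids$neuron_id))
    abort("missing centroid for at least one neuron in the pair table")
  dist <- pair_distances(centroids, neighbor_dist)
  joined <- left_join(pair_tbl, dist, by = c("neuron_a", "neuron_b"))
  if (!is.null(dff))
    joined <- left_join(joined, trace_correlations(dff),
                        by = c("neuron_a", "neuron_b"))
  far <- joined[!joined$neighbor, ]
  structure(list(
    pairs = joined,
    stability_all = across_day_stability(pair_tbl),
    stability_excluded = across_day_stability(far[, names(pair_tbl)])
  ), class = "ca_distance")
}

#' Per-neuron-day event statistics
#'
#' Mean transient amplitude, mean FWHM, mean interevent interval, event
#' count and a large-event flag for every tracked neuron-day (and
#' condition, when present).
#'
#' @param events Events tibble with `neuron_id`, `day`, `peak_dff`,
#'   `fwhm`, `iei` (optional `size_class`, `condition`).
#' @return Tibble with one row per neuron-day (x condition).
#' @export
day_stats <- function(events) {
  keys <- intersect(c("neuron_id", "day", "condition"), names(events))
  stopifnot(all(c("neuron_id", "day") %in% keys))
  events |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_events = n(),
      mean_peak_dff = mean(peak_dff, na.rm = TRUE),
      mean_fwhm = mean(fwhm, na.rm = TRUE),
      mean_iei = mean(iei, na.rm = TRUE),
      has_large = if ("size_class" %in% names(events))
        any(size_class == "awake_large") else NA,
      .groups = "drop")
}

#' Across-day correlations of per-neuron event statistics
#'
#' Pearson correlation of per-neuron mean amplitude, FWHM and IEI between
#' consecutive days, over neurons present on both days.
#'
#' @param stats Tibble from [day_stats()].
#' @param min_neurons Minimal paired neurons (fewer gives `NA`, flagged by
#'   a warning).
#' @return Tibble with `day_n`, `day_n1`, `condition` (if present),
#'   `statistic`, `rho`, `n_neurons`.
#' @export
day_stat_correlations <- function(stats, min_neurons = 3L) {
  conds <- if ("condition" %in% names(stats)) unique(stats$condition)
  else NA
  rows <- list()
  for (cond in conds) {
    sub <- if (is.na(cond[1])) stats else stats[stats$condition == cond, ]
    days <- sort(unique(sub$day))
    for (d in days[-length(days)]) {
      a <- sub[sub$day == d, ]; b <- sub[sub$day == d + 1, ]
      if (nrow(b) == 0L) next
      j <- inner_join(a, b, by = "neuron_id", suffix = c("_n", "_n1"))
      for (st in c("mean_peak_dff", "mean_fwhm", "mean_iei")) {
        x <- j[[paste0(st, "_n")]]; y <- j[[paste0(st, "_n1")]]
        ok <- is.finite(x) & is.finite(y)
        rho <- if (sum(ok) >= min_neurons && sd(x[ok]) > 0 &&
                   sd(y[ok]) > 0) cor(x[ok], y[ok]) else {
                     warn(paste0("stability of ", st, " undefined for days ",
                                 d, "/", d + 1))
                     NA_real_
                   }
        row <- tibble(day_n = d, day_n1 = d + 1, statistic = st,
                      rho = rho, n_neurons = sum(ok))
        if (!is.na(cond[1])) row <- mutate(row, condition = cond,
                                           .before = 1)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Monte Carlo null for multi-day large-event incidence
#'
#' Observed statistic: among neurons with a large event on at least one
#' day, the fraction that have large events on at least two days (and on
#' all days). Null: per simulation and per day, the day's large-event
#' count is reassigned to a uniformly random subset of all tracked
#' neurons, independently across days; the chance level is the null mean
#' and the p-value the fraction of simulations at or above the observed
#' value.
#'
#' @param flags Tibble with `neuron_id`, `day`, `has_large` (one row per
#'   tracked neuron-day).
#' @param n_sims Number of Monte Carlo simulations.
#' @param seed RNG seed.
#' @return Object of class `ca_incidence`: list with `observed` (tibble
#'   `statistic`, `value`), `chance` (null means), `p_value`, `n_sims`,
#'   `per_day` counts.
#' @export
large_event_incidence_null <- function(flags, n_sims = 1e5, seed = 1L) {
  stopifnot(all(c("neuron_id", "day", "has_large") %in% names(flags)))
  days <- sort(unique(flags$day))
  if (length(days) < 2L) abort("need at least 2 days")
  ids <- sort(unique(flags$neuron_id))
  n <- length(ids)
  n_days <- length(days)
  # per-day large counts among tracked neurons
  k <- vapply(days, function(d)
    sum(flags$has_large[flags$day == d], na.rm = TRUE), numeric(1))
  if (any(k == 0))
    warn("day(s) with zero large-event neurons contribute no reassignments")
  per_neuron <- vapply(ids, function(i)
    sum(flags$has_large[flags$neuron_id == i], na.rm = TRUE), numeric(1))
  obs_ge1 <- sum(per_neuron >= 1)
  obs <- tibble(
    statistic = c("ge2_days", "all_days"),
    value = c(if (obs_ge1 > 0) sum(per_neuron >= 2) / obs_ge1 else NA_real_,
              if (obs_ge1 > 0) sum(per_neuron == n_days) / obs_ge1
              else NA_real_))

  sims <- with_seed(seed, {
    res <- matrix(NA_real_, n_sims, 2)
    for (s in seq_len(n_sims)) {
      cnt <- integer(n)
      for (d in seq_len(n_days)) {
        if (k[d] == 0) next
        pick <- sample.int(n, k[d])
        cnt[pick] <- cnt[pick] + 1L
      }
      ge1 <- sum(cnt >= 1)
      if (ge1 > 0) {
        res[s, 1] <- sum(cnt >= 2) / ge1
        res[s, 2] <- sum(cnt == n_days) / ge1
      }
    }
    res
  })
  chance <- colMeans(sims, na.rm = TRUE)
  p <- vapply(1:2, function(i)
    mean(sims[, i] >= obs$value[i], na.rm = TRUE), numeric(1))
  structure(list(observed = obs,
                 chance = setNames(chance, obs$statistic),
                 p_value = setNames(p, obs$statistic),
                 n_sims = n_sims,
                 per_day = tibble(day = days, n_large = k, n_tracked = n)),
            class = "ca_incidence")
}

#' Null-corrected ratio between two conditions
#'
#' Subtracts the shuffle-null means and forms the ratio
#' `r = (a - null_a) / (b - null_b)` with its SEM by Gaussian error
#' propagation:
#' `sem_r = |r| * sqrt((sem_a/(a-null_a))^2 + (sem_b/(b-null_b))^2)`.
#'
#' @param mean_a,sem_a Numerator mean and SEM.
#' @param mean_b,sem_b Denominator mean and SEM.
#' @param null_a,null_b Null offsets subtracted before the ratio.
#' @return Tibble with `ratio` and `sem`.
#' @export
condition_ratio <- function(mean_a, sem_a, mean_b, sem_b,
                            null_a = 0, null_b = 0) {
  da <- mean_a - null_a
  db <- mean_b - null_b
  if (db == 0) abort("denominator is zero after null subtraction")
  r <- da / db
  tibble(ratio = r,
         sem = abs(r) * sqrt((sem_a / da)^2 + (sem_b / db)^2))
}
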