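# session serialization (CSV + YAML manifest) and the staged pipeline

SCHEMA_VERSION <- "1.0"

provenance_line <- function(hash, seed) {
  paste0("# calico manifest_hash=", hash, " seed=", seed)
}

write_table <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(provenance_line(hash, seed), con)
  close(con)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

read_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

spec_as_list <- function(spec) {
  out <- unclass(spec)
  out$coactivity_groups <- lapply(out$coactivity_groups, function(g)
    lapply(g, function(v) if (is.numeric(v)) as.numeric(v) else v))
  out
}

#' Write a session to disk
#'
#' Serializes a `ca_session` as a YAML manifest plus plain CSV tables
#' (traces, spikes, centroids, speed, background). Times are in seconds and
#' dF/F values are fractions; every table carries the manifest hash and
#' seed in a comment header line for provenance.
#'
#' @param session A `ca_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ca_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec_list <- spec_as_list(session$spec)
  hash <- rlang::hash(spec_list)
  files <- list(traces = "traces.csv", spikes = "spikes.csv",
                centroids = "centroids.csv", speed = "speed.csv",
                background = "background.csv")
  manifest <- list(schema_version = SCHEMA_VERSION,
                   generator = "calico",
                   seed = session$spec$seed,
                   manifest_hash = hash,
                   units = list(time = "s", dff = "fraction",
                                speed = "cm_s", distance = "um"),
                   spec = spec_list,
                   large_event_neurons =
                     as.integer(session$large_event_neurons),
                   amplitude_scale = as.numeric(session$amplitude_scale),
                   files = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  write_table(session$traces, file.path(dir, files$traces), hash,
              session$spec$seed)
  write_table(session$spikes, file.path(dir, files$spikes), hash,
              session$spec$seed)
  write_table(session$centroids, file.path(dir, files$centroids), hash,
              session$spec$seed)
  write_table(session$behavior, file.path(dir, files$speed), hash,
              session$spec$seed)
  write_table(session$background, file.path(dir, files$background), hash,
              session$spec$seed)
  invisible(file.path(dir, "manifest.yaml"))
}

known_manifest_keys <- c("schema_version", "generator", "seed",
                         "manifest_hash", "units", "spec",
                         "large_event_neurons", "amplitude_scale", "files")

#' Load a session from disk
#'
#' Reads a manifest written by [write_session()] and reassembles the
#' `ca_session`. Missing referenced files raise an error naming the file;
#' unknown manifest keys produce a warning and are ignored.
#'
#' @param path Path to the manifest file or its directory.
#' @return A `ca_session`.
#' @export
load_session <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.yaml")
  else path
  if (!file.exists(manifest_path))
    abort(paste0("manifest not found: ", manifest_path))
  m <- yaml::read_yaml(manifest_path)
  extra <- setdiff(names(m), known_manifest_keys)
  if (length(extra))
    warn(paste0("ignoring unknown manifest keys: ",
                paste(extra, collapse = ", ")))
  if (is.null(m$spec)) abort("manifest field missing: spec")
  dir <- dirname(manifest_path)
  for (f in unlist(m$files)) {
    if (!file.exists(file.path(dir, f)))
      abort(paste0("referenced file missing: ", file.path(dir, f)))
  }
  sp <- m$spec
  groups <- lapply(sp$coactivity_groups %||% list(), function(g) {
    g$neurons <- as.integer(g$neurons); g
  })
  spec <- session_spec(
    n_neurons = sp$n_neurons, n_days = sp$n_days, n_trials = sp$n_trials,
    trial_length = sp$trial_length, inter_trial_gap = sp$inter_trial_gap,
    frame_rate = sp$frame_rate, condition = sp$condition,
    coactivity_groups = groups,
    large_event_fraction = sp$large_event_fraction,
    amplitude_scale_sd = sp$amplitude_scale_sd, fov_um = sp$fov_um,
    centroid_min_dist = sp$centroid_min_dist, seed = sp$seed)
  structure(list(
    spec = spec,
    traces = read_table(file.path(dir, m$files$traces)),
    spikes = read_table(file.path(dir, m$files$spikes)),
    behavior = read_table(file.path(dir, m$files$speed)),
    background = read_table(file.path(dir, m$files$background)),
    centroids = read_table(file.path(dir, m$files$centroids)),
    large_event_neurons = as.integer(m$large_event_neurons),
    amplitude_scale = as.numeric(m$amplitude_scale)
  ), class = "ca_session")
}

#' Run the session analysis pipeline
#'
#' Chains the analysis stages on a `ca_session`:
#' `preprocess` (background subtraction, sliding-percentile dF/F,
#' Savitzky-Golay smoothing), `detect` (transient detection and per-event
#' statistics), `behavior` (speed downsampling, state segmentation,
#' state-resolved rates) and `population` (pairwise co-activity, shuffle
#' null, across-day stability, per-neuron-day statistics). Later stages
#' require the earlier ones; requesting a stage without its prerequisite is
#' an error. With `out_dir` set, tidy CSV tables and a JSON summary are
#' written, each embedding the session seed and manifest hash.
#'
#' @param session A `ca_session`.
#' @param stages Character vector, subset of
#'   `c("preprocess", "detect", "behavior", "population")`.
#' @param out_dir Optional output directory.
#' @param n_shuffles Shuffle count for the co-activity null.
#' @param seed Seed for the shuffle null.
#' @return List with elements `dff`, `events`, `states`, `rates`, `pairs`,
#'   `stability`, `day_stats` (those produced by the requested stages).
#' @export
run_pipeline <- function(session,
                         stages = c("preprocess", "detect", "behavior",
                                    "population"),
                         out_dir = NULL, n_shuffles = 20L, seed = 1L) {
  stopifnot(inherits(session, "ca_session"))
  allowed <- c("preprocess", "detect", "behavior", "population")
  if (!all(stages %in% allowed))
    abort(paste0("unknown stage(s): ",
                 paste(setdiff(stages, allowed), collapse = ", ")))
  needs <- list(detect = "preprocess", behavior = "detect",
                population = "detect")
  for (sname in stages) {
    pre <- needs[[sname]]
    if (!is.null(pre) && !pre %in% stages)
      abort(paste0("stage '", sname, "' requires stage '", pre, "'"))
  }
  out <- list()
  spec <- session$spec
  cond <- if (spec$condition == "anesthetized") "anesthetized" else "awake"

  if ("preprocess" %in% stages) {
    dffs <- list()
    for (d in sort(unique(session$traces$day))) {
      bg <- estimate_background(
        session$background[session$background$day == d, ])
      day_tr <- session$traces[session$traces$day == d, ]
      for (j in sort(unique(day_tr$neuron_id))) {
        tr <- day_tr[day_tr$neuron_id == j, ]
        dff <- smooth_dff(compute_dff(tr, bg,
                                      sampling_rate = spec$frame_rate))
        dffs[[length(dffs) + 1L]] <- mutate(dff, day = d, neuron_id = j)
      }
    }
    out$dff <- dplyr::bind_rows(dffs)
  }

  if ("detect" %in% stages) {
    ev <- detect_events(out$dff, condition = cond)
    out$events <- event_stats(out$dff, ev)
  }

  if ("behavior" %in% stages) {
    states <- list(); rates <- list()
    for (d in sort(unique(session$behavior$day))) {
      ft <- sort(unique(out$dff$time[out$dff$day == d]))
      sp10 <- downsample_speed(session$behavior[session$behavior$day == d, ],
                               ft, spec$frame_rate)
      st <- segment_states(sp10)
      states[[length(states) + 1L]] <- mutate(st, day = d)
      evd <- out$events[out$events$day == d, ]
      if (nrow(evd) > 0)
        rates[[length(rates) + 1L]] <-
          mutate(event_rates_by_state(evd, st, spec$frame_rate), day = d)
    }
    out$states <- dplyr::bind_rows(states)
    out$rates <- dplyr::bind_rows(rates)
  }

  if ("population" %in% stages) {
    trials <- trials_table(spec)
    pairs <- shuffle_null(out$events, trials, n_shuffles = n_shuffles,
                          seed = seed, statistic = "pairwise",
                          frame_rate = spec$frame_rate)
    out$pairs <- pairs
    if (spec$n_days >= 2) out$stability <- across_day_stability(pairs)
    out$day_stats <- day_stats(out$events)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    hash <- rlang::hash(spec_as_list(spec))
    for (nm in intersect(c("dff", "events", "states", "rates", "pairs",
                           "stability", "day_stats"), names(out))) {
      if (is.data.frame(out[[nm]]) && nrow(out[[nm]]) > 0)
        write_table(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                    hash, spec$seed)
    }
    summary <- list(
      manifest_hash = hash, seed = spec$seed, stages = stages,
      n_neurons = spec$n_neurons, n_days = spec$n_days,
      n_events = if (!is.null(out$events)) nrow(out$events) else NULL,
      mean_coactivity = if (!is.null(out$pairs))
        mean(out$pairs$coactivity, na.rm = TRUE) else NULL,
      mean_null_coactivity = if (!is.null(out$pairs))
        mean(out$pairs$null_coactivity, na.rm = TRUE) else NULL,
      stability_rho = if (!is.null(out$stability))
        mean(out$stability$rho, na.rm = TRUE) else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
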