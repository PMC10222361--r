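#' Pipeline configuration with method defaults
#'
#' Returns the full nested configuration for the detection pipeline. The
#' method-defining defaults are: 7th-order 3 Hz Butterworth high-pass, EEMD
#' noise ratio 0.1 with ensemble size 50, energy-ratio gate delta = 0.6,
#' spike coefficient a = 0.03 (midpoint of the 0.01..0.05 range), and 6 s
#' event merging. Overrides are given as nested lists; unknown keys are
#' rejected.
#'
#' @param ... nested overrides, e.g. \code{spike = list(a = 0.02)}.
#' @return Nested list of class \code{fm_config}.
#' @export
fm_config <- function(...) {
  defaults <- list(
    schema_version = 1L,
    video = list(fps = NULL, min_segment_s = 3),
    skin_model = list(cx = 109.38, cy = 152.02, a = 25.39, b = 14.03,
                      theta = 2.53),
    opening = list(radius_px = NULL),
    abdomen = list(lock_region = FALSE),
    flow = list(levels = 3L, iters = 5L, win_radius = 7L, m_norm = 5),
    filter = list(order = 7L, cutoff_hz = 3, zero_phase = TRUE),
    eemd = list(noise_ratio = 0.1, n_ensemble = 50L, seed = 42L,
                max_sift = 10L),
    selection = list(delta = 0.6),
    spike = list(a = 0.03, compare_on = "signal"),
    events = list(gap_s = 6, interval_mode = "end_to_start"),
    evaluation = list(pad_s = 0),
    report_channel = "S")
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  cfg <- merge_config(defaults, overrides, path = "config")
  class(cfg) <- c("fm_config", "list")
  cfg
}

merge_config <- function(base, override, path) {
  if (length(override) == 0) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == ""))
    stop("config overrides must be named (at ", path, ")")
  unknown <- setdiff(nms, names(base))
  if (length(unknown))
    stop("unknown config key(s) at ", path, ": ",
         paste(unknown, collapse = ", "))
  for (k in nms) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]]))
        stop("config key ", path, "$", k, " must be a list")
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, "$", k))
    } else {
      base[k] <- override[k]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the [fm_config()] defaults; unknown keys are
#' rejected with the offending key named.
#'
#' @param path YAML file.
#' @return An \code{fm_config}.
#' @export
read_config <- function(path) {
  fm_config(yaml::read_yaml(path))
}

#' Run the full detection pipeline
#'
#' Executes abdomen detection, optical-flow HS series extraction, high-pass
#' filtering, EEMD and IMF selection, spike detection and event merging for
#' both channels of every contiguous segment, and computes the clinical
#' movement parameters. When annotations are supplied the event-level metrics
#' are computed for the reporting channel (S by default).
#'
#' @param video a [frame_sequence()], a PNG-stack directory path, or a
#'   pre-extracted list of \code{hs_series} (signal-only path).
#' @param exclusions frame-exclusion vector or JSON path (video path input
#'   only).
#' @param config an [fm_config()].
#' @param annotations optional gold-standard intervals (data.frame or file
#'   for [read_annotations()]).
#' @param out_dir optional output directory; events, parameters, resolved
#'   config and the report are written there as JSON/CSV.
#' @return List of class \code{run_report}: per-channel events and
#'   \code{fm_parameters}, selection diagnostics, analyzed time, metrics (or
#'   NULL), and the resolved config.
#' @export
run_detect <- function(video, exclusions = NULL, config = fm_config(),
                       annotations = NULL, out_dir = NULL) {
  if (is.character(video) && length(video) == 1) {
    video <- load_video(video, exclusions = exclusions,
                        fps = config$video$fps)
  }
  if (inherits(video, "frame_sequence")) {
    masks <- detect_abdomen(video, model = do.call(skin_model,
                                                   config$skin_model),
                            radius_px = config$opening$radius_px,
                            lock = config$abdomen$lock_region)
    series <- build_series(video, masks, m_norm = config$flow$m_norm,
                           min_len_s = config$video$min_segment_s,
                           flow_params = config$flow[c("levels", "iters",
                                                       "win_radius")])
  } else if (is.list(video) && all(vapply(video, inherits, TRUE,
                                          "hs_series"))) {
    series <- video
  } else if (inherits(video, "hs_series")) {
    series <- list(video)
  } else stop("video must be a path, frame_sequence, or hs_series input")
  if (length(series) == 0) stop("no analyzable segments")
  fs <- series[[1]]$fs
  analyzed_s <- sum(vapply(series, function(s) length(s$S) / s$fs, 0))

  channels <- list()
  for (ch in c("H", "S")) {
    spike_times <- numeric()
    diags <- list()
    for (s in series) {
      # both channels are processed on a common [0,1] scale: saturation is
      # already unit-bounded, hue (degrees) is converted to turns -- the
      # difference-threshold rule is scale-sensitive (Th2 grows with the
      # square of the amplitude), so channel scales must be comparable
      x <- if (ch == "H") s[[ch]] / 360 else s[[ch]]
      min_len <- max(64, 3 * config$filter$order + 1)
      if (length(x) < min_len) next
      sig <- extract_fm_signal(x, fs, config)
      if (is.null(sig)) next  # motionless segment: nothing to detect
      tr <- detect_spikes(sig, a = config$spike$a,
                          compare_on = config$spike$compare_on)
      spike_times <- c(spike_times,
                       s$t[1] + (tr$spike_indices - 1) / fs)
      diags[[length(diags) + 1L]] <-
        cbind(segment_id = s$segment_id, channel = ch, sig$diagnostics,
              selected = sig$diagnostics$imf == sig$selected_index,
              fallback = sig$fallback_flag)
    }
    events <- merge_spikes(sort(spike_times), gap_s = config$events$gap_s,
                           fs = fs)
    channels[[ch]] <- list(
      events = events,
      parameters = fm_parameters(events, analyzed_s,
                                 interval_mode = config$events$interval_mode),
      diagnostics = if (length(diags)) do.call(rbind, diags) else NULL)
  }

  metrics <- NULL
  if (!is.null(annotations)) {
    if (is.character(annotations))
      annotations <- read_annotations(annotations, fps = fs)
    metrics <- detection_metrics(
      match_events(channels[[config$report_channel]]$events, annotations,
                   pad_s = config$evaluation$pad_s))
  }
  report <- structure(list(channels = channels, metrics = metrics,
                           analyzed_time_s = analyzed_s, fs = fs,
                           config = config,
                           version = as.character(utils::packageVersion("videofm"))),
                      class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %.1f s analyzed @ %g Hz\n", x$analyzed_time_s,
              x$fs))
  for (ch in names(x$channels)) {
    p <- x$channels[[ch]]$parameters
    cat(sprintf("  %s: %d events (%.2f /h, %.2f%% of time)\n", ch,
                p$n_events, p$number_per_hour, p$percentage))
  }
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits per-channel events and parameters, selection diagnostics, the
#' resolved configuration, and a combined report as JSON/CSV. Outputs are
#' deterministic for fixed inputs, config and seed.
#'
#' @param report a \code{run_report}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  for (ch in names(report$channels)) {
    chd <- report$channels[[ch]]
    wj(as.data.frame(chd$events), sprintf("events_%s.json", ch))
    p <- chd$parameters
    wj(p[c("number_per_hour", "intervals_s", "durations_s", "percentage",
           "analyzed_time_s", "n_events")],
       sprintf("parameters_%s.json", ch))
    if (!is.null(chd$diagnostics))
      write.csv(chd$diagnostics,
                file.path(out_dir, sprintf("diagnostics_%s.csv", ch)),
                row.names = FALSE)
  }
  wj(unclass_deep(report$config), "config_resolved.json")
  if (!is.null(report$metrics))
    wj(c(report$metrics[c("TDR", "PPV", "SEN", "ACC", "F1")],
         report$metrics$counts), "metrics.json")
  invisible(out_dir)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Evaluate detected events against annotations
#'
#' Single-recording input gives the event-level metrics; lists of recordings
#' additionally give pooled metrics and Bland-Altman agreement of the
#' per-recording event counts.
#'
#' @param events detected events (\code{fm_events}/data.frame, path to an
#'   events JSON, or a list of such for multiple recordings).
#' @param annotations gold-standard intervals (data.frame, path, or list).
#' @param config an [fm_config()] (for the matching pad).
#' @return For one recording a \code{metrics_report}; for several, a list
#'   with \code{per_recording}, pooled \code{metrics} and
#'   \code{bland_altman_n_events}.
#' @export
run_eval <- function(events, annotations, config = fm_config()) {
  load_ev <- function(e) {
    if (is.character(e)) e <- jsonlite::fromJSON(e)
    as.data.frame(e)
  }
  load_an <- function(a) if (is.character(a)) read_annotations(a) else a
  multi <- is.list(events) && !is.data.frame(events)
  if (!multi) {
    counts <- match_events(load_ev(events), load_an(annotations),
                           pad_s = config$evaluation$pad_s)
    return(detection_metrics(counts))
  }
  if (length(events) != length(annotations))
    stop("events and annotations lists differ in length")
  per <- Map(function(e, a) {
    match_events(load_ev(e), load_an(a), pad_s = config$evaluation$pad_s)
  }, events, annotations)
  pooled <- list(TP = sum(vapply(per, `[[`, 0, "TP")),
                 FP = sum(vapply(per, `[[`, 0, "FP")),
                 FN = sum(vapply(per, `[[`, 0, "FN")),
                 TME = sum(vapply(per, `[[`, 0, "TME")))
  n_pred <- vapply(events, function(e) nrow(load_ev(e)), 0)
  n_lab <- vapply(annotations, function(a) nrow(load_an(a)), 0)
  list(per_recording = lapply(per, detection_metrics),
       metrics = detection_metrics(pooled),
       bland_altman_n_events = if (length(n_pred) >= 2)
         bland_altman(n_pred, n_lab) else NULL)
}
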