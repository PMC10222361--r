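#' Merge spikes into fetal-movement events
#'
#' Greedy left-to-right grouping: a spike joins the current event iff its
#' time minus the previous spike's time is strictly less than \code{gap_s};
#' otherwise it starts a new event. Event boundaries run from the first to
#' the last constituent spike; a single-spike event occupies one sample
#' period.
#'
#' @param spikes a \code{spike_train} (see [detect_spikes()]), or a numeric
#'   vector of spike times in seconds (then \code{fs} must be given).
#' @param gap_s merging gap (seconds); spikes closer than this belong to one
#'   movement.
#' @param fs sampling rate, required for a plain numeric input.
#' @param t0 time offset (seconds) added to spike times, used to place
#'   segment-local indices in original video time.
#' @return data.frame of class \code{fm_events} with columns \code{start_s},
#'   \code{end_s}, \code{n_spikes}, \code{duration_s}.
#' @export
merge_spikes <- function(spikes, gap_s = 6, fs = NULL, t0 = 0) {
  if (inherits(spikes, "spike_train")) {
    fs <- spikes$fs
    times <- (spikes$spike_indices - 1) / fs + t0
  } else {
    if (is.null(fs)) stop("fs required for plain spike-time input")
    times <- sort(as.numeric(spikes)) + t0
  }
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_spikes = integer(), duration_s = numeric())
  class(empty) <- c("fm_events", "data.frame")
  if (length(times) == 0) return(empty)
  new_event <- c(TRUE, diff(times) >= gap_s)
  grp <- cumsum(new_event)
  ev <- do.call(rbind, lapply(split(times, grp), function(tt)
    data.frame(start_s = tt[1], end_s = tt[length(tt)],
               n_spikes = length(tt))))
  ev$duration_s <- ifelse(ev$n_spikes == 1, 1 / fs, ev$end_s - ev$start_s)
  rownames(ev) <- NULL
  class(ev) <- c("fm_events", "data.frame")
  ev
}

#' Clinical fetal-movement parameters
#'
#' Summarizes merged events over the analyzed recording time: events per
#' hour, gaps between adjacent events, event durations, and total movement
#' time as a percentage of the analyzed time. The analyzed time is the total
#' duration of the contiguous segments actually processed, so manually
#' excluded frames never inflate the percentage denominator.
#'
#' @param events an \code{fm_events} data.frame (see [merge_spikes()]).
#' @param analyzed_time_s analyzed recording time (seconds, > 0).
#' @param interval_mode \code{"end_to_start"} (elapsed time from one event's
#'   end to the next event's start, default) or \code{"onset_to_onset"}.
#' @return List of class \code{fm_parameters}: \code{number_per_hour},
#'   \code{intervals_s}, \code{durations_s}, \code{percentage},
#'   \code{analyzed_time_s}, \code{n_events}.
#' @export
fm_parameters <- function(events, analyzed_time_s,
                          interval_mode = c("end_to_start", "onset_to_onset")) {
  interval_mode <- match.arg(interval_mode)
  stopifnot(analyzed_time_s > 0)
  n <- nrow(events)
  intervals <- if (n >= 2) {
    if (interval_mode == "end_to_start")
      events$start_s[-1] - events$end_s[-n]
    else diff(events$start_s)
  } else numeric()
  structure(list(
    number_per_hour = n * 3600 / analyzed_time_s,
    intervals_s = intervals,
    durations_s = events$duration_s,
    percentage = sum(events$duration_s) / analyzed_time_s * 100,
    analyzed_time_s = analyzed_time_s,
    n_events = n), class = "fm_parameters")
}

#' @export
print.fm_parameters <- function(x, ...) {
  cat(sprintf(paste0("<fm_parameters> %d events in %.1f s analyzed\n",
                     "  number: %.2f /h | mean interval: %s s | ",
                     "mean duration: %s s | percentage: %.2f%%\n"),
              x$n_events, x$analyzed_time_s, x$number_per_hour,
              if (length(x$intervals_s)) sprintf("%.2f", mean(x$intervals_s)) else "-",
              if (length(x$durations_s)) sprintf("%.2f", mean(x$durations_s)) else "-",
              x$percentage))
  invisible(x)
}
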