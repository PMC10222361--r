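#' First-order difference
#'
#' @param x numeric series, length >= 2.
#' @return \code{y1(n) = x(n+1) - x(n)}, length \code{length(x) - 1}.
#' @export
first_diff <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples for a first difference")
  diff(x)
}

#' Second-order difference
#'
#' @param x numeric series, length >= 3.
#' @return \code{y2(n) = x(n+2) - 2 x(n+1) + x(n)}, length
#'   \code{length(x) - 2}.
#' @export
second_diff <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples for a second difference")
  diff(x, differences = 2)
}

#' First spike threshold
#'
#' Mean of the strict interior local minima of the second-order difference.
#' When the input has no interior local minimum (monotone or too short) the
#' minimum value is used and the result is flagged degenerate.
#'
#' @param y2 second-order difference series.
#' @return Threshold Th1 with attribute \code{"degenerate"}.
#' @export
threshold_th1 <- function(y2) {
  idx <- local_extrema(y2, "min")
  if (length(idx) == 0) {
    out <- min(y2)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- mean(y2[idx])
  attr(out, "degenerate") <- FALSE
  out
}

#' Second spike threshold
#'
#' Forms the weighted combination \code{y3(n) = y1max*y1(n) + y2max*y2(n)}
#' over the common index range (y1 truncated to the length of y2), where
#' y1max, y2max are the maxima of the two difference series, and sets
#' \code{Th2 = a * max(y3)}.
#'
#' @param y1 first-order difference series.
#' @param y2 second-order difference series.
#' @param a threshold coefficient; the method is specified for 0.01..0.05
#'   (values outside only produce a warning).
#' @return List with \code{y3} and \code{Th2}.
#' @export
threshold_th2 <- function(y1, y2, a = 0.03) {
  if (a < 0.01 || a > 0.05)
    warning("coefficient a outside the stated 0.01..0.05 range")
  n <- length(y2)
  y1c <- y1[seq_len(n)]
  y3 <- max(y1) * y1c + max(y2) * y2
  list(y3 = y3, Th2 = a * max(y3))
}

#' Detect fetal-movement spikes
#'
#' Differential-threshold spike recognition: sample n is a spike iff
#' \code{x(n) > Th1} and \code{x(n) > Th2} (strict), where Th1 is the mean of
#' the local minima of the second difference and Th2 = a * max(y3). The
#' alternative reading that compares the combined difference signal y3
#' against Th2 is available via \code{compare_on = "y3"} (then a spike
#' requires \code{x(n) > Th1} and \code{y3(n) > Th2}).
#'
#' @param x fetal-movement signal (selected IMF) or an \code{fm_signal}.
#' @param a Th2 coefficient (0.01..0.05; default the midpoint 0.03).
#' @param fs sampling rate (Hz), taken from an \code{fm_signal} input.
#' @param compare_on \code{"signal"} (literal rule, default) or \code{"y3"}.
#' @return Object of class \code{spike_train}: \code{spike_indices} (1-based
#'   sample indices, both differences defined), \code{fs}, thresholds and
#'   settings.
#' @export
detect_spikes <- function(x, a = 0.03, fs = NULL,
                          compare_on = c("signal", "y3")) {
  compare_on <- match.arg(compare_on)
  if (inherits(x, "fm_signal")) {
    fs <- x$fs
    x <- x$x
  }
  if (is.null(fs)) stop("fs required when x is a plain numeric vector")
  if (length(x) < 3) stop("need at least 3 samples")
  y1 <- first_diff(x)
  y2 <- second_diff(x)
  th1 <- threshold_th1(y2)
  t2 <- threshold_th2(y1, y2, a)
  ncommon <- length(y2)
  xc <- x[seq_len(ncommon)]
  hit <- if (compare_on == "signal") {
    xc > as.numeric(th1) & xc > t2$Th2
  } else {
    xc > as.numeric(th1) & t2$y3 > t2$Th2
  }
  structure(list(spike_indices = which(hit), fs = fs,
                 Th1 = as.numeric(th1), Th2 = t2$Th2, a = a,
                 compare_on = compare_on, n = length(x),
                 th1_degenerate = isTRUE(attr(th1, "degenerate"))),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes / %d samples @ %g Hz (Th1=%.4g, Th2=%.4g, a=%.3g)\n",
              length(x$spike_indices), x$n, x$fs, x$Th1, x$Th2, x$a))
  invisible(x)
}
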