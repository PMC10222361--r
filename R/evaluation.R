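#' Read gold-standard annotations
#'
#' Accepts JSON (array of objects or arrays with start/end) or CSV with
#' columns \code{start_s}, \code{end_s} — or \code{start_frame},
#' \code{end_frame} plus an \code{fps} argument.
#'
#' @param path annotation file (.json or .csv).
#' @param fps frame rate for frame-based files.
#' @return data.frame with \code{start_s}, \code{end_s}, ordered; its row
#'   count is TME, the total number of manually labeled movements.
#' @export
read_annotations <- function(path, fps = 25) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    x <- jsonlite::fromJSON(path)
    if (is.matrix(x)) data.frame(start_s = x[, 1], end_s = x[, 2]) else as.data.frame(x)
  } else utils::read.csv(path)
  if (all(c("start_frame", "end_frame") %in% names(df)))
    df <- data.frame(start_s = df$start_frame / fps, end_s = df$end_frame / fps)
  if (!all(c("start_s", "end_s") %in% names(df)))
    stop("annotations need start_s/end_s (or start_frame/end_frame) fields")
  df <- df[order(df$start_s), c("start_s", "end_s")]
  if (any(df$end_s < df$start_s)) stop("annotation with end before start")
  rownames(df) <- NULL
  df
}

#' Match detected events against labeled events
#'
#' A labeled movement counts as a true positive when at least one detected
#' event overlaps it (closed-interval overlap, optionally padded); a detected
#' event overlapping no label is a false positive; a label with no
#' overlapping detection is a false negative. One detected event may validate
#' several labels. TN is undefined at event level and reported as NA.
#'
#' @param pred detected events: \code{fm_events} or data.frame with
#'   \code{start_s}, \code{end_s}.
#' @param labels gold-standard intervals (data.frame \code{start_s},
#'   \code{end_s}); row count = TME.
#' @param pad_s symmetric tolerance pad (seconds) applied to labels before
#'   the overlap test.
#' @return List of class \code{match_counts}: \code{TP}, \code{FP},
#'   \code{FN}, \code{TN} (NA), \code{TME}.
#' @export
match_events <- function(pred, labels, pad_s = 0) {
  tme <- nrow(labels)
  overlaps <- function(a0, a1, b0, b1) a0 <= b1 & b0 <= a1
  lab_hit <- rep(FALSE, tme)
  pred_hit <- rep(FALSE, nrow(pred))
  if (nrow(pred) && tme) {
    for (i in seq_len(tme)) {
      o <- overlaps(pred$start_s, pred$end_s,
                    labels$start_s[i] - pad_s, labels$end_s[i] + pad_s)
      lab_hit[i] <- any(o)
      pred_hit <- pred_hit | o
    }
  }
  structure(list(TP = sum(lab_hit), FP = sum(!pred_hit),
                 FN = sum(!lab_hit), TN = NA_integer_, TME = tme),
            class = "match_counts")
}

#' Event-level detection metrics
#'
#' True detection rate, positive predictive value, sensitivity, accuracy and
#' F1 score, all as percentages. TDR = TP/TME; since every label is either
#' detected or missed (TP + FN = TME), TDR always equals SEN. Accuracy is
#' computed as TP/(TP+FP+FN): the event-level reading in which true negatives
#' do not exist (there is no countable set of correctly rejected non-events),
#' consistent with the harmonic relation ACC = 1/(1/ppv + 1/sen - 1).
#'
#' @param counts a \code{match_counts} (see [match_events()]), or a list with
#'   \code{TP}, \code{FP}, \code{FN} and \code{TME}.
#' @param TME override for the number of labeled movements.
#' @return List of class \code{metrics_report} with \code{TDR}, \code{PPV},
#'   \code{SEN}, \code{ACC}, \code{F1} (percent; \code{NA} where a
#'   denominator is zero) and the counts.
#' @export
detection_metrics <- function(counts, TME = NULL) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  tme <- TME %||% counts$TME
  div <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tdr <- div(tp, tme)
  ppv <- div(tp, tp + fp)
  sen <- div(tp, tp + fn)
  acc <- div(tp, tp + fp + fn)
  f1 <- if (!is.na(ppv) && !is.na(sen) && (ppv + sen) > 0)
    2 * ppv * sen / (ppv + sen) else NA_real_
  structure(list(TDR = tdr, PPV = ppv, SEN = sen, ACC = acc, F1 = f1,
                 counts = list(TP = tp, FP = fp, FN = fn, TME = tme)),
            class = "metrics_report")
}

#' F1 score from PPV and sensitivity
#'
#' Harmonic mean of positive predictive value and sensitivity, both in
#' percent.
#'
#' @param ppv,sen percentages.
#' @return F1 in percent.
#' @export
f1_score <- function(ppv, sen) 2 * ppv * sen / (ppv + sen)

#' Accuracy implied by PPV and sensitivity
#'
#' Under event-level counting, TP/(TP+FP+FN) depends on the counts only
#' through PPV and SEN: ACC = 1/(1/ppv + 1/sen - 1) with ppv, sen as
#' fractions. Useful for consistency checks on reported metric tables.
#'
#' @param ppv,sen percentages.
#' @return ACC in percent.
#' @export
acc_from_ppv_sen <- function(ppv, sen) {
  100 / (100 / ppv + 100 / sen - 1)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP=%d FP=%d FN=%d TME=%d\n",
              x$counts$TP, x$counts$FP, x$counts$FN, x$counts$TME))
  cat(sprintf("  TDR %.2f%% | PPV %.2f%% | SEN %.2f%% | ACC %.2f%% | F1 %.2f%%\n",
              x$TDR, x$PPV, x$SEN, x$ACC, x$F1))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Per-pair means and differences of a parameter measured two ways, the mean
#' difference (bias) and 95% limits of agreement at
#' \code{mean_diff +/- 1.96 * SD} (sample SD, n-1 denominator).
#'
#' @param p1,p2 paired measurements (equal length >= 2), e.g. a movement
#'   parameter from the detector and from manual labeling, one value per
#'   recording.
#' @return List of class \code{bland_altman}: \code{means}, \code{diffs},
#'   \code{mean_diff}, \code{sd_diff}, \code{loa_low}, \code{loa_high}.
#' @export
bland_altman <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("paired inputs differ in length")
  if (length(p1) < 2) stop("need at least 2 pairs")
  d <- p1 - p2
  md <- mean(d)
  sdd <- sd(d)
  structure(list(means = (p1 + p2) / 2, diffs = d, mean_diff = md,
                 sd_diff = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, 95%% limits [%.4g, %.4g] (n=%d)\n",
              x$mean_diff, x$loa_low, x$loa_high, length(x$diffs)))
  invisible(x)
}
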