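#' Dense optical flow between two frames
#'
#' Coarse-to-fine windowed least-squares flow (pyramidal Lucas-Kanade with
#' iterative bilinear warping). Fully deterministic: no random
#' initialization, fixed iteration counts.
#'
#' @param frame_k,frame_k1 RGB integer arrays of identical shape
#'   (consecutive frames of one segment).
#' @param levels pyramid levels.
#' @param iters warping iterations per level.
#' @param win_radius half-width of the least-squares window (pixels).
#' @return List with matrices \code{u} (columnwise/x displacement) and
#'   \code{v} (rowwise/y displacement, y pointing down), in pixels/frame.
#' @export
dense_flow <- function(frame_k, frame_k1, levels = 3, iters = 5,
                       win_radius = 7) {
  if (!identical(dim(frame_k), dim(frame_k1)))
    stop("frames differ in shape")
  g1 <- to_gray(frame_k)
  g2 <- to_gray(frame_k1)
  .cpp_dense_flow(g1, g2, levels = levels, iters = iters,
                  win_radius = win_radius)
}

to_gray <- function(frame) {
  (0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]) / 255
}

#' Encode a flow field as hue and saturation
#'
#' Motion direction maps to hue (degrees, counterclockwise from +x with image
#' y pointing down, so downward motion is 270 deg) and magnitude to
#' saturation, clipped at a fixed normalization scale. A stationary pixel has
#' saturation 0 (renders white at fixed lightness) and hue 0 by convention.
#' The normalization is a global constant rather than a per-frame maximum so
#' that saturation amplitude is comparable across time.
#'
#' @param flow list with displacement matrices \code{u}, \code{v}.
#' @param m_norm magnitude mapping to full saturation (pixels/frame).
#' @return List with matrices \code{h} (degrees in [0, 360)) and \code{s}
#'   (in [0, 1]).
#' @export
encode_hs <- function(flow, m_norm = 5) {
  stopifnot(m_norm > 0)
  mag <- sqrt(flow$u^2 + flow$v^2)
  s <- pmin(mag / m_norm, 1)
  h <- (atan2(-flow$v, flow$u) * 180 / pi) %% 360
  h[mag == 0] <- 0
  list(h = h, s = s)
}

#' Region-averaged channel value
#'
#' The per-frame motion sample is the arithmetic mean of the channel over the
#' N abdominal pixels.
#'
#' @param channel numeric matrix (hue or saturation image).
#' @param mask a [region_mask()] or logical matrix.
#' @return Scalar mean, or \code{NA} (with a warning) on an empty mask.
#' @export
region_average <- function(channel, mask) {
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  if (!any(m)) {
    warning("empty abdominal mask: sample dropped")
    return(NA_real_)
  }
  mean(channel[m])
}

#' Build H and S time series for each contiguous segment
#'
#' For every consecutive in-segment frame pair (k, k+1): dense flow, HS
#' encoding, then region averaging with the mask of frame k. Produces one H
#' and one S sample per pair at the video frame rate.
#'
#' @param seq a [frame_sequence()].
#' @param masks per-frame list of [region_mask()]s aligned with
#'   \code{seq$frames} (see [detect_abdomen()]).
#' @param m_norm saturation normalization (pixels/frame).
#' @param min_len_s minimum segment length (seconds).
#' @param max_missing maximum tolerated fraction of dropped samples per
#'   segment before the whole segment is rejected.
#' @param flow_params list of [dense_flow()] settings.
#' @return List of \code{hs_series} objects, one per retained segment; each
#'   has fields \code{H}, \code{S}, \code{fs}, \code{segment_id},
#'   \code{k_indices} (original frame number of the pair's first frame) and
#'   \code{t} (seconds in original video time).
#' @export
build_series <- function(seq, masks, m_norm = 5, min_len_s = 0,
                         max_missing = 0.1, flow_params = list()) {
  segs <- contiguous_segments(seq, min_len_s)
  out <- list()
  for (si in seq_len(nrow(segs))) {
    frames_in <- which(seq$frame_indices >= segs$start[si] &
                         seq$frame_indices < segs$end[si])
    if (length(frames_in) < 2) next
    npair <- length(frames_in) - 1L
    H <- S <- rep(NA_real_, npair)
    for (p in seq_len(npair)) {
      i <- frames_in[p]
      mask <- masks[[i]]
      empty <- isTRUE(attr(mask, "empty")) ||
        (inherits(mask, "region_mask") && mask$area_px == 0)
      if (empty) {
        warning(sprintf("frame %d: empty mask, pair dropped",
                        seq$frame_indices[i]))
        next
      }
      flow <- do.call(dense_flow,
                      c(list(seq$frames[[i]], seq$frames[[i + 1L]]),
                        flow_params))
      hs <- encode_hs(flow, m_norm)
      H[p] <- region_average(hs$h, mask)
      S[p] <- region_average(hs$s, mask)
    }
    miss <- mean(is.na(S))
    if (miss > max_missing) {
      warning(sprintf("segment %d rejected: %.0f%% samples missing",
                      si, 100 * miss))
      next
    }
    k_idx <- seq$frame_indices[frames_in[seq_len(npair)]]
    out[[length(out) + 1L]] <- structure(
      list(H = H, S = S, fs = seq$fps, segment_id = si,
           k_indices = k_idx, t = k_idx / seq$fps),
      class = "hs_series")
  }
  out
}

#' @export
print.hs_series <- function(x, ...) {
  cat(sprintf("<hs_series> segment %d: %d samples @ %g Hz (t = %.2f..%.2f s)\n",
              x$segment_id, length(x$S), x$fs, min(x$t), max(x$t)))
  invisible(x)
}

#' Export H/S series to CSV
#'
#' @param series list of \code{hs_series} (from [build_series()]).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_hs_csv <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(segment_id = s$segment_id, k = s$k_indices, t_seconds = s$t,
               H = s$H, S = s$S)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read H/S series from CSV
#'
#' Accepts the [write_hs_csv()] layout (columns \code{segment_id}, \code{k},
#' \code{t_seconds}, \code{H}, \code{S}), for users supplying motion series
#' from their own extraction.
#'
#' @param path CSV path.
#' @param fs sampling rate (Hz).
#' @return List of \code{hs_series}.
#' @export
read_hs_csv <- function(path, fs = 25) {
  df <- utils::read.csv(path)
  need <- c("segment_id", "k", "t_seconds", "H", "S")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  lapply(split(df, df$segment_id), function(d)
    structure(list(H = d$H, S = d$S, fs = fs, segment_id = d$segment_id[1],
                   k_indices = d$k, t = d$t_seconds),
              class = "hs_series"))
}
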