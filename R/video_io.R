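#' Construct a frame sequence
#'
#' A frame sequence is the in-memory representation of an abdominal video
#' after manual frame exclusion: an ordered list of RGB frames plus the
#' bookkeeping needed to map every retained frame back to original video time.
#'
#' @param frames list of RGB frames, each an integer array
#'   \code{height x width x 3} with values in 0..255.
#' @param fps frames per second (Hz), positive.
#' @param frame_indices original 0-based frame numbers of the retained frames,
#'   strictly increasing.
#' @param excluded integer vector of original frame numbers removed before
#'   analysis (e.g. maternal-movement frames).
#' @return An object of class \code{frame_sequence}.
#' @export
frame_sequence <- function(frames, fps,
                           frame_indices = seq_along(frames) - 1L,
                           excluded = integer()) {
  stopifnot(is.list(frames), length(frames) >= 1, fps > 0)
  dims <- vapply(frames, function(f) dim(f)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same height and width")
  frame_indices <- as.integer(frame_indices)
  if (length(frame_indices) != length(frames))
    stop("frame_indices must match frames in length")
  if (any(diff(frame_indices) <= 0))
    stop("frame_indices must be strictly increasing")
  if (any(frame_indices %in% excluded))
    stop("a retained frame index appears in the excluded set")
  structure(list(frames = frames, fps = fps,
                 frame_indices = frame_indices,
                 excluded = as.integer(excluded)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames (%dx%d) @ %g fps, %d excluded\n",
              length(x$frames), d[2], d[1], x$fps, length(x$excluded)))
  invisible(x)
}

#' Read a frame-exclusion list
#'
#' Exclusion files are JSON: either a flat array of 0-based frame numbers or
#' an array of two-element \code{[start, end)} pairs.
#'
#' @param path JSON file path.
#' @return Sorted integer vector of excluded frame numbers.
#' @export
read_exclusions <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.list(x)) x <- do.call(rbind, x)
  if (is.matrix(x)) {
    if (ncol(x) != 2) stop("exclusion pairs must have two columns [start, end)")
    x <- unlist(lapply(seq_len(nrow(x)),
                       function(i) seq.int(x[i, 1], x[i, 2] - 1L)))
  }
  sort(unique(as.integer(x)))
}

#' Load a video stored as a PNG image stack
#'
#' Videos are read from a directory of lossless PNG frames (one file per
#' frame, lexicographic order = temporal order) with an optional
#' \code{meta.json} carrying the frame rate. Frames listed in
#' \code{exclusions} are dropped before analysis; their original indices are
#' kept so that downstream timing refers to original video time.
#'
#' @param path directory containing \code{*.png} frames and optionally
#'   \code{meta.json} with an \code{fps} field.
#' @param exclusions integer vector of 0-based frame numbers to drop, or a
#'   path to a JSON exclusion file (see [read_exclusions()]).
#' @param fps frame rate override; when given it wins over \code{meta.json}
#'   (with a warning if the two disagree).
#' @return A [frame_sequence()].
#' @export
load_video <- function(path, exclusions = NULL, fps = NULL) {
  if (!dir.exists(path)) stop("cannot read video: no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no decodable frames found in ", path)
  meta_fps <- NA_real_
  meta_file <- file.path(path, "meta.json")
  if (file.exists(meta_file)) {
    meta <- jsonlite::fromJSON(meta_file)
    if (!is.null(meta$fps)) meta_fps <- as.numeric(meta$fps)
  }
  if (is.null(fps)) {
    fps <- if (is.na(meta_fps)) 25 else meta_fps
  } else if (!is.na(meta_fps) && fps != meta_fps) {
    warning(sprintf("fps override %g differs from container metadata %g; using %g",
                    fps, meta_fps, fps))
  }
  if (is.character(exclusions)) exclusions <- read_exclusions(exclusions)
  exclusions <- as.integer(exclusions %||% integer())
  n <- length(files)
  if (length(exclusions) && (min(exclusions) < 0 || max(exclusions) >= n))
    stop("exclusions outside [0, ", n, ")")
  keep <- setdiff(seq_len(n) - 1L, exclusions)
  frames <- lapply(files[keep + 1L], read_png_frame)
  frame_sequence(frames, fps, frame_indices = keep, excluded = exclusions)
}

#' Write a frame sequence as a PNG image stack
#'
#' @param seq a [frame_sequence()].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_video <- function(seq, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    f <- seq$frames[[i]] / 255
    png::writePNG(f, file.path(path, sprintf("frame_%06d.png",
                                             seq$frame_indices[i])))
  }
  jsonlite::write_json(list(fps = seq$fps, schema_version = 1L),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

read_png_frame <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  array(as.integer(round(img * 255)), dim(img))
}

#' Contiguous analyzable segments of a frame sequence
#'
#' Frame exclusion cuts the video into runs of consecutive frames. Signal
#' analysis runs per segment and never across an exclusion gap, which would
#' create artificial motion spikes at the seam.
#'
#' @param seq a [frame_sequence()].
#' @param min_len_s segments shorter than this (seconds) are dropped.
#' @return data.frame with columns \code{start}, \code{end} (original frame
#'   numbers, half-open \code{[start, end)}) and \code{duration_s}.
#' @export
contiguous_segments <- function(seq, min_len_s = 0) {
  idx <- seq$frame_indices
  breaks <- c(0L, which(diff(idx) > 1L), length(idx))
  out <- do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(k) {
    run <- idx[(breaks[k] + 1L):breaks[k + 1L]]
    data.frame(start = run[1], end = run[length(run)] + 1L)
  }))
  out$duration_s <- (out$end - out$start) / seq$fps
  out[out$duration_s >= min_len_s & out$duration_s > 0, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
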