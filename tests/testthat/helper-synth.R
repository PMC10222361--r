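# Shared fixture builders; everything is generated in code at test time.

# Smoothed random texture as an RGB frame (gradient-rich, flow-trackable).
textured_frame <- function(h = 100, w = 140, seed = 7) {
  set.seed(seed)
  m <- matrix(runif(h * w), h, w)
  smooth1 <- function(x) (x + rbind(x[-1, ], x[nrow(x), ]) +
                            rbind(x[1, ], x[-nrow(x), ]) +
                            cbind(x[, -1], x[, ncol(x)]) +
                            cbind(x[, 1], x[, -ncol(x)])) / 5
  m <- smooth1(smooth1(m))
  m <- (m - min(m)) / (max(m) - min(m))
  array(as.integer(round(m * 255)), c(h, w, 3))
}

shift_right <- function(frame, k) {
  out <- frame
  out[, (k + 1):dim(frame)[2], ] <- frame[, 1:(dim(frame)[2] - k), ]
  for (i in seq_len(k)) out[, i, ] <- frame[, 1, ]
  out
}

shift_down <- function(frame, k) {
  out <- frame
  out[(k + 1):dim(frame)[1], , ] <- frame[1:(dim(frame)[1] - k), , ]
  for (i in seq_len(k)) out[i, , ] <- frame[1, , ]
  out
}

# Uniform-color frame from an RGB triple.
flat_frame <- function(rgb, h = 20, w = 30) {
  array(rep(as.integer(rgb), each = h * w), c(h, w, 3))
}

# Tiny deterministic frame sequence (luma ramp pattern per frame).
tiny_sequence <- function(n = 10, h = 8, w = 12, fps = 25,
                          excluded = integer()) {
  keep <- setdiff(seq_len(n) - 1L, excluded)
  frames <- lapply(keep, function(k) {
    v <- (k * 7L + outer(seq_len(h), seq_len(w))) %% 256L
    array(rep(as.integer(v), 3), c(h, w, 3))
  })
  frame_sequence(frames, fps, frame_indices = keep, excluded = excluded)
}

interior <- function(m, b = 15) m[(b + 1):(nrow(m) - b), (b + 1):(ncol(m) - b)]

rms <- function(x) sqrt(mean(x^2))
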