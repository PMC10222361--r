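#' Butterworth high-pass preprocessing
#'
#' Removes low-frequency background (respiration ~0.2-0.5 Hz, slow drift)
#' before decomposition. Default is the 7th-order, 3 Hz design; applied
#' zero-phase (forward-backward) by default so spike timing is preserved,
#' which doubles the stopband attenuation.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz high-pass cutoff (Hz), below Nyquist.
#' @param order filter order.
#' @param zero_phase apply forward-backward (TRUE) or single pass.
#' @return Filtered series, same length.
#' @export
highpass <- function(x, fs, cutoff_hz = 3, order = 7, zero_phase = TRUE) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  min_len <- 3 * order + 1
  if (length(x) < min_len)
    stop(sprintf("series too short for order-%d filtering: need >= %d samples, got %d",
                 order, min_len, length(x)))
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  # odd-reflection padding suppresses start/end transients that would
  # otherwise masquerade as movement spikes at segment boundaries
  n <- length(x)
  pad <- min(n - 1, max(3 * (order + 1), round(10 * fs / cutoff_hz)))
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- if (zero_phase) as.numeric(signal::filtfilt(bf, xe))
       else as.numeric(signal::filter(bf, xe))
  y[(pad + 1):(pad + n)]
}

# Strict interior extrema of a series; returns indices.
local_extrema <- function(x, find = c("max", "min")) {
  find <- match.arg(find)
  d <- diff(x)
  if (find == "min") d <- -d
  which(d[-length(d)] > 0 & d[-1] < 0) + 1L
}

# Upper/lower envelope through extrema with mirrored boundary extrema,
# natural cubic spline interpolation.
envelope <- function(x, idx) {
  n <- length(x)
  # mirror up to two extrema across each boundary to tame end swings
  pre <- head(idx, 2); post <- tail(idx, 2)
  pos <- c(2 - rev(pre), idx, 2 * n - rev(post))
  val <- c(x[rev(pre)], x[idx], x[rev(post)])
  keep <- !duplicated(pos)
  stats::spline(pos[keep], val[keep], xout = seq_len(n), method = "natural")$y
}

# Plain EMD by sifting with a fixed sift count per IMF.
emd_decompose <- function(x, max_imf, max_sift = 10) {
  n <- length(x)
  imfs <- list()
  r <- x
  while (length(imfs) < max_imf) {
    mx <- local_extrema(r, "max")
    mn <- local_extrema(r, "min")
    if (length(mx) + length(mn) < 4) break   # residual is monotone-ish
    h <- r
    for (s in seq_len(max_sift)) {
      imax <- local_extrema(h, "max")
      imin <- local_extrema(h, "min")
      if (length(imax) < 2 || length(imin) < 2) break
      m <- (envelope(h, imax) + envelope(h, imin)) / 2
      h <- h - m
    }
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  list(imfs = imfs, residual = r)
}

#' Ensemble empirical mode decomposition
#'
#' Decomposes a 1-D series into intrinsic mode functions (IMFs), ordered fast
#' to slow. Plain EMD suffers mode mixing; EEMD adds an independent white
#' noise realization to the series in each of \code{n_ensemble} trials, sifts
#' each noisy copy, and averages the IMFs index-wise, which maps components
#' to the dyadic reference scales of the noise while the noise itself cancels
#' in the ensemble mean (~\code{noise_ratio/sqrt(n_ensemble)} residual
#' level). The residual is defined as the input minus the IMF sum.
#'
#' @param x numeric series, length >= 64.
#' @param noise_ratio white-noise standard deviation as a fraction of
#'   \code{sd(x)}.
#' @param n_ensemble number of noise realizations averaged.
#' @param seed RNG seed (reproducible bit-for-bit for a fixed seed).
#' @param max_sift fixed sifting count per IMF extraction.
#' @param max_imf cap on the number of IMFs; default \code{floor(log2(n)) - 1}.
#' @return Object of class \code{imf_set}: matrix \code{imfs}
#'   (\code{m x n}), \code{residual}, the parameters, and a
#'   \code{degenerate} flag for constant input (zero IMFs).
#' @export
eemd <- function(x, noise_ratio = 0.1, n_ensemble = 50, seed = 42,
                 max_sift = 10, max_imf = NULL) {
  n <- length(x)
  if (n < 64) stop("series too short for EEMD: need >= 64 samples")
  if (is.null(max_imf)) max_imf <- max(1L, floor(log2(n)) - 1L)
  sx <- sd(x)
  if (sx == 0) {
    return(structure(list(imfs = matrix(numeric(0), 0, n), residual = x,
                          noise_ratio = noise_ratio, n_ensemble = n_ensemble,
                          seed = seed, degenerate = TRUE),
                     class = "imf_set"))
  }
  acc <- matrix(0, max_imf, n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  got <- integer(max_imf)
  for (tr in seq_len(n_ensemble)) {
    noisy <- x + rnorm(n, sd = noise_ratio * sx)
    dec <- emd_decompose(noisy, max_imf, max_sift)
    for (j in seq_along(dec$imfs)) {
      acc[j, ] <- acc[j, ] + dec$imfs[[j]]
      got[j] <- got[j] + 1L
    }
  }
  m <- max(which(got > 0), 0L)
  imfs <- acc[seq_len(m), , drop = FALSE] / n_ensemble
  structure(list(imfs = imfs, residual = x - colSums(imfs),
                 noise_ratio = noise_ratio, n_ensemble = n_ensemble,
                 seed = seed, degenerate = m == 0),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs x %d samples (noise %.3g, ensemble %d, seed %s)\n",
              nrow(x$imfs), ncol(x$imfs), x$noise_ratio, x$n_ensemble,
              format(x$seed)))
  invisible(x)
}

#' Band energy ratio of a signal
#'
#' Fraction of the one-sided spectral energy (FFT periodogram, excluding DC)
#' that falls in the fetal-movement band. The nominal band is 3-20 Hz; its
#' upper edge is clipped at Nyquist (12.5 Hz when fs = 25).
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param band two-element numeric, band edges in Hz.
#' @return Ratio in [0, 1]; 0 (with attribute \code{degenerate = TRUE}) for an
#'   all-zero signal.
#' @export
band_energy_ratio <- function(x, fs, band = c(3, 20)) {
  if (band[1] >= fs / 2) stop("band lower edge must be below Nyquist")
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  half <- f > 0 & f <= fs / 2
  p <- Mod(X[half])^2
  fh <- f[half]
  total <- sum(p)
  if (total == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  hi <- min(band[2], fs / 2)
  sum(p[fh >= band[1] & fh <= hi]) / total
}

#' Spearman rank correlation
#'
#' Both series are ranked (average ranks on ties) and the product-moment
#' correlation of the ranks is returned; this captures any monotone
#' association, linear or not.
#'
#' @param x,y numeric series of equal length (n >= 3).
#' @return Correlation in [-1, 1]; \code{NA} when either input is constant.
#' @export
spearman_eta <- function(x, y) {
  if (length(x) != length(y)) stop("inputs differ in length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y))
}

#' Select the fetal-movement IMF
#'
#' For every IMF the band energy ratio r_j (3 Hz to min(20, Nyquist) Hz) and
#' the Spearman correlation eta_j against the filtered series that was
#' decomposed are computed. IMFs with r_j > delta are candidates; among them
#' the one maximizing r_j + eta_j is the fetal-movement signal. When no IMF
#' clears delta the global maximizer of r_j + eta_j is returned with
#' \code{fallback_flag} set.
#'
#' @param imfset an [eemd()] result.
#' @param reference the high-pass-filtered series that was decomposed.
#' @param fs sampling rate (Hz).
#' @param delta energy-ratio gate (default 0.6).
#' @param band nominal fetal-movement band (Hz).
#' @return Object of class \code{fm_signal}: the selected IMF \code{x},
#'   \code{fs}, \code{selected_index}, per-IMF \code{diagnostics}
#'   (data.frame: energy_ratio, eta, score) and \code{fallback_flag}.
#' @export
select_fm_imf <- function(imfset, reference, fs, delta = 0.6,
                          band = c(3, 20)) {
  m <- nrow(imfset$imfs)
  if (m == 0) stop("no IMFs to select from (degenerate decomposition)")
  r <- apply(imfset$imfs, 1, band_energy_ratio, fs = fs, band = band)
  eta <- apply(imfset$imfs, 1, function(im)
    suppressWarnings(spearman_eta(im, reference)))
  score <- r + eta
  cand <- which(r > delta & !is.na(score))
  fallback <- length(cand) == 0
  pool <- if (fallback) which(!is.na(score)) else cand
  if (length(pool) == 0) pool <- seq_len(m) # all eta missing: fall back on r
  jstar <- pool[which.max(ifelse(is.na(score[pool]), r[pool], score[pool]))]
  structure(list(x = imfset$imfs[jstar, ], fs = fs,
                 selected_index = jstar,
                 diagnostics = data.frame(imf = seq_len(m), energy_ratio = r,
                                          eta = eta, score = score),
                 delta = delta, fallback_flag = fallback),
            class = "fm_signal")
}

#' @export
print.fm_signal <- function(x, ...) {
  cat(sprintf("<fm_signal> IMF %d selected (r=%.3f, eta=%.3f%s)\n",
              x$selected_index,
              x$diagnostics$energy_ratio[x$selected_index],
              x$diagnostics$eta[x$selected_index],
              if (x$fallback_flag) ", fallback" else ""))
  invisible(x)
}

#' Extract the fetal-movement signal from one motion series
#'
#' Convenience composition: high-pass filter, EEMD, IMF selection.
#'
#' @param x region-averaged motion series (H or S channel).
#' @param fs sampling rate (Hz).
#' @param config pipeline config (see [fm_config()]); uses its
#'   \code{filter}, \code{eemd} and \code{selection} sections.
#' @return An \code{fm_signal} (see [select_fm_imf()]), with the filtered
#'   series attached as attribute \code{"reference"}; \code{NULL} for a
#'   constant (motionless) series, whose decomposition is degenerate.
#' @export
extract_fm_signal <- function(x, fs, config = fm_config()) {
  filt <- highpass(x, fs, cutoff_hz = config$filter$cutoff_hz,
                   order = config$filter$order,
                   zero_phase = config$filter$zero_phase)
  dec <- eemd(filt, noise_ratio = config$eemd$noise_ratio,
              n_ensemble = config$eemd$n_ensemble, seed = config$eemd$seed,
              max_sift = config$eemd$max_sift)
  if (dec$degenerate) return(NULL)
  sel <- select_fm_imf(dec, filt, fs, delta = config$selection$delta)
  attr(sel, "reference") <- filt
  sel
}
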