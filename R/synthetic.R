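#' Synthetic-data configuration
#'
#' Defines the generating conditions for synthetic abdominal recordings: a
#' skin-toned abdomen (wider than tall) filling most of the frame,
#' quasi-periodic low-frequency respiration motion, sparse transient fetal
#' movements with in-band oscillatory content, and sensor noise. Defaults
#' emulate the recording geometry of the target setting at a reduced
#' resolution (320 x 180 at 25 fps).
#'
#' @param duration_s recording length (s).
#' @param fps frame rate (Hz).
#' @param width,height frame size (px).
#' @param n_events number of fetal movements.
#' @param event_times optional data.frame \code{start_s}, \code{end_s} fixing
#'   the schedule; otherwise events are placed by seeded stratified sampling.
#' @param event_duration_range movement duration range (s).
#' @param event_freq_range movement oscillation frequency range (Hz); must
#'   stay below fps/2, and below fps/4 for video rendering so that the
#'   rectified flow magnitude keeps its dominant harmonic in-band.
#' @param event_amp_px peak surface displacement of a movement (px).
#' @param resp_freq_hz respiration frequency (Hz), below the 3 Hz cutoff.
#' @param resp_amp_px respiration displacement amplitude (px).
#' @param pixel_noise_sd per-pixel luma noise SD (0..255 scale).
#' @param s_event_amp,s_resp_amp,s_noise_sd saturation-series amplitudes and
#'   white-noise SD for the direct signal path (S units).
#' @param h_event_amp,h_resp_amp,h_noise_sd hue-series analogues (degrees).
#' @param s_baseline,h_baseline series baselines.
#' @param well_separated enforce a minimum gap between events.
#' @param min_gap_s minimum gap between events (s) in well-separated mode.
#' @param edge_pad_s keep events away from the recording boundaries (s).
#' @param texture_amp luma texture amplitude of the rendered surface
#'   (uniform, 0..255 scale); texture is what optical flow tracks.
#' @param event_sigma_px spatial extent (Gaussian SD, px) of a movement bump;
#'   \code{NULL} scales with frame width (0.18 * width), emulating a kick
#'   that visibly deflects a sizable patch of the abdominal wall.
#' @param seed master seed; all sub-generators derive from it.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(duration_s = 120, fps = 25, width = 320, height = 180,
                         n_events = 5, event_times = NULL,
                         event_duration_range = c(1.5, 3),
                         event_freq_range = c(4, 6),
                         event_amp_px = 2.5,
                         resp_freq_hz = 0.3, resp_amp_px = 1.2,
                         pixel_noise_sd = 1,
                         s_event_amp = 0.35, s_resp_amp = 0.1,
                         s_noise_sd = 0.003,
                         h_event_amp = 60, h_resp_amp = 20, h_noise_sd = 2,
                         s_baseline = 0.02, h_baseline = 180,
                         well_separated = TRUE, min_gap_s = 8,
                         edge_pad_s = 5, texture_amp = 30,
                         event_sigma_px = NULL, seed = 1) {
  if (max(event_freq_range) >= fps / 2)
    stop("event frequency must stay below fps/2 = ", fps / 2, " Hz")
  if (resp_freq_hz >= 3)
    stop("respiration frequency must stay below the 3 Hz high-pass cutoff")
  if (duration_s <= 0 || fps <= 0) stop("duration_s and fps must be positive")
  structure(as.list(environment()), class = "synth_config")
}

# Deterministic sub-seed derivation from the master seed.
sub_seed <- function(seed, k) (as.integer(seed) * 7919L + k * 104729L) %% 2147483647L

# Seeded stratified event schedule: one event per equal timeline slot, placed
# uniformly where it fits with the required margins.
schedule_events <- function(cfg) {
  if (!is.null(cfg$event_times)) {
    ev <- cfg$event_times
    ev$freq_hz <- if (!is.null(ev$freq_hz)) ev$freq_hz else
      rep(mean(cfg$event_freq_range), nrow(ev))
    return(ev)
  }
  if (cfg$n_events == 0)
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      freq_hz = numeric()))
  span <- cfg$duration_s - 2 * cfg$edge_pad_s
  slot <- span / cfg$n_events
  gap <- if (cfg$well_separated && cfg$n_events > 1) cfg$min_gap_s else 0
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sub_seed(cfg$seed, 1L))
  d <- runif(cfg$n_events, cfg$event_duration_range[1],
             cfg$event_duration_range[2])
  if (any(slot < d + gap))
    stop("cannot place ", cfg$n_events, " events of up to ",
         max(cfg$event_duration_range), " s with a ", gap,
         " s gap in ", span, " s; reduce n_events or durations")
  f <- runif(cfg$n_events, cfg$event_freq_range[1], cfg$event_freq_range[2])
  start <- cfg$edge_pad_s + (seq_len(cfg$n_events) - 1) * slot +
    runif(cfg$n_events, gap / 2, slot - d - gap / 2)
  data.frame(start_s = start, end_s = start + d, freq_hz = f)
}

# Gaussian temporal envelope of one event evaluated at times t.
event_envelope <- function(t, start_s, end_s) {
  tc <- (start_s + end_s) / 2
  sigma <- (end_s - start_s) / 4
  exp(-(t - tc)^2 / (2 * sigma^2))
}

#' Synthesize H and S motion series with known ground truth
#'
#' Direct signal-path generator (no rendering): the saturation series is a
#' baseline plus a respiration sinusoid, Gaussian-enveloped oscillatory
#' movement bursts, and white noise; the hue series is the analogue in
#' degrees with independent noise. The clean respiration and movement
#' components are returned so recovery can be scored exactly.
#'
#' @param cfg a [synth_config()].
#' @return List: \code{series} (an \code{hs_series}), \code{truth} (list with
#'   \code{events} data.frame matching the annotation schema, \code{clean_fm},
#'   \code{clean_resp}), and \code{cfg}.
#' @export
synth_signal <- function(cfg = synth_config()) {
  ev <- schedule_events(cfg)
  n <- round(cfg$duration_s * cfg$fps)
  t <- (seq_len(n) - 1) / cfg$fps
  resp <- sin(2 * pi * cfg$resp_freq_hz * t)
  fm_unit <- rep(0, n)
  for (i in seq_len(nrow(ev)))
    fm_unit <- fm_unit + event_envelope(t, ev$start_s[i], ev$end_s[i]) *
      sin(2 * pi * ev$freq_hz[i] * (t - ev$start_s[i]))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sub_seed(cfg$seed, 2L))
  S <- cfg$s_baseline + cfg$s_resp_amp * resp + cfg$s_event_amp * fm_unit +
    rnorm(n, sd = cfg$s_noise_sd)
  H <- cfg$h_baseline + cfg$h_resp_amp * resp + cfg$h_event_amp * fm_unit +
    rnorm(n, sd = cfg$h_noise_sd)
  series <- structure(list(H = H, S = S, fs = cfg$fps, segment_id = 1L,
                           k_indices = seq_len(n) - 1L, t = t),
                      class = "hs_series")
  list(series = series,
       truth = list(events = ev[, c("start_s", "end_s")],
                    clean_fm = cfg$s_event_amp * fm_unit,
                    clean_resp = cfg$s_resp_amp * resp),
       cfg = cfg)
}

#' Render a synthetic abdominal video with known ground truth
#'
#' Renders a skin-toned, luma-textured ellipse (wider than tall) on a
#' non-skin background. Respiration is a slow global vertical translation;
#' each fetal movement is a localized oscillatory vertical displacement bump
#' (Gaussian in space, Gaussian-enveloped sinusoid in time) warped into the
#' frames by inverse bilinear sampling; seeded luma noise is added per frame.
#' The skin tone sits exactly at the skin-model ellipse center, and texture
#' and noise perturb luma only, so chroma classification is exercised
#' meaningfully.
#'
#' @param cfg a [synth_config()].
#' @param path optional output directory; when given, the PNG image stack,
#'   \code{meta.json} and \code{ground_truth.json} (annotation schema) are
#'   written there.
#' @param model the [skin_model()] whose center defines the rendered skin
#'   tone.
#' @return List: \code{seq} (a [frame_sequence()]), \code{truth} (as in
#'   [synth_signal()], without clean series), and \code{cfg}.
#' @export
synth_video <- function(cfg = synth_config(), path = NULL,
                        model = skin_model()) {
  if (max(cfg$event_freq_range) >= cfg$fps / 4)
    stop("video rendering needs event frequencies below fps/4 = ",
         cfg$fps / 4, " Hz: the flow-magnitude series oscillates at twice ",
         "the displacement frequency")
  ev <- schedule_events(cfg)
  h <- cfg$height; w <- cfg$width
  sigma_e <- cfg$event_sigma_px %||% (0.18 * w)
  n <- round(cfg$duration_s * cfg$fps)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sub_seed(cfg$seed, 3L))

  # static scene: abdomen ellipse + background, shared luma texture
  skin <- skin_color(model)
  bg <- c(60L, 70L, 120L)
  cx <- 0.5 * w; cy <- 0.55 * h; ax <- 0.44 * w; ay <- 0.34 * h
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  inside <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
  texture <- matrix(runif(h * w, -cfg$texture_amp, cfg$texture_amp), h, w)
  base <- array(0, c(h, w, 3))
  for (c3 in 1:3)
    base[, , c3] <- ifelse(inside, skin[c3], bg[c3]) + texture

  # per-event spatial bump centers, inside the ellipse
  necnt <- nrow(ev)
  exc <- cx + runif(necnt, -0.25, 0.25) * ax
  eyc <- cy + runif(necnt, -0.25, 0.25) * ay
  noise_seeds <- sub_seed(cfg$seed, 100L + seq_len(n))

  zero <- matrix(0, h, w)
  frames <- vector("list", n)
  tgrid <- (seq_len(n) - 1) / cfg$fps
  for (k in seq_len(n)) {
    t <- tgrid[k]
    d <- zero + cfg$resp_amp_px * sin(2 * pi * cfg$resp_freq_hz * t)
    for (i in seq_len(necnt)) {
      env <- event_envelope(t, ev$start_s[i], ev$end_s[i])
      if (env < 1e-4) next
      bump <- exp(-((X - exc[i])^2 + (Y - eyc[i])^2) / (2 * sigma_e^2))
      d <- d + cfg$event_amp_px * env *
        sin(2 * pi * ev$freq_hz[i] * (t - ev$start_s[i])) * bump
    }
    set.seed(noise_seeds[k])
    lnoise <- matrix(rnorm(h * w, sd = cfg$pixel_noise_sd), h, w)
    fr <- array(0L, c(h, w, 3))
    for (c3 in 1:3) {
      ch <- .cpp_warp(base[, , c3], zero, -d) + lnoise
      fr[, , c3] <- as.integer(round(pmin(pmax(ch, 0), 255)))
    }
    frames[[k]] <- fr
  }
  seq <- frame_sequence(frames, cfg$fps)
  truth <- list(events = ev[, c("start_s", "end_s")])
  if (!is.null(path)) {
    write_video(seq, path)
    jsonlite::write_json(truth$events, file.path(path, "ground_truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(seq = seq, truth = truth, cfg = cfg)
}
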