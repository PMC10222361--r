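---
title: "Non-contact fetal movement detection from abdominal video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact fetal movement detection from abdominal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(videofm)
```

## The problem

Fetal movement (FM) counting is a routine indicator of fetal well-being, but
maternal perception is unreliable and contact sensors (accelerometers, strain
gauges, piezoelectric films) are cumbersome for long, ambulatory monitoring.
A fixed camera pointed at the exposed maternal abdomen offers a contactless
alternative: a fetal kick or stretch deflects the abdominal wall, and that
deflection is visible as transient, localized motion in the video.

`videofm` implements the full analysis chain from video frames to clinical
movement parameters:

1. **Abdomen localization** — per-frame skin segmentation with an elliptical
   chroma model, morphological opening, 8-connected component labeling, and
   an aspect-ratio rule (the supine abdomen is wider than tall).
2. **Motion signal** — dense optical flow between consecutive frames, encoded
   as hue (direction) and saturation (magnitude), averaged over the abdominal
   region: one H and one S sample per frame pair, at the video frame rate.
3. **FM signal extraction** — 7th-order 3 Hz Butterworth high-pass, ensemble
   empirical mode decomposition (EEMD, noise ratio 0.1, ensemble 50), and
   selection of the intrinsic mode function (IMF) maximizing band-energy
   ratio plus Spearman correlation, gated at energy ratio > 0.6.
4. **Spike detection** — first/second-order difference thresholds: Th1 is the
   mean of the local minima of the second difference; Th2 = a·max(y3) with
   y3(n) = y1max·y1(n) + y2max·y2(n) and a = 0.03 by default.
5. **Events and parameters** — spikes closer than 6 s merge into one FM
   event; events are summarized as number/hour, intervals, durations, and
   percentage of analyzed time.
6. **Evaluation** — event-level TDR/PPV/SEN/ACC/F1 against gold-standard
   annotations, and Bland–Altman agreement of per-recording parameters.

## Data model and assumptions

The subject lies still; frames contaminated by maternal movement are removed
beforehand via an exclusion list (automatic maternal-motion rejection is out
of scope). All signal analysis runs per contiguous segment between
exclusions — never across a gap, which would manufacture motion spikes at the
seam. Analyzed time is the sum of segment durations, so exclusions never
inflate the percentage denominator.

Respiration dominates the raw motion series as a quasi-periodic 0.2–0.5 Hz
component; fetal movements contribute transients with spectral content from
3 Hz up to roughly 20 Hz. At the 25 fps frame rate the usable band is capped
by Nyquist, so the FM band is effectively **3–12.5 Hz**; the band-energy
ratio clips its upper edge at Nyquist rather than pretending content exists
above it.

Because videos arrive without a reliable R codec binding, recordings are
handled as lossless PNG image-stack directories with a `meta.json` frame-rate
record (the same representation the synthetic generator writes). Users with
their own motion-extraction front end can enter the pipeline at the H/S
series level via `read_hs_csv()` and `run_detect()`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `filter$order`, `filter$cutoff_hz` | 7, 3 | –, Hz | removes respiration and drift while keeping the FM band |
| `eemd$noise_ratio`, `eemd$n_ensemble` | 0.1, 50 | –, trials | ensemble averaging suppresses mode mixing; residual noise ≈ 0.1/√50 ≈ 1.4% |
| `selection$delta` | 0.6 | – | energy-ratio gate separating FM-band IMFs from background |
| `spike$a` | 0.03 | – | midpoint of the stated 0.01–0.05 range; Th2 = a·max(y3) |
| `events$gap_s` | 6 | s | spikes closer than this belong to one movement |
| `flow$m_norm` | 5 | px/frame | flow magnitude mapping to full saturation; a fixed global scale keeps S comparable over time |
| `opening$radius_px` | 5 at width 1280 | px | removes skin-mask speckle only; scaled with frame width |

The skin-model ellipse (CbCr center, axes, rotation) is config-exposed
because lighting and complexion shift the skin locus between recordings; the
defaults are the classical elliptical skin-locus parameters.

## Numerical choices

- **Zero-phase filtering.** The high-pass is applied forward–backward so that
  spike timing is undistorted for event matching; this doubles the stopband
  attenuation (an order-7 design at 0.3 Hz already exceeds 60 dB one-way).
  The series is odd-reflection padded before `filtfilt` and trimmed after;
  without padding, start/end transients of the filter masquerade as movement
  spikes at segment boundaries.
- **EEMD.** Sifting uses natural cubic-spline envelopes through strict
  interior extrema, with up to two extrema mirrored across each boundary; a
  fixed count of 10 sifts per IMF (determinism over adaptive stopping), at
  most ⌊log₂ n⌋ − 1 IMFs, and a fixed seed (default 42) so that a run is
  reproducible bit for bit. The residual is defined as input minus IMF sum.
  Constant segments decompose degenerately (zero IMFs) and yield no events.
- **Hue averaging.** The region average of hue is arithmetic, matching the
  channel-averaging definition, although hue is circular; S is the primary
  reporting channel and is unaffected.
- **Spike rule reading.** The published rule compares the signal amplitude
  x(n) itself against Th1 and Th2 even though y3 (and hence Th2) carries
  squared-amplitude units. The literal comparison is the default; the
  arguably intended comparison of y3(n) against Th2 is available as
  `spike$compare_on = "y3"`. Strict inequalities are used throughout, so an
  all-zero signal produces no spikes.
- **Th1 degeneracy.** A second difference with no interior local minimum
  (monotone input) falls back to its minimum value, flagged.
- **Selection fallback.** If no IMF clears the 0.6 energy-ratio gate, the
  global maximizer of (energy ratio + Spearman) is returned with
  `fallback_flag` set rather than failing the segment.
- **Aspect-ratio tie-break.** Among components whose bounding-box
  width/height exceeds 1, the largest pixel area wins (the abdomen dominates
  the frame).
- **Mask for a frame pair** is the mask of the earlier frame — deterministic
  and simple; nothing in the method requires one choice over the other.
- **Single-spike events** last one sample period (1/fs): a spike occupies at
  least one sample, and no other duration is defined for it.
- **Event intervals** are measured end-of-event to start-of-next by default
  (consistent with intervals an order of magnitude longer than durations);
  onset-to-onset is available via `events$interval_mode`.
- **Accuracy formula.** Event-level detection has no countable true-negative
  set, and the published accuracy values are reproduced exactly by
  TP/(TP+FP+FN) — equivalently ACC = 1/(1/PPV + 1/SEN − 1) on fractions — so
  that reading is implemented (`acc_from_ppv_sen()` exposes the identity).
  TDR always equals SEN because TP + FN equals the number of labeled events.
- **Matching rule.** A labeled movement is detected if any predicted event
  overlaps it (closed intervals, optional pad); one long prediction may
  validate several labels, each judged independently.

## The synthetic generator

No abdominal recordings ship with the package, so `synth_video()` and
`synth_signal()` generate the study conditions with exact ground truth:

- a skin-toned, luma-textured ellipse (wider than tall) on a non-skin
  background — texture and per-frame sensor noise perturb luma only, so the
  chroma sits exactly on the skin-model locus;
- respiration as a slow global vertical translation (0.3 Hz, ~1 px);
- each fetal movement as a localized vertical displacement bump, Gaussian in
  space and a Gaussian-enveloped sinusoid (4–6 Hz) in time, warped into the
  frames by inverse bilinear sampling;
- seeded white noise on pixels (video path) or directly on the H/S series
  (signal path). All randomness derives from one master seed.

Default magnitudes are chosen to be physically sensible rather than easy: a
visible kick deflects a sizable patch of the abdominal wall (spatial SD 18%
of frame width, peak displacement 2.5 px at 320×180 — about 0.5 of the
saturation scale), and sensor noise is ~1 digital level. Note that averaging
the flow magnitude over ~2×10⁴ abdominal pixels suppresses incoherent flow
noise by orders of magnitude, so the region-averaged series is much cleaner
than any single pixel; the signal-path default noise (SD 0.003 in saturation
units) reflects that. In video-derived series the saturation during an event
is a *rectified* oscillation, so its dominant spectral line sits at twice the
displacement frequency; the generator therefore keeps displacement
frequencies below fps/4 for rendered videos.

What the generator does **not** emulate: maternal motion artifacts (the
method assumes they are excluded upstream), lighting drift, camera shake,
perspective deformation, fetal biomechanics, and photorealistic skin. Passing
the recovery tests therefore demonstrates the pipeline's internal
correctness under its stated assumptions, not clinical performance on real
recordings.

## Known limitations

- **Threshold noise floor.** Th2 = a·max(y3) has squared-amplitude units
  while it gates the amplitude x(n); for signals of magnitude ≪ 1 the
  threshold is quadratically small. In practice the selected IMF's baseline
  must be roughly 40 dB below the event amplitude, or baseline samples cross
  the threshold. Region averaging delivers that headroom on clean recordings,
  but on noisier series the detector emits stray single-spike events, and a
  recording with no movement at all (but nonzero noise) will still yield
  detections — the thresholds are purely relative. This is inherent to the
  published rule; both comparison modes share it.
- **Hue channel.** Because Th2 grows with the square of the signal amplitude,
  the spike rule only behaves for unit-scale series; a hue series in degrees
  (amplitudes of tens) could never cross Th2 at all. The pipeline therefore
  detects on hue converted to turns (H/360), putting both channels on a
  common [0,1] scale. Even so, direction is discriminative only when movement
  has a consistent direction; on synthetic data the S channel is uniformly
  superior, matching the published channel comparison.
- **No maternal-motion rejection**; exclusion lists are trusted as exact.
- 8-connected labeling, opening radius, and the skin ellipse were validated
  on synthetic frames only.

## Problem sizes used by the tests

Unit and acceptance tests run at reduced scale chosen by the package:
320×180 at 25 fps for rendered recordings (up to 120 s, 5 events for the
end-to-end recovery check; 60 s, 3 events in the acceptance script), 30 s
series for the EEMD contract, and 1000 randomized trials for the
selection-rule oracle. These sizes exercise every code path while keeping a
full run to minutes on one CPU.

## A worked example

```{r example, eval = FALSE}
syn <- synth_signal(synth_config(n_events = 5, seed = 3))
report <- run_detect(syn$series, annotations = syn$truth$events)
report
#> <run_report> 120.0 s analyzed @ 25 Hz
#>   H: 1 events (30.00 /h, 99.63% of time)
#>   S: 5 events (150.00 /h, 11.37% of time)
#> <metrics_report> TP=5 FP=0 FN=0 TME=5
#>   TDR 100.00% | PPV 100.00% | SEN 100.00% | ACC 100.00% | F1 100.00%
```

All five seeded movements are recovered on the saturation channel with
perfect event-level metrics; the hue channel smears into one long detection —
direction is a far weaker cue than magnitude, consistent with the published
channel comparison.
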