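fs <- 25

test_that("high-pass kills DC and low tones and passes the movement band", {
  t <- seq(1 / fs, 60, by = 1 / fs)
  expect_lte(max(abs(highpass(rep(3, 800), fs))), 3e-6)
  slow <- highpass(sin(2 * pi * 0.3 * t), fs)
  expect_lte(20 * log10(rms(slow) / rms(sin(2 * pi * 0.3 * t))), -60)
  fast <- sin(2 * pi * 10 * t)
  expect_lte(abs(20 * log10(rms(highpass(fast, fs)) / rms(fast))), 1)
  expect_error(highpass(rnorm(10), fs), "too short")
  expect_error(highpass(rnorm(100), fs, cutoff_hz = 13), "Nyquist|cutoff")
})

test_that("EEMD reconstructs, concentrates tones, and separates scales", {
  t <- seq(1 / fs, 30, by = 1 / fs)
  tone <- sin(2 * pi * 5 * t)
  dec <- eemd(tone, seed = 42)
  recon <- colSums(dec$imfs) + dec$residual
  expect_lte(rms(recon - tone), 0.05 * sd(tone))
  energy <- rowSums(dec$imfs^2)
  expect_gte(max(energy) / sum(energy), 0.85)

  mix <- sin(2 * pi * 5 * t) + sin(2 * pi * 0.5 * t)
  dmix <- eemd(mix, seed = 42)
  c5 <- apply(dmix$imfs, 1, function(im) abs(cor(im, sin(2 * pi * 5 * t))))
  c05 <- apply(dmix$imfs, 1, function(im) abs(cor(im, sin(2 * pi * 0.5 * t))))
  expect_true(which.max(c5) != which.max(c05))
  expect_gte(max(c5), 0.9)
  expect_gte(max(c05), 0.9)
})

test_that("EEMD is seed-reproducible and flags degenerate input", {
  set.seed(99)
  x <- rnorm(128)
  a <- eemd(x, n_ensemble = 10, seed = 7)
  b <- eemd(x, n_ensemble = 10, seed = 7)
  expect_identical(a$imfs, b$imfs)
  c2 <- eemd(x, n_ensemble = 10, seed = 8)
  expect_false(identical(a$imfs, c2$imfs))
  expect_lte(rms(a$imfs - c2$imfs), 0.2 * sd(x))

  flat <- eemd(rep(1, 100), seed = 1)
  expect_true(flat$degenerate)
  expect_equal(nrow(flat$imfs), 0)
  expect_equal(flat$residual, rep(1, 100))
  expect_error(eemd(rnorm(32)), "too short")
})

test_that("band energy ratio integrates the movement band up to Nyquist", {
  t <- seq(1 / fs, 30, by = 1 / fs)
  expect_gte(band_energy_ratio(sin(2 * pi * 5 * t), fs), 0.99)
  expect_lte(band_energy_ratio(sin(2 * pi * 1 * t), fs), 0.01)
  two <- sin(2 * pi * 1 * t) + sin(2 * pi * 5 * t)
  expect_equal(band_energy_ratio(two, fs), 0.5, tolerance = 0.02)
  # scale invariance and bounds
  set.seed(3)
  x <- rnorm(500)
  expect_equal(band_energy_ratio(3 * x, fs), band_energy_ratio(x, fs))
  for (i in 1:10) {
    r <- band_energy_ratio(rnorm(200), fs)
    expect_gte(r, 0); expect_lte(r, 1)
  }
  z <- band_energy_ratio(rep(0, 100), fs)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("Spearman correlation matches rank arithmetic and base R", {
  expect_equal(spearman_eta(1:5, (1:5)^3), 1)
  expect_equal(spearman_eta(1:5, -(1:5)), -1)
  # ranks of y = (2,3,1,5,4); Pearson on ranks gives 0.6
  expect_equal(spearman_eta(c(1, 2, 3, 4, 5), c(5, 6, 4, 8, 7)), 0.6)
  set.seed(11)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(spearman_eta(x, y), cor(x, y, method = "spearman"))
  # invariance under strictly monotone transforms
  expect_equal(spearman_eta(exp(x), y), spearman_eta(x, y))
  expect_equal(spearman_eta(x, atan(y)), spearman_eta(x, y))
  expect_warning(out <- spearman_eta(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(out))
  expect_error(spearman_eta(1:4, 1:5), "length")
})

test_that("IMF selection equals brute-force scoring with the delta gate", {
  # independent scorer: energy ratio by direct periodogram + Spearman by ranks
  brute <- function(imfs, ref, delta) {
    n <- ncol(imfs)
    f <- (seq_len(n) - 1) * fs / n
    half <- f > 0 & f <= fs / 2
    r <- apply(imfs, 1, function(x) {
      p <- Mod(fft(x)[half])^2
      sum(p[f[half] >= 3 & f[half] <= min(20, fs / 2)]) / sum(p)
    })
    eta <- apply(imfs, 1, function(x) cor(rank(x), rank(ref)))
    cand <- which(r > delta)
    if (length(cand)) cand[which.max((r + eta)[cand])]
    else which.max(r + eta)
  }
  set.seed(2024)
  for (trial in 1:200) {
    m <- sample(2:6, 1); n <- 128
    tt <- seq_len(n) / fs
    imfs <- t(sapply(seq_len(m), function(j)
      sin(2 * pi * runif(1, 0.2, 12) * tt + runif(1, 0, 2 * pi)) *
        runif(1, 0.2, 2) + rnorm(n, sd = 0.05)))
    ref <- colSums(imfs) + rnorm(n, sd = 0.1)
    iset <- structure(list(imfs = imfs, residual = rep(0, n)),
                      class = "imf_set")
    sel <- select_fm_imf(iset, ref, fs, delta = 0.6)
    expect_equal(sel$selected_index, brute(imfs, ref, 0.6))
    expect_identical(sel$fallback_flag,
                     !any(sel$diagnostics$energy_ratio > 0.6))
  }
})

test_that("a lone candidate is selected without fallback, else fallback flags", {
  n <- 256; tt <- seq_len(n) / fs
  inband <- sin(2 * pi * 6 * tt)
  low <- sin(2 * pi * 0.4 * tt)
  iset1 <- structure(list(imfs = rbind(inband + 0.4 * rnorm(n, sd = 0.1)),
                          residual = rep(0, n)), class = "imf_set")
  s1 <- select_fm_imf(iset1, inband, fs)
  expect_equal(s1$selected_index, 1)
  expect_false(s1$fallback_flag)
  iset2 <- structure(list(imfs = rbind(low, 0.5 * low + 0.1), residual = rep(0, n)),
                     class = "imf_set")
  s2 <- select_fm_imf(iset2, low, fs)
  expect_true(s2$fallback_flag)
})

test_that("selection tracks the movement bursts, not respiration", {
  cfg <- synth_config(duration_s = 60, n_events = 4, seed = 21,
                      event_freq_range = c(4, 8))
  syn <- synth_signal(cfg)
  sig <- extract_fm_signal(syn$series$S, fs)
  cor_fm <- abs(cor(sig$x, syn$truth$clean_fm))
  cor_resp <- abs(cor(sig$x, syn$truth$clean_resp))
  expect_gt(cor_fm, cor_resp)
  expect_gt(cor_fm, 0.5)
})
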