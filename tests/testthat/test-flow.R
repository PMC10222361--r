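test_that("flow is zero for identical frames and recovers known shifts", {
  f <- textured_frame(100, 140, seed = 7)
  still <- dense_flow(f, f)
  expect_lte(max(abs(still$u)), 1e-3)
  expect_lte(max(abs(still$v)), 1e-3)

  right1 <- dense_flow(f, shift_right(f, 1))
  expect_gte(median(interior(right1$u)), 0.8)
  expect_lte(median(interior(right1$u)), 1.2)
  expect_lte(abs(median(interior(right1$v))), 0.2)

  down2 <- dense_flow(f, shift_down(f, 2))
  expect_gte(median(interior(down2$v)), 1.6)
  expect_lte(median(interior(down2$v)), 2.4)
  expect_lte(abs(median(interior(down2$u))), 0.2)

  expect_error(dense_flow(f, f[1:50, , ]), "shape")
})

test_that("HS encoding follows the direction/magnitude conventions", {
  mk <- function(u, v) list(u = matrix(u, 2, 2), v = matrix(v, 2, 2))
  z <- encode_hs(mk(0, 0), m_norm = 5)
  expect_equal(z$s, matrix(0, 2, 2))
  expect_equal(z$h, matrix(0, 2, 2))
  r <- encode_hs(mk(5, 0), m_norm = 5)
  expect_equal(r$s, matrix(1, 2, 2))
  expect_equal(r$h, matrix(0, 2, 2))
  d <- encode_hs(mk(0, 5), m_norm = 5)   # y-down: downward motion is 270
  expect_equal(d$s, matrix(1, 2, 2))
  expect_equal(d$h, matrix(270, 2, 2))
})

test_that("saturation is rotation-invariant and linear below the clip", {
  set.seed(5)
  u <- matrix(rnorm(48), 6, 8); v <- matrix(rnorm(48), 6, 8)
  base <- encode_hs(list(u = u, v = v), m_norm = 10)
  ang <- 0.7
  rot <- encode_hs(list(u = cos(ang) * u - sin(ang) * v,
                        v = sin(ang) * u + cos(ang) * v), m_norm = 10)
  expect_equal(rot$s, base$s, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(rot$h, base$h)))
  dbl <- encode_hs(list(u = 2 * u, v = 2 * v), m_norm = 10)
  expect_equal(dbl$s, 2 * base$s, tolerance = 1e-12)
})

test_that("region averaging is the masked mean and ignores outside pixels", {
  ch <- matrix(0.4, 5, 5)
  mask <- matrix(FALSE, 5, 5); mask[2:3, 2:3] <- TRUE
  expect_equal(region_average(ch, mask), 0.4)
  ch2 <- matrix(0, 5, 5); ch2[2, 2:3] <- 1   # mask values {1,1,0,0}
  expect_equal(region_average(ch2, mask), 0.5)
  ch3 <- ch2; ch3[!mask] <- 99
  expect_equal(region_average(ch3, mask), 0.5)
  set.seed(1)
  ch4 <- matrix(runif(25), 5, 5)
  avg <- region_average(ch4, mask)
  expect_gte(avg, min(ch4[mask])); expect_lte(avg, max(ch4[mask]))
  expect_warning(bad <- region_average(ch, matrix(FALSE, 5, 5)), "empty")
  expect_true(is.na(bad))
})

test_that("series length, static-scene silence, and event localization hold", {
  # static scene: zero amplitudes, zero noise
  cfg0 <- synth_config(duration_s = 0.4, n_events = 0, width = 160, height = 90,
                       resp_amp_px = 0, pixel_noise_sd = 0, seed = 4)
  sv0 <- synth_video(cfg0)
  masks <- detect_abdomen(sv0$seq)
  ser0 <- build_series(sv0$seq, masks)
  expect_length(ser0, 1)
  expect_length(ser0[[1]]$S, length(sv0$seq$frames) - 1)
  expect_lte(mean(abs(ser0[[1]]$S)), 0.01)

  # one rendered movement: the S peak falls inside the event window
  cfg1 <- synth_config(duration_s = 16, n_events = 1, width = 160, height = 90,
                       edge_pad_s = 4, seed = 4)
  sv1 <- synth_video(cfg1)
  ser1 <- build_series(sv1$seq, detect_abdomen(sv1$seq))
  s <- ser1[[1]]
  tpeak <- s$t[which.max(s$S)]
  expect_gte(tpeak, sv1$truth$events$start_s[1] - 0.2)
  expect_lte(tpeak, sv1$truth$events$end_s[1] + 0.2)
})
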