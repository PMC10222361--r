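ev_df <- function(...) {
  m <- matrix(c(..., numeric()), ncol = 2, byrow = TRUE)
  data.frame(start_s = m[, 1], end_s = m[, 2])
}

test_that("event matching follows the overlap rule", {
  labs <- ev_df(9, 11, 30, 33)
  same <- match_events(labs, labs)
  expect_equal(same$TP, 2); expect_equal(same$FP, 0); expect_equal(same$FN, 0)

  disj <- match_events(ev_df(50, 52, 60, 61), labs)
  expect_equal(disj$TP, 0); expect_equal(disj$FP, 2); expect_equal(disj$FN, 2)

  one <- match_events(ev_df(10, 12), labs)
  expect_equal(one$TP, 1); expect_equal(one$FP, 0); expect_equal(one$FN, 1)

  # one long detection spanning both labels validates both
  span <- match_events(ev_df(8, 34), labs)
  expect_equal(span$TP, 2); expect_equal(span$FP, 0)

  # tolerance pad turns a near miss into a hit
  near <- ev_df(11.5, 12)
  expect_equal(match_events(near, labs)$TP, 0)
  expect_equal(match_events(near, labs, pad_s = 1)$TP, 1)

  expect_equal(match_events(ev_df(), labs)$FN, 2)
  expect_true(all(c(same$TP + same$FN, disj$TP + disj$FN) == same$TME))
})

test_that("metrics reproduce the worked example and degenerate NAs", {
  m <- detection_metrics(list(TP = 2, FP = 1, FN = 2, TME = 4))
  expect_equal(m$TDR, 50)
  expect_equal(m$PPV, 200 / 3, tolerance = 1e-10)
  expect_equal(m$SEN, 50)
  expect_equal(m$ACC, 40)
  expect_equal(m$F1, 2 * m$PPV * m$SEN / (m$PPV + m$SEN))

  none <- detection_metrics(list(TP = 0, FP = 0, FN = 5, TME = 5))
  expect_equal(none$TDR, 0)
  expect_true(is.na(none$PPV))
  expect_true(is.na(none$F1))
})

test_that("TDR equals SEN and F1 stays between PPV and SEN", {
  set.seed(31)
  for (trial in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fn == 0 || tp + fp == 0 || tp == 0) next
    m <- detection_metrics(list(TP = tp, FP = fp, FN = fn, TME = tp + fn))
    expect_equal(m$TDR, m$SEN)
    expect_gte(m$F1, min(m$PPV, m$SEN) - 1e-9)
    expect_lte(m$F1, max(m$PPV, m$SEN) + 1e-9)
  }
})

test_that("metrics agree with brute-force recomputation from event lists", {
  set.seed(77)
  for (trial in 1:25) {
    n_lab <- sample(1:8, 1); n_pred <- sample(0:8, 1)
    labs <- ev_df(); start <- 0
    for (i in seq_len(n_lab)) {
      start <- start + runif(1, 5, 20)
      labs <- rbind(labs, data.frame(start_s = start,
                                     end_s = start + runif(1, 1, 4)))
      start <- labs$end_s[nrow(labs)]
    }
    pred <- data.frame(start_s = runif(n_pred, 0, start),
                       end_s = NA_real_)
    pred$end_s <- pred$start_s + runif(n_pred, 0.5, 5)
    pred <- pred[order(pred$start_s), ]
    got <- match_events(pred, labs)
    # brute force, label by label / prediction by prediction
    tp <- 0
    for (i in seq_len(nrow(labs)))
      if (any(pred$start_s <= labs$end_s[i] & labs$start_s[i] <= pred$end_s))
        tp <- tp + 1
    fp <- 0
    for (j in seq_len(nrow(pred)))
      if (!any(labs$start_s <= pred$end_s[j] & pred$start_s[j] <= labs$end_s))
        fp <- fp + 1
    expect_equal(got$TP, tp)
    expect_equal(got$FP, fp)
    expect_equal(got$FN, nrow(labs) - tp)
  }
})

test_that("annotation files load from JSON, CSV and frame-based CSV", {
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"start_s": 3, "end_s": 5}, {"start_s": 1, "end_s": 2}]', j)
  a <- read_annotations(j)
  expect_equal(a$start_s, c(1, 3))   # reordered
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start_frame,end_frame", "50,100"), csv)
  b <- read_annotations(csv, fps = 25)
  expect_equal(b$start_s, 2)
  expect_equal(b$end_s, 4)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_annotations(bad), "start_s")
})

test_that("Bland-Altman matches hand-computed fixtures", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  off <- bland_altman(c(4, 5, 6), c(1, 2, 3))
  expect_equal(off$mean_diff, 3)
  expect_equal(c(off$loa_low, off$loa_high), c(3, 3))

  ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(ba$diffs, c(-1, 0, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)  # sample SD
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))
  expect_equal(ba$means, c(1.5, 2, 2.5))
  expect_error(bland_altman(1:3, 1:4), "length")
})
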