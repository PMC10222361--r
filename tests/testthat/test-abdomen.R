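test_that("chroma at the ellipse center is skin, saturated blue is not", {
  model <- skin_model()
  center_rgb <- skin_color(model)
  # independent check of the example: evaluate the ellipse inequality at the
  # analytically transformed chroma of each fill color
  chroma <- function(rgb) c(
    cb = 128 - 0.168736 * rgb[1] - 0.331264 * rgb[2] + 0.5 * rgb[3],
    cr = 128 + 0.5 * rgb[1] - 0.418688 * rgb[2] - 0.081312 * rgb[3])
  inside <- function(rgb) {
    d <- chroma(rgb) - c(model$cx, model$cy)
    x <- cos(model$theta) * d[1] + sin(model$theta) * d[2]
    y <- -sin(model$theta) * d[1] + cos(model$theta) * d[2]
    (x / model$a)^2 + (y / model$b)^2 <= 1
  }
  expect_true(inside(center_rgb))
  expect_false(inside(c(0, 0, 255)))

  m1 <- skin_mask(flat_frame(center_rgb), model)
  expect_true(all(m1$mask))
  expect_equal(m1$area_px, 20 * 30)

  m2 <- skin_mask(flat_frame(c(0, 0, 255)), model)
  expect_false(any(m2$mask))
  expect_equal(m2$bbox, rep(0L, 4))

  half <- flat_frame(center_rgb, h = 20, w = 30)
  half[, 16:30, ] <- flat_frame(c(0L, 0L, 255L), h = 20, w = 15)
  m3 <- skin_mask(half, model)
  expect_true(all(m3$mask[, 1:15]))
  expect_false(any(m3$mask[, 16:30]))
})

test_that("opening removes speckle, preserves blocks, and is idempotent", {
  m <- matrix(FALSE, 40, 40)
  m[20, 20] <- TRUE
  expect_equal(open_mask(region_mask(m, "skin"), 2)$area_px, 0)

  block <- matrix(FALSE, 120, 120)
  block[11:110, 11:110] <- TRUE
  opened <- open_mask(region_mask(block, "skin"), 2)
  expect_gte(opened$area_px, 0.99 * sum(block))
  expect_true(all(opened$mask[block == FALSE] == FALSE))

  mixed <- block
  mixed[2, 2] <- TRUE
  once <- open_mask(region_mask(mixed, "skin"), 2)
  twice <- open_mask(once, 2)
  expect_identical(twice$mask, once$mask)
})

test_that("component selection follows the aspect-ratio and area rules", {
  mk <- function(rects) {
    m <- matrix(FALSE, 60, 80)
    for (r in rects) m[r[1]:r[2], r[3]:r[4]] <- TRUE
    region_mask(m, "opened")
  }
  # wide 30x10 beats tall 10x30
  sel <- select_abdomen(mk(list(c(5, 14, 5, 34), c(25, 54, 50, 59))))
  expect_false(attr(sel, "empty"))
  expect_equal(sel$area_px, 300)
  expect_equal(sel$bbox, c(4L, 4L, 14L, 34L))
  # two qualifying components: larger area wins (800 over 300)
  sel2 <- select_abdomen(mk(list(c(5, 14, 5, 34), c(30, 49, 20, 59))))
  expect_equal(sel2$area_px, 800)
  # only a tall component: nothing qualifies
  sel3 <- select_abdomen(mk(list(c(10, 39, 10, 19))))
  expect_true(attr(sel3, "empty"))
  expect_equal(sel3$area_px, 0)
  # empty input mask
  sel4 <- select_abdomen(region_mask(matrix(FALSE, 10, 10), "opened"))
  expect_true(attr(sel4, "empty"))
})

test_that("selected region is one 8-connected component nested in the stages", {
  sv <- synth_video(synth_config(duration_s = 1, n_events = 0, width = 160,
                                 height = 90, seed = 2))
  frame <- sv$seq$frames[[1]]
  skin <- skin_mask(frame)
  opened <- open_mask(skin, 1)
  sel <- select_abdomen(opened)
  expect_true(all(opened$mask[skin$mask == FALSE] == FALSE))
  expect_true(all(sel$mask[opened$mask == FALSE] == FALSE))
  lab <- videofm:::.cpp_label8(sel$mask)
  expect_equal(max(lab), 1)
  # diagonal connectivity counts as one component
  diag2 <- matrix(FALSE, 5, 5); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(max(videofm:::.cpp_label8(diag2)), 1)
})

test_that("detection recovers the rendered abdomen ellipse per frame", {
  cfg <- synth_config(duration_s = 0.4, n_events = 0, width = 160,
                      height = 90, seed = 3)
  sv <- synth_video(cfg)
  w <- cfg$width; h <- cfg$height
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  truth <- ((X - 0.5 * w) / (0.44 * w))^2 +
    ((Y - 0.55 * h) / (0.34 * h))^2 <= 1
  masks <- detect_abdomen(sv$seq)
  for (m in masks) {
    expect_false(attr(m, "empty"))
    expect_gte(sum(m$mask & truth) / sum(truth), 0.95)
    expect_lte(sum(m$mask & !truth) / sum(!truth), 0.05)
  }
  # lock mode reuses one mask
  locked <- detect_abdomen(sv$seq, lock = TRUE)
  expect_identical(locked[[1]]$mask, locked[[length(locked)]]$mask)
})
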