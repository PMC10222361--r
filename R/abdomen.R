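#' Elliptical chroma skin model
#'
#' Skin pixels cluster in a compact elliptical region of the CbCr chroma
#' plane, largely independent of luma. A pixel is classified as skin when its
#' (Cb, Cr) coordinates, rotated by \code{theta} about the ellipse center,
#' fall inside the ellipse. The defaults are the classical elliptical skin
#' locus parameters; lighting varies between recordings, so every parameter
#' is exposed through the pipeline config.
#'
#' @param cx,cy ellipse center in (Cb, Cr) coordinates (0..255 scale).
#' @param a,b semi-axes along the rotated major/minor directions.
#' @param theta rotation angle (radians, counterclockwise).
#' @return An object of class \code{skin_model}.
#' @export
skin_model <- function(cx = 109.38, cy = 152.02, a = 25.39, b = 14.03,
                       theta = 2.53) {
  stopifnot(a > 0, b > 0)
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "skin_model")
}

#' RGB color at the skin-model ellipse center
#'
#' Inverts the BT.601 YCbCr transform at the model's chroma center for a given
#' luma. Used by the synthetic generator so the rendered abdomen sits exactly
#' on the skin locus.
#'
#' @param model a [skin_model()].
#' @param y luma value (0..255).
#' @return Integer RGB triple in 0..255.
#' @export
skin_color <- function(model = skin_model(), y = 160) {
  cb <- model$cx - 128
  cr <- model$cy - 128
  rgb <- c(y + 1.402 * cr,
           y - 0.344136 * cb - 0.714136 * cr,
           y + 1.772 * cb)
  as.integer(round(pmin(pmax(rgb, 0), 255)))
}

rgb_to_cbcr <- function(frame) {
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  list(cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
       cr = 128 + 0.5 * r - 0.418688 * g - 0.081312 * b)
}

#' Construct a region mask
#'
#' @param mask logical matrix (height x width).
#' @param stage provenance stage: \code{"skin"}, \code{"opened"} or
#'   \code{"selected"}.
#' @return Object of class \code{region_mask} with the tight bounding box
#'   (\code{bbox}, half-open \code{(row0, col0, row1, col1)}, 0-based) and
#'   pixel area.
#' @export
region_mask <- function(mask, stage = c("skin", "opened", "selected")) {
  stage <- match.arg(stage)
  stopifnot(is.logical(mask), is.matrix(mask))
  area <- sum(mask)
  bbox <- if (area > 0) {
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    c(rows[1] - 1L, cols[1] - 1L, rows[2], cols[2])
  } else rep(0L, 4)
  structure(list(mask = mask, stage = stage, bbox = bbox, area_px = area),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask:%s> %d px, bbox [%d,%d)x[%d,%d)\n", x$stage,
              x$area_px, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Skin-color segmentation of a frame
#'
#' @param frame RGB integer array (height x width x 3, 0..255).
#' @param model a [skin_model()].
#' @return A [region_mask()] at stage \code{"skin"}: true where the pixel's
#'   chroma falls inside the model ellipse.
#' @export
skin_mask <- function(frame, model = skin_model()) {
  ch <- rgb_to_cbcr(frame)
  dx <- ch$cb - model$cx
  dy <- ch$cr - model$cy
  xr <- cos(model$theta) * dx + sin(model$theta) * dy
  yr <- -sin(model$theta) * dx + cos(model$theta) * dy
  inside <- (xr / model$a)^2 + (yr / model$b)^2 <= 1
  region_mask(inside, "skin")
}

#' Morphological opening of a skin mask
#'
#' Erosion followed by dilation with a disk structuring element removes
#' speckle and thin bridges smaller than the disk, keeping the large skin
#' region intact.
#'
#' @param rm a [region_mask()].
#' @param radius_px disk radius in pixels (>= 1). The default pipeline scales
#'   5 px at 1280-wide frames proportionally with frame width.
#' @return A [region_mask()] at stage \code{"opened"}.
#' @export
open_mask <- function(rm, radius_px = 5) {
  stopifnot(radius_px >= 1)
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1, shape = "disc")
  opened <- EBImage::opening(rm$mask * 1, brush)
  region_mask(as.matrix(opened) > 0.5, "opened")
}

#' Select the abdominal component
#'
#' Labels the opened mask with 8-connectivity; components whose bounding-box
#' width/height ratio exceeds 1 are abdominal candidates (a supine abdomen is
#' wider than tall in the study framing), and the largest-area candidate is
#' returned. If nothing qualifies an empty-flagged mask is returned and the
#' frame is skipped downstream.
#'
#' @param rm a [region_mask()] at stage \code{"opened"}.
#' @return A [region_mask()] at stage \code{"selected"}; attribute
#'   \code{"empty"} is TRUE when no candidate qualified.
#' @export
select_abdomen <- function(rm) {
  lab <- .cpp_label8(rm$mask)
  ncomp <- max(lab)
  if (ncomp == 0) {
    out <- region_mask(rm$mask & FALSE, "selected")
    attr(out, "empty") <- TRUE
    return(out)
  }
  best <- 0L; best_area <- -1
  for (k in seq_len(ncomp)) {
    comp <- lab == k
    rows <- range(which(rowSums(comp) > 0))
    cols <- range(which(colSums(comp) > 0))
    width <- cols[2] - cols[1] + 1
    height <- rows[2] - rows[1] + 1
    if (width / height > 1) {
      area <- sum(comp)
      if (area > best_area) { best <- k; best_area <- area }
    }
  }
  if (best == 0L) {
    out <- region_mask(rm$mask & FALSE, "selected")
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- region_mask(lab == best, "selected")
  attr(out, "empty") <- FALSE
  out
}

#' Per-frame abdominal masks for a frame sequence
#'
#' Runs skin segmentation, opening and component selection on every frame.
#' With \code{lock = TRUE} the mask of the first frame is detected once and
#' reused (cheaper; valid while the subject lies still).
#'
#' @param seq a [frame_sequence()].
#' @param model a [skin_model()].
#' @param radius_px opening radius; \code{NULL} scales 5 px at width 1280.
#' @param lock reuse the first frame's mask.
#' @return List of stage-\code{"selected"} [region_mask()]s, one per frame.
#' @export
detect_abdomen <- function(seq, model = skin_model(), radius_px = NULL,
                           lock = FALSE) {
  w <- dim(seq$frames[[1]])[2]
  if (is.null(radius_px)) radius_px <- max(1L, as.integer(round(5 * w / 1280)))
  one <- function(frame)
    select_abdomen(open_mask(skin_mask(frame, model), radius_px))
  if (lock) {
    m <- one(seq$frames[[1]])
    rep(list(m), length(seq$frames))
  } else {
    lapply(seq$frames, one)
  }
}
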