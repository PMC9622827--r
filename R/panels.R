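# Panel segmentation: split a multi-panel figure into constituent panel
# bounding boxes. This is a deterministic projection/connected-component
# heuristic with the same interface as a learned panel detector, so a
# trained model can be swapped in without touching the rest of the
# pipeline. It assumes panels are darker regions on a light page background
# (the common case for scientific figures); set `dark_background = TRUE`
# for inverted material.

#' Segment a figure into panel bounding boxes
#'
#' Foreground is binarized as pixels darker than the background intensity
#' (estimated as the `gutter_quantile` quantile of the image, minus a small
#' slack for background noise), small gaps are closed morphologically,
#' connected components become candidate boxes, boxes separated by less than
#' 4 px are merged, and boxes smaller than `min_panel_px` per side are
#' dropped.
#'
#' @param image numeric matrix or rows x cols x 3 array in `[0, 255]`.
#' @param min_panel_px minimum box side, px.
#' @param gutter_quantile intensity quantile used as the background
#'   (gutter) estimate.
#' @param dark_background set to `TRUE` for light-on-dark figures.
#' @return box table (see [boxes()]), pairwise non-overlapping, sorted
#'   row-major by `(r0, c0)`. May be empty.
#' @export
segment_panels <- function(image, min_panel_px = 32L,
                           gutter_quantile = 0.98,
                           dark_background = FALSE) {
  assert_image(image)
  g <- as_gray(image)
  if (dark_background) g <- 255 - g
  bg <- quantile(g, gutter_quantile, names = FALSE)
  fg <- g < (bg - 10)
  if (!any(fg)) return(empty_boxes())
  fgc <- EBImage::closing(fg, EBImage::makeBrush(3L, "box")) > 0
  lab <- EBImage::bwlabel(fgc)
  b <- label_bounding_boxes(lab)
  b <- merge_close_boxes(b, gap = 4L)
  keep <- (b$r1 - b$r0) >= min_panel_px & (b$c1 - b$c0) >= min_panel_px
  b <- b[keep, , drop = FALSE]
  b <- b[order(b$r0, b$c0), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# 0-based bounding boxes of the positive labels in a label matrix.
label_bounding_boxes <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(empty_boxes())
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab)
  c <- (idx - 1L) %/% nrow(lab)
  boxes(r0 = tapply(r, l, min), c0 = tapply(c, l, min),
        r1 = tapply(r, l, max) + 1L, c1 = tapply(c, l, max) + 1L)
}

# Iteratively union boxes whose separation is below `gap` px (overlapping
# boxes have negative separation and are always merged), until a fixpoint:
# the result is pairwise non-overlapping.
merge_close_boxes <- function(b, gap = 4L) {
  repeat {
    n <- nrow(b)
    if (n <= 1L) return(b)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dr <- max(b$r0[i], b$r0[j]) - min(b$r1[i], b$r1[j])
        dc <- max(b$c0[i], b$c0[j]) - min(b$c1[i], b$c1[j])
        if (max(dr, dc) < gap) {
          b$r0[i] <- min(b$r0[i], b$r0[j]); b$c0[i] <- min(b$c0[i], b$c0[j])
          b$r1[i] <- max(b$r1[i], b$r1[j]); b$c1[i] <- max(b$c1[i], b$c1[j])
          b <- b[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(b)
  }
}

#' Rasterize boxes into a binary mask
#'
#' @param b box table (see [boxes()]).
#' @param rows,cols mask dimensions.
#' @return logical matrix, true exactly on the union of the boxes.
#' @export
boxes_to_mask <- function(b, rows, cols) {
  b <- validate_boxes(b, rows, cols)
  m <- matrix(FALSE, rows, cols)
  for (i in seq_len(nrow(b)))
    m[(b$r0[i] + 1L):b$r1[i], (b$c0[i] + 1L):b$c1[i]] <- TRUE
  m
}

#' Crop panels out of a figure
#'
#' @param image source image.
#' @param b box table; each box yields one cropped image.
#' @return list of images, in box order.
#' @export
crop_panels <- function(image, b) {
  assert_image(image)
  d <- img_dims(image)
  b <- validate_boxes(b, d[1], d[2])
  lapply(seq_len(nrow(b)), function(i) {
    ri <- (b$r0[i] + 1L):b$r1[i]
    ci <- (b$c0[i] + 1L):b$c1[i]
    if (img_channels(image) == 1L) image[ri, ci, drop = FALSE]
    else image[ri, ci, , drop = FALSE]
  })
}
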