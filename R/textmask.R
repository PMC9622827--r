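# Text localization and removal. Overlaid labels are a notorious source of
# false copy-move and keypoint matches (identical lettering recurs across
# panels), so text is erased before feature extraction and keypoints inside
# text boxes are discarded.
#
# The default backend is a self-contained glyph heuristic; a real OCR
# engine can be plugged in through `options(scifig.ocr = function(image)
# <box table>)` and selected with `backend = "ocr"`.

#' Detect likely text regions
#'
#' The `"heuristic"` backend binarizes high-contrast pixels (deviation from
#' the image median above `contrast`), keeps glyph-sized connected
#' components (height 4-32 px, width at most `max_glyph_aspect` times the
#' height), and groups horizontally adjacent glyphs into line boxes; lines
#' with fewer than `min_glyphs` components are discarded, which keeps
#' blot bands and round cells from masquerading as lettering. The `"ocr"`
#' backend delegates to the function registered in `options(scifig.ocr=)`
#' and returns its word boxes.
#'
#' @param image numeric matrix or rows x cols x 3 array in `[0, 255]`.
#' @param backend `"heuristic"` (default) or `"ocr"`.
#' @param contrast minimum absolute deviation from the image median for a
#'   pixel to count as glyph ink.
#' @param max_glyph_aspect maximum width/height ratio of a single glyph
#'   component.
#' @param min_glyphs minimum number of glyphs for a line to be reported.
#' @return box table of suspected text lines.
#' @export
detect_text_regions <- function(image, backend = c("heuristic", "ocr"),
                                contrast = 80, max_glyph_aspect = 2,
                                min_glyphs = 3L) {
  assert_image(image)
  backend <- match.arg(backend)
  if (backend == "ocr") {
    engine <- getOption("scifig.ocr", NULL)
    if (!is.function(engine))
      stop("no OCR engine registered: set options(scifig.ocr = <function>) ",
           "or use backend = \"heuristic\"", call. = FALSE)
    d <- img_dims(image)
    return(validate_boxes(engine(image), d[1], d[2]))
  }
  g <- as_gray(image)
  ink <- abs(g - median(g)) > contrast
  if (!any(ink)) return(empty_boxes())
  lab <- EBImage::bwlabel(ink)
  glyphs <- label_bounding_boxes(lab)
  counts <- tabulate(lab[lab > 0])
  h <- glyphs$r1 - glyphs$r0
  w <- glyphs$c1 - glyphs$c0
  keep <- h >= 4L & h <= 32L & w <= max_glyph_aspect * h &
    counts[seq_len(nrow(glyphs))] >= 4L
  glyphs <- glyphs[keep, , drop = FALSE]
  if (!nrow(glyphs)) return(empty_boxes())
  grp <- group_glyph_lines(glyphs, gap = 6L)
  lines <- do.call(rbind, lapply(split(glyphs, grp), function(b) {
    data.frame(r0 = min(b$r0), c0 = min(b$c0), r1 = max(b$r1),
               c1 = max(b$c1), n = nrow(b))
  }))
  lines <- lines[lines$n >= min_glyphs, , drop = FALSE]
  if (!nrow(lines)) return(empty_boxes())
  b <- boxes(lines$r0, lines$c0, lines$r1, lines$c1)
  b <- b[order(b$r0, b$c0), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# Cluster glyph boxes into text lines: glyphs join a line when their
# vertical ranges overlap and the horizontal gap is below `gap` px.
# Returns an integer group id per glyph (single-linkage components).
group_glyph_lines <- function(glyphs, gap = 6L) {
  n <- nrow(glyphs)
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      voverlap <- min(glyphs$r1[i], glyphs$r1[j]) -
        max(glyphs$r0[i], glyphs$r0[j])
      hgap <- max(glyphs$c0[i], glyphs$c0[j]) -
        min(glyphs$c1[i], glyphs$c1[j])
      if (voverlap > 0L && hgap <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) grp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Erase regions of an image
#'
#' Pixels inside the given boxes are replaced by the image's median
#' intensity (per channel) or by white; pixels outside are untouched.
#'
#' @param image numeric matrix or rows x cols x 3 array in `[0, 255]`.
#' @param b box table of regions to erase.
#' @param fill `"median"` (default) or `"white"`.
#' @return image of the same shape.
#' @export
erase_regions <- function(image, b, fill = c("median", "white")) {
  assert_image(image)
  fill <- match.arg(fill)
  d <- img_dims(image)
  b <- validate_boxes(b, d[1], d[2])
  if (!nrow(b)) return(image)
  nch <- img_channels(image)
  fillv <- if (fill == "white") rep(255, nch)
  else if (nch == 1L) median(image)
  else vapply(1:3, function(k) median(image[, , k]), numeric(1))
  out <- image
  for (i in seq_len(nrow(b))) {
    ri <- (b$r0[i] + 1L):b$r1[i]
    ci <- (b$c0[i] + 1L):b$c1[i]
    if (nch == 1L) out[ri, ci] <- fillv
    else for (k in 1:3) out[ri, ci, k] <- fillv[k]
  }
  out
}
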