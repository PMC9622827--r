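# Core domain types and shared helpers.
#
# Conventions used throughout the package:
#   * images are plain numeric arrays with values in [0, 255]: a rows x cols
#     matrix for grayscale, a rows x cols x 3 array for RGB;
#   * masks are logical rows x cols matrices;
#   * all externally visible pixel coordinates are 0-based, row-major,
#     half-open intervals [r0, r1) x [c0, c1) (internal R code converts to
#     1-based indexing at the point of use).

img_dims <- function(img) dim(img)[1:2]

img_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3] else 1L

assert_image <- function(img, arg = "image") {
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop(arg, " must be a rows x cols matrix or rows x cols x 3 array",
         call. = FALSE)
  if (d[1] < 1L || d[2] < 1L)
    stop(arg, " has zero area", call. = FALSE)
  if (length(d) == 3L && d[3] != 3L)
    stop(arg, " must have 1 or 3 channels, got ", d[3], call. = FALSE)
  invisible(img)
}

#' Convert an image to single-channel luma
#'
#' RGB images are reduced with the Rec. 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale images pass through unchanged.
#'
#' @param img numeric matrix or rows x cols x 3 array, intensities in
#'   `[0, 255]`.
#' @return numeric matrix of the same rows x cols.
#' @export
as_gray <- function(img) {
  assert_image(img)
  if (img_channels(img) == 1L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

as_rgb <- function(img) {
  assert_image(img)
  if (img_channels(img) == 3L) return(img)
  array(img, dim = c(dim(img), 3L))
}

clamp8 <- function(x) pmin(pmax(round(x), 0), 255)

#' Construct a table of panel/text bounding boxes
#'
#' Boxes are 0-based, half-open pixel intervals `[r0, r1) x [c0, c1)`, stored
#' one per row of a data frame. This is the coordinate convention used by
#' every function in the package and by the JSON interchange format.
#'
#' @param r0,c0,r1,c1 integer vectors (recycled to a common length).
#' @return data frame with integer columns `r0`, `c0`, `r1`, `c1`.
#' @export
boxes <- function(r0 = integer(), c0 = integer(), r1 = integer(),
                  c1 = integer()) {
  b <- data.frame(r0 = as.integer(r0), c0 = as.integer(c0),
                  r1 = as.integer(r1), c1 = as.integer(c1))
  if (nrow(b) && any(b$r0 >= b$r1 | b$c0 >= b$c1))
    stop("degenerate box: need r0 < r1 and c0 < c1", call. = FALSE)
  if (nrow(b) && any(b$r0 < 0L | b$c0 < 0L))
    stop("box coordinates must be non-negative", call. = FALSE)
  b
}

empty_boxes <- function() boxes()

validate_boxes <- function(b, rows, cols) {
  b <- boxes(b$r0, b$c0, b$r1, b$c1)
  if (nrow(b) && any(b$r1 > rows | b$c1 > cols))
    stop("box exceeds image bounds (", rows, " x ", cols, ")", call. = FALSE)
  b
}

#' Parse a publication date
#'
#' Accepts ISO-8601 `YYYY-MM-DD` dates and bare years (compared as
#' `YYYY-01-01`). `NULL`, `NA` and empty strings give `NA`: figures without a
#' date are exempt from the provenance date constraint.
#'
#' @param x character scalar, `Date`, or `NULL`.
#' @return a `Date` (possibly `NA`).
#' @export
parse_pub_date <- function(x) {
  if (is.null(x) || length(x) == 0L) return(as.Date(NA))
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  if (is.na(x) || !nzchar(x)) return(as.Date(NA))
  if (grepl("^[0-9]{4}$", x)) x <- paste0(x, "-01-01")
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d)) stop("unparseable date: '", x, "' (expect YYYY[-MM-DD])",
                     call. = FALSE)
  d
}

#' Bundle a figure with its provenance metadata
#'
#' A figure record ties a raster image to the identifiers the provenance
#' stage needs: a case-unique id, the DOI of the paper it appeared in, the
#' paper's publication date, and (optionally) known panel and text-region
#' boxes.
#'
#' @param id character scalar, unique within a case.
#' @param image numeric matrix or rows x cols x 3 array in `[0, 255]`.
#' @param doi character scalar (may be empty).
#' @param date publication date, see [parse_pub_date()].
#' @param panels,text_regions box tables as produced by [boxes()].
#' @return an object of class `figure_record`.
#' @export
figure_record <- function(id, image, doi = "", date = NULL,
                          panels = empty_boxes(),
                          text_regions = empty_boxes()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  assert_image(image)
  d <- img_dims(image)
  structure(
    list(id = id, image = image, doi = doi, date = parse_pub_date(date),
         panels = validate_boxes(panels, d[1], d[2]),
         text_regions = validate_boxes(text_regions, d[1], d[2])),
    class = "figure_record")
}

#' @export
print.figure_record <- function(x, ...) {
  d <- img_dims(x$image)
  cat(sprintf("<figure_record '%s': %d x %d x %d, doi='%s', date=%s, %d panel(s), %d text box(es)>\n",
              x$id, d[1], d[2], img_channels(x$image), x$doi,
              ifelse(is.na(x$date), "NA", format(x$date)),
              nrow(x$panels), nrow(x$text_regions)))
  invisible(x)
}

#' Configuration of the copy-move detector
#'
#' All tunable parameters of the dense-field copy-move pipeline in one
#' validated object. Sizes are in pixels.
#'
#' @param zernike_order maximum Zernike order of the moment branch.
#' @param zernike_radius_px radius of the circular patch for Zernike moments.
#' @param rgb_patch_px side of the square patch for the raw-RGB branch
#'   (even).
#' @param pm_iterations propagation/random-search sweeps of the
#'   nearest-neighbor-field search.
#' @param min_offset_px minimum admissible offset length; suppresses trivial
#'   near-self matches.
#' @param bidir_tol_px tolerance (Chebyshev norm, pixels) of the
#'   bidirectional match check.
#' @param median_window_px half-width of the offset median filter and of the
#'   local affine-fit neighborhood.
#' @param dlf_error_thresh maximum squared residual (px^2) of a pixel's
#'   offset against the local affine fit before it is discarded.
#' @param min_region_px minimum connected-region area kept in the final
#'   mask.
#' @param dilation_radius_px radius of the final morphological dilation.
#' @param min_patch_sd texture gate: pixels whose local standard
#'   deviation over the patch support (luma for the Zernike branch,
#'   best channel for the RGB branch) is below this are excluded from
#'   matching (exactly uniform regions match anything at zero cost).
#' @param max_cost_frac noise-floor rejection: after the bidirectional
#'   check, a pixel is kept only if its match cost is at most this
#'   fraction of the field's median match cost. Cloned content carries
#'   identical pixel noise and matches near cost zero, while unrelated
#'   flat or weakly textured regions match no better than the noise
#'   floor, so this separates true clones from background coincidences.
#' @param fusion how the Zernike and RGB branch masks are combined:
#'   `"or"` (union, the default) or `"and"` (intersection).
#' @param seed integer seed for the randomized search.
#' @return an object of class `copymove_config`.
#' @export
copymove_config <- function(zernike_order = 5L, zernike_radius_px = 8L,
                            rgb_patch_px = 8L, pm_iterations = 8L,
                            min_offset_px = 16L, bidir_tol_px = 2L,
                            median_window_px = 7L, dlf_error_thresh = 4.0,
                            min_region_px = 50L, dilation_radius_px = 3L,
                            min_patch_sd = 2.5, max_cost_frac = 0.25,
                            fusion = c("or", "and"), seed = 0L) {
  cfg <- list(zernike_order = as.integer(zernike_order),
              zernike_radius_px = as.integer(zernike_radius_px),
              rgb_patch_px = as.integer(rgb_patch_px),
              pm_iterations = as.integer(pm_iterations),
              min_offset_px = as.integer(min_offset_px),
              bidir_tol_px = as.integer(bidir_tol_px),
              median_window_px = as.integer(median_window_px),
              dlf_error_thresh = as.numeric(dlf_error_thresh),
              min_region_px = as.integer(min_region_px),
              dilation_radius_px = as.integer(dilation_radius_px),
              min_patch_sd = as.numeric(min_patch_sd),
              max_cost_frac = as.numeric(max_cost_frac),
              fusion = match.arg(fusion),
              seed = as.integer(seed))
  sizes <- c("zernike_order", "zernike_radius_px", "rgb_patch_px",
             "pm_iterations", "min_offset_px", "median_window_px",
             "min_region_px", "dilation_radius_px")
  for (s in sizes)
    if (cfg[[s]] <= 0L) stop(s, " must be positive", call. = FALSE)
  if (cfg$bidir_tol_px < 0L) stop("bidir_tol_px must be >= 0", call. = FALSE)
  if (cfg$min_offset_px <= cfg$bidir_tol_px)
    stop("min_offset_px must exceed bidir_tol_px", call. = FALSE)
  if (cfg$rgb_patch_px %% 2L != 0L)
    stop("rgb_patch_px must be even", call. = FALSE)
  structure(cfg, class = "copymove_config")
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
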