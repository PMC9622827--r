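# Raster and mask I/O. PNG, TIFF and JPEG are read through the standard
# readers; everything is normalized to the package's 8-bit convention.

read_raster_array <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png  = png::readPNG(path),
           tif  = ,
           tiff = tiff::readTIFF(path),
           jpg  = ,
           jpeg = jpeg::readJPEG(path),
           stop("unsupported raster format '.", ext, "'", call. = FALSE)),
    error = function(e)
      stop("cannot read image ", path, ": ", conditionMessage(e),
           call. = FALSE))
  arr
}

#' Load a raster figure as an 8-bit image
#'
#' Reads a PNG, TIFF or JPEG file and normalizes it to the package's internal
#' representation: intensities in `[0, 255]`, a matrix for grayscale or a
#' rows x cols x 3 array for color. Alpha channels are dropped, palette
#' images are expanded to RGB by the reader, and high-bit-depth inputs are
#' rescaled to 8 bits by a linear min-max stretch.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return numeric matrix or rows x cols x 3 array with values in
#'   `{0, ..., 255}`.
#' @export
load_image <- function(path) {
  arr <- read_raster_array(path)
  d <- dim(arr)
  if (is.null(d)) d <- c(length(arr), 1L)
  if (d[1] < 1L || d[2] < 1L)
    stop("zero-area image: ", path, call. = FALSE)
  # drop alpha: gray+alpha (2 channels) or RGBA (4 channels)
  if (length(d) == 3L) {
    if (d[3] == 2L) arr <- arr[, , 1]
    if (d[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
    if (!is.null(dim(arr)) && length(dim(arr)) == 3L && dim(arr)[3] == 1L)
      arr <- arr[, , 1]
  }
  x <- arr * 255
  if (max(abs(x - round(x))) > 1e-6) {
    # finer than 8-bit quantization: linear min-max stretch to [0, 255]
    lo <- min(arr); hi <- max(arr)
    x <- if (hi > lo) (arr - lo) / (hi - lo) * 255 else arr * 0
  }
  out <- round(x)
  assert_image(out)
  out
}

#' Write a binary mask as a 0/255 PNG
#'
#' True pixels are written as 255, false as 0, in a single-channel 8-bit
#' PNG; [load_mask()] reproduces the mask exactly.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
save_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ok <- tryCatch({png::writePNG(img, target = path); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write mask ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(NULL)
}

#' Read a 0/255 PNG mask
#'
#' @param path path to a mask PNG written by [save_mask()] (any pixel above
#'   127 counts as true).
#' @return logical matrix.
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  as_gray(img) > 127
}

#' Write an 8-bit image to PNG
#'
#' @param img numeric matrix or rows x cols x 3 array in `[0, 255]`.
#' @param path output path.
#' @export
save_image <- function(img, path) {
  assert_image(img)
  png::writePNG(clamp8(img) / 255, target = path)
  invisible(NULL)
}
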