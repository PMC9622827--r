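# Mirror-aware keypoint detection and description. The detector is a
# determinant-of-Hessian blob/corner detector over a small Gaussian scale
# stack with "top-N by response" selection; descriptors are upright
# SIFT-style gradient histograms turned into RootSIFT vectors. Because the
# descriptor is not mirror-invariant, every figure is additionally
# described on its horizontally mirrored version; mirrored keypoints carry
# coordinates in the mirrored frame and are flagged.

# Detector scale stack: 2^(1/3) spacing keeps descriptors usable across
# the moderate rescaling (roughly 0.8-1.2x) typical of figure reuse.
default_sigmas <- function() 1.6 * 2^((0:7) / 3)

shift_mat <- function(m, dr, dc) {
  rows <- nrow(m); cols <- ncol(m)
  out <- matrix(-Inf, rows, cols)
  rs <- max(1, 1 + dr):min(rows, rows + dr)
  cs <- max(1, 1 + dc):min(cols, cols + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Determinant-of-Hessian response stack and per-scale smoothed images.
# Scales whose Gaussian support exceeds the image are dropped.
hessian_stack <- function(gray01, sigmas) {
  rows <- nrow(gray01); cols <- ncol(gray01)
  sigmas <- sigmas[2 * ceiling(3 * sigmas) + 1 <= min(rows, cols)]
  if (!length(sigmas)) return(list(resp = NULL, smoothed = list(),
                                   sigmas = sigmas))
  smoothed <- lapply(sigmas, function(s) EBImage::gblur(gray01, sigma = s))
  resp <- array(-Inf, c(rows, cols, length(sigmas)))
  for (k in seq_along(sigmas)) {
    L <- smoothed[[k]]
    i <- 2:(rows - 1); j <- 2:(cols - 1)
    Lrr <- Lcc <- Lrc <- matrix(0, rows, cols)
    Lrr[i, ] <- L[i - 1, ] - 2 * L[i, ] + L[i + 1, ]
    Lcc[, j] <- L[, j - 1] - 2 * L[, j] + L[, j + 1]
    Lrc[i, j] <- (L[i + 1, j + 1] + L[i - 1, j - 1] -
                    L[i + 1, j - 1] - L[i - 1, j + 1]) / 4
    resp[, , k] <- sigmas[k]^4 * (Lrr * Lcc - Lrc^2)
    resp[c(1, rows), , k] <- -Inf
    resp[, c(1, cols), k] <- -Inf
  }
  list(resp = resp, smoothed = smoothed, sigmas = sigmas)
}

#' Detect interest points by Hessian response
#'
#' Scale-space local maxima of the scale-normalized determinant of the
#' Hessian, sorted by descending response (ties broken by scale, row,
#' column, so selection is deterministic).
#'
#' @param image image in `[0, 255]`; color is reduced to luma.
#' @param n_points keep at most this many strongest points.
#' @param sigmas Gaussian scales of the detector stack.
#' @param threshold minimum normalized response.
#' @return data frame with 0-based `row`, `col`, the detection `scale`
#'   (sigma, px) and `response`, plus the internal `scale_idx`.
#' @export
detect_keypoints <- function(image, n_points = 500L,
                             sigmas = default_sigmas(),
                             threshold = 1e-6) {
  g <- as_gray(image) / 255
  hs <- hessian_stack(g, sigmas)
  resp <- hs$resp
  sigmas <- hs$sigmas
  S <- length(sigmas)
  if (!S) {
    out <- data.frame(row = numeric(), col = numeric(), scale = numeric(),
                      response = numeric(), scale_idx = integer())
    attr(out, "smoothed") <- list()
    return(out)
  }
  nbr_max <- array(-Inf, dim(resp))
  for (k in 1:S) {
    m <- resp[, , k]
    best <- matrix(-Inf, nrow(m), ncol(m))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      best <- pmax(best, shift_mat(m, dr, dc))
    }
    if (k > 1) best <- pmax(best, resp[, , k - 1])
    if (k < S) best <- pmax(best, resp[, , k + 1])
    nbr_max[, , k] <- best
  }
  is_max <- resp > nbr_max & resp > threshold
  idx <- which(is_max)
  if (!length(idx)) {
    return(data.frame(row = numeric(), col = numeric(), scale = numeric(),
                      response = numeric(), scale_idx = integer()))
  }
  rows <- dim(resp)[1]; cols <- dim(resp)[2]
  r <- (idx - 1L) %% rows
  csi <- (idx - 1L) %/% rows
  c <- csi %% cols
  k <- csi %/% cols + 1L
  kp <- data.frame(row = as.numeric(r), col = as.numeric(c),
                   scale = sigmas[k], response = resp[idx],
                   scale_idx = as.integer(k))
  kp <- kp[order(-kp$response, kp$scale, kp$row, kp$col), , drop = FALSE]
  kp <- utils::head(kp, n_points)
  rownames(kp) <- NULL
  attr(kp, "smoothed") <- hs$smoothed
  kp
}

#' RootSIFT transform
#'
#' L1-normalizes a non-negative descriptor and takes the element-wise
#' square root, so that Euclidean distance between the results emulates
#' the Hellinger kernel on the originals. The output has unit Euclidean
#' norm; an all-zero input stays all-zero.
#'
#' @param raw numeric vector of non-negative values, or a matrix with one
#'   descriptor per row.
#' @return vector or matrix of the same shape.
#' @export
root_sift <- function(raw) {
  if (any(raw < 0)) stop("RootSIFT input must be non-negative", call. = FALSE)
  if (is.matrix(raw)) {
    s <- rowSums(raw)
    s[s == 0] <- 1
    return(sqrt(raw / s))
  }
  s <- sum(raw)
  if (s == 0) return(raw)
  sqrt(raw / s)
}

kp_in_boxes <- function(kp, b) {
  if (!nrow(b) || !nrow(kp)) return(rep(FALSE, nrow(kp)))
  inside <- rep(FALSE, nrow(kp))
  for (i in seq_len(nrow(b))) {
    inside <- inside | (kp$row >= b$r0[i] & kp$row < b$r1[i] &
                          kp$col >= b$c0[i] & kp$col < b$c1[i])
  }
  inside
}

mirror_boxes <- function(b, cols) {
  if (!nrow(b)) return(b)
  boxes(r0 = b$r0, c0 = cols - b$c1, r1 = b$r1, c1 = cols - b$c0)
}

describe_one_side <- function(image, text_regions, n_points, mirrored) {
  g <- as_gray(image)
  if (mirrored) {
    g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
    text_regions <- mirror_boxes(text_regions, ncol(g))
  }
  kp <- detect_keypoints(g, n_points = .Machine$integer.max)
  smoothed <- attr(kp, "smoothed")
  kp <- kp[!kp_in_boxes(kp, text_regions), , drop = FALSE]
  kp <- utils::head(kp, n_points)
  if (!nrow(kp)) {
    return(list(keypoints = data.frame(row = numeric(), col = numeric(),
                                       scale = numeric(),
                                       response = numeric(),
                                       mirrored = logical()),
                descriptors = matrix(0, 0L, 128L)))
  }
  desc <- sift_descriptors(smoothed,
                           cbind(kp$row, kp$col, kp$scale_idx, kp$scale))
  desc <- root_sift(desc)
  list(keypoints = data.frame(row = kp$row, col = kp$col, scale = kp$scale,
                              response = kp$response, mirrored = mirrored),
       descriptors = desc)
}

#' Describe a figure with mirror-augmented RootSIFT keypoints
#'
#' Detects up to `n_points` interest points on the figure and up to
#' `n_points` more on its horizontally mirrored version (flagged
#' `mirrored = TRUE`, with coordinates in the mirrored frame), each set
#' selected by descending detector response. Keypoints falling inside the
#' record's `text_regions` are discarded before selection, so overlaid
#' labels cannot generate matches.
#'
#' @param figure a [figure_record()] (image at least 32 px per side).
#' @param n_points per-side keypoint budget.
#' @return list with `keypoints` (data frame: `row`, `col`, `scale`,
#'   `response`, `mirrored`) and `descriptors` (matrix, one unit-norm
#'   RootSIFT row per keypoint).
#' @export
describe_figure <- function(figure, n_points = 500L) {
  stopifnot(inherits(figure, "figure_record"))
  if (min(img_dims(figure$image)) < 32L)
    stop("figure too small to describe (need >= 32 px per side)",
         call. = FALSE)
  plain <- describe_one_side(figure$image, figure$text_regions, n_points,
                             mirrored = FALSE)
  mirr <- describe_one_side(figure$image, figure$text_regions, n_points,
                            mirrored = TRUE)
  list(keypoints = rbind(plain$keypoints, mirr$keypoints),
       descriptors = rbind(plain$descriptors, mirr$descriptors))
}
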