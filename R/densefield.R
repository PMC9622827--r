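# Dense per-pixel feature fields for the copy-move detector. Two branches:
# rotation/mirror-invariant Zernike moment magnitudes on luma, and raw RGB
# patch values. A field carries a validity mask: pixels whose patch support
# leaves the image (or the caller-supplied support region), or whose local
# texture is too flat to match meaningfully, are excluded from the search.

dense_field <- function(features, valid) {
  stopifnot(length(dim(features)) == 3L, is.logical(valid),
            all(dim(valid) == dim(features)[1:2]))
  structure(list(features = features, valid = valid, d = dim(features)[3]),
            class = "dense_field")
}

#' @export
print.dense_field <- function(x, ...) {
  cat(sprintf("<dense_field %d x %d, d=%d, %d valid px>\n",
              nrow(x$valid), ncol(x$valid), x$d, sum(x$valid)))
  invisible(x)
}

# Indices (n, m) of the Zernike basis up to `order`: m >= 0, n - m even.
# order 5 gives the 12 moments used by the default detector.
zernike_indices <- function(order) {
  idx <- expand.grid(m = 0:order, n = 0:order)
  idx <- idx[idx$n >= idx$m & (idx$n - idx$m) %% 2L == 0L, c("n", "m")]
  idx[order(idx$n, idx$m), ]
}

# Complex Zernike polynomial V_{n,m} sampled on the (2r+1)^2 grid; zero
# outside the unit disk rho <= 1. theta measured from the column axis.
zernike_poly_kernel <- function(n, m, radius) {
  off <- -radius:radius
  di <- matrix(off, 2 * radius + 1, 2 * radius + 1)
  dj <- t(di)
  rho <- sqrt(di^2 + dj^2) / radius
  theta <- atan2(di, dj)
  R <- matrix(0, nrow(rho), ncol(rho))
  for (k in 0:((n - m) / 2)) {
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) *
         factorial((n - m) / 2 - k))
    R <- R + coef * rho^(n - 2 * k)
  }
  V <- R * exp(1i * m * theta)
  V[rho > 1] <- 0
  V
}

# Cross-correlation via FFT: out[p] = sum_q K[q] * g[p + q], q in
# [-r, r]^2, with circular wraparound (only the r-wide border is affected,
# which the validity margin excludes anyway). K may be complex.
xcorr_fft <- function(g, K) {
  P <- nrow(g); Q <- ncol(g)
  r <- (nrow(K) - 1L) %/% 2L
  kp <- matrix(0 + 0i, P, Q)
  off <- -r:r
  ii <- ((-off) %% P) + 1L
  jj <- ((-off) %% Q) + 1L
  kp[ii, jj] <- K
  stats::fft(stats::fft(g) * stats::fft(kp), inverse = TRUE) / (P * Q)
}

# Local mean and sd of g over the disk of the given radius (FFT-based).
disk_stats <- function(g, radius) {
  D <- zernike_poly_kernel(0, 0, radius)  # indicator of the disk
  D <- Re(D)
  N <- sum(D)
  mu <- Re(xcorr_fft(g, D)) / N
  m2 <- Re(xcorr_fft(g^2, D)) / N
  list(mu = mu, sd = sqrt(pmax(m2 - mu^2, 0)), n = N)
}

#' Dense Zernike moment magnitudes
#'
#' Computes, for every pixel, the magnitudes of the Zernike moments of the
#' circular patch of the given radius centered there, on the luma of the
#' image. The moment for index `(n, m)` is
#' `Z_nm(p) = (1/N) * sum_q conj(V_nm(q)) * x(p + q)` over the `N` grid
#' points of the disk, where `x` is the raw patch for `(0, 0)` and the
#' patch minus its disk mean for all higher indices (so a constant patch
#' has exactly one nonzero feature). Magnitudes are invariant under patch
#' rotation and mirroring, which is what lets this branch catch mirrored
#' clones.
#'
#' @param image numeric matrix or rows x cols x 3 array in `[0, 255]`
#'   (color is reduced to luma).
#' @param radius_px patch radius, `>= 4`.
#' @param order maximum Zernike order, `<= 8` (order 5 gives d = 12).
#' @param min_patch_sd texture gate; see [copymove_config()].
#' @param support optional logical matrix: pixels whose disk support is not
#'   entirely inside `support` are invalid.
#' @return a `dense_field` with `d = length(zernike index set)` features.
#' @export
zernike_field <- function(image, radius_px = 8L, order = 5L,
                          min_patch_sd = 0, support = NULL) {
  assert_image(image)
  if (radius_px < 4L) stop("radius_px must be >= 4", call. = FALSE)
  if (order > 8L) stop("order must be <= 8", call. = FALSE)
  g <- as_gray(image)
  rows <- nrow(g); cols <- ncol(g)
  if (rows < 2L * radius_px + 1L || cols < 2L * radius_px + 1L)
    stop("image smaller than the 2*radius+1 patch support", call. = FALSE)
  idx <- zernike_indices(order)
  st <- disk_stats(g, radius_px)
  feats <- array(0, c(rows, cols, nrow(idx)))
  for (k in seq_len(nrow(idx))) {
    n <- idx$n[k]; m <- idx$m[k]
    K <- Conj(zernike_poly_kernel(n, m, radius_px))
    Z <- xcorr_fft(g, K) / st$n
    if (!(n == 0L && m == 0L)) Z <- Z - st$mu * (sum(K) / st$n)
    feats[, , k] <- Mod(Z)
  }
  valid <- field_valid(rows, cols, margin_lo = radius_px,
                       margin_hi = radius_px, support = support,
                       brush = 2L * radius_px + 1L)
  if (min_patch_sd > 0) valid <- valid & (st$sd >= min_patch_sd)
  dense_field(feats, valid)
}

#' Dense raw-RGB patch features
#'
#' The feature at pixel `p` is the raveled `patch_px x patch_px x 3` block
#' whose top-left corner sits at `p - patch_px/2` (row index fastest, then
#' column, then channel), in raw intensities. Grayscale input is replicated
#' to three channels. Unlike the Zernike branch this is sensitive to the
#' exact pixel values, which makes it the discriminative branch for
#' texture-rich content and for clones that differ only in chroma.
#'
#' @param image numeric matrix or rows x cols x 3 array in `[0, 255]`.
#' @param patch_px patch side, even, `>= 4`.
#' @param min_patch_sd texture gate on luma; see [copymove_config()].
#' @param support optional logical support mask as in [zernike_field()].
#' @return a `dense_field` with `d = 3 * patch_px^2` features.
#' @export
rgb_field <- function(image, patch_px = 8L, min_patch_sd = 0,
                      support = NULL) {
  assert_image(image)
  if (patch_px < 4L || patch_px %% 2L != 0L)
    stop("patch_px must be even and >= 4", call. = FALSE)
  arr <- as_rgb(image)
  rows <- dim(arr)[1]; cols <- dim(arr)[2]
  h <- patch_px %/% 2L
  if (rows < patch_px + 1L || cols < patch_px + 1L)
    stop("image smaller than the patch support", call. = FALSE)
  d <- 3L * patch_px^2
  feats <- array(0, c(rows, cols, d))
  ri <- (h + 1L):(rows - h + 1L)
  ci <- (h + 1L):(cols - h + 1L)
  k <- 0L
  for (ch in 1:3) for (dj in (-h):(h - 1L)) for (di in (-h):(h - 1L)) {
    k <- k + 1L
    feats[ri, ci, k] <- arr[ri + di, ci + dj, ch]
  }
  valid <- field_valid(rows, cols, margin_lo = h, margin_hi = h - 1L,
                       support = support, brush = patch_px + 1L)
  if (min_patch_sd > 0) {
    # per-channel texture: a chroma-only texture must stay valid even
    # when its luma is constant
    chan_sd <- lapply(1:3, function(k) disk_stats(arr[, , k], h)$sd)
    sd_max <- pmax(chan_sd[[1]], chan_sd[[2]], chan_sd[[3]])
    valid <- valid & (sd_max >= min_patch_sd)
  }
  out <- dense_field(feats, valid)
  # component permutation realizing a horizontal mirror of the patch
  # (row index fastest, then column, then channel); lets the search
  # match a patch against mirrored copies of itself
  di <- rep(0:(patch_px - 1L), times = 3L * patch_px)
  dj <- rep(rep(0:(patch_px - 1L), each = patch_px), times = 3L)
  ch <- rep(0:2, each = patch_px^2)
  out$mirror_perm <- di + patch_px * (patch_px - 1L - dj) +
    patch_px^2 * ch
  out
}

# Border margin + optional support-region erosion for field validity.
field_valid <- function(rows, cols, margin_lo, margin_hi, support, brush) {
  valid <- matrix(FALSE, rows, cols)
  valid[(margin_lo + 1L):(rows - margin_hi), (margin_lo + 1L):(cols - margin_hi)] <- TRUE
  if (!is.null(support)) {
    stopifnot(all(dim(support) == c(rows, cols)))
    eroded <- EBImage::erode(support, EBImage::makeBrush(brush, "box")) > 0
    valid <- valid & eroded
  }
  valid
}
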