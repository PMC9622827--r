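# Shared fixture builders. Everything is generated in code, seeded, and
# small enough to keep the whole suite fast.

seeded_gray <- function(seed, rows = 64, cols = 64, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(round(runif(rows * cols, lo, hi)), rows, cols)
}

seeded_rgb <- function(seed, rows = 64, cols = 64) {
  set.seed(seed)
  array(round(runif(rows * cols * 3, 0, 255)), c(rows, cols, 3))
}

# A small figure with an exactly duplicated block, for NNF convergence
# tests: block at columns 81:112 copied to columns 17:48 (offset 0, +/-64).
duplicated_block_image <- function(seed = 1, rows = 128, cols = 160) {
  img <- seeded_gray(seed, rows, cols)
  img[33:64, 17:48] <- img[33:64, 81:112]
  img
}

# Exhaustive nearest-neighbor cost under the same admissibility rule as
# the randomized search (valid targets, offset length >= min_offset).
exhaustive_nnf_cost <- function(field, min_offset) {
  v <- which(field$valid)
  rows <- nrow(field$valid)
  X <- matrix(field$features, length(field$valid), field$d)[v, , drop = FALSE]
  D2 <- as.matrix(dist(X))^2
  rr <- (v - 1) %% rows
  cc <- (v - 1) %/% rows
  adm <- outer(rr, rr, "-")^2 + outer(cc, cc, "-")^2 >= min_offset^2
  D2[!adm] <- Inf
  apply(D2, 1, min)
}

# Hand-built offset field (for filter tests that need exact control).
manual_offset_field <- function(dr, dc, valid = NULL,
                                cost = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(dr), ncol(dr))
  if (is.null(cost)) cost <- matrix(0, nrow(dr), ncol(dr))
  structure(list(dr = dr, dc = dc, cost = cost, valid = valid,
                 min_offset_px = 0L),
            class = "offset_field")
}

# Independent Zernike oracle: evaluates the double sum directly, pixel by
# pixel, with its own radial-polynomial code (the implementation computes
# the same projections by FFT correlation).
zernike_oracle_at <- function(g, pr, pc, radius, order) {
  idx <- expand.grid(m = 0:order, n = 0:order)
  idx <- idx[idx$n >= idx$m & (idx$n - idx$m) %% 2 == 0, c("n", "m")]
  idx <- idx[order(idx$n, idx$m), ]
  off <- -radius:radius
  patch <- g[pr + off, pc + off]
  D <- outer(off, off, function(di, dj) sqrt(di^2 + dj^2) / radius <= 1)
  N <- sum(D)
  mu <- sum(patch[D]) / N
  vals <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    n <- idx$n[k]; m <- idx$m[k]
    acc <- 0 + 0i
    for (a in seq_along(off)) for (b in seq_along(off)) {
      di <- off[a]; dj <- off[b]
      rho <- sqrt(di^2 + dj^2) / radius
      if (rho > 1) next
      Rnm <- 0
      for (s in 0:((n - m) / 2))
        Rnm <- Rnm + (-1)^s * factorial(n - s) /
          (factorial(s) * factorial((n + m) / 2 - s) *
             factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
      V <- Rnm * exp(1i * m * atan2(di, dj))
      x <- if (n == 0 && m == 0) patch[a, b] else patch[a, b] - mu
      acc <- acc + Conj(V) * x
    }
    vals[k] <- Mod(acc) / N
  }
  vals
}

# 48x48 phantom-panel crop used by the NNF oracle tests.
phantom_crop_48 <- function(seed) {
  panel <- if (seed %% 2) make_blot_panel(seed, 3, 2, c(64, 64))
  else make_micrograph_panel(seed, 3, c(64, 64))
  panel[9:56, 9:56]
}
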