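test_that("a planted duplicate block converges to its exact offset", {
  img <- duplicated_block_image(1)
  f <- rgb_field(img, 8)
  nnf <- patchmatch_nnf(f, iterations = 8, min_offset_px = 16, seed = 0)
  ri <- 38:59; ci <- 22:43  # interior of the copied block (patch margin)
  off_ok <- nnf$dr[ri, ci] == 0 & abs(nnf$dc[ri, ci]) == 64
  expect_true(all(off_ok))
  expect_true(all(nnf$cost[ri, ci] <= 1e-9))
})

test_that("all offsets respect the minimum-offset constraint", {
  set.seed(2)
  feats <- array(runif(32 * 32 * 6), c(32, 32, 6))
  fld <- structure(list(features = feats,
                        valid = matrix(TRUE, 32, 32), d = 6L),
                   class = "dense_field")
  nnf <- patchmatch_nnf(fld, iterations = 4, min_offset_px = 16, seed = 1)
  expect_true(all(sqrt(nnf$dr^2 + nnf$dc^2) >= 16))
})

test_that("the randomized search converges to exhaustive-search cost", {
  # run to convergence on phantom-panel fields; per-seed within 5%
  for (s in 1:4) {
    img <- phantom_crop_48(s)
    f <- if (s %% 2) rgb_field(img, 8) else zernike_field(img, 8, 5)
    nnf <- patchmatch_nnf(f, iterations = 128, min_offset_px = 16,
                          seed = s)
    exact <- exhaustive_nnf_cost(f, 16)
    ratio <- mean(nnf$cost[f$valid]) / mean(exact)
    expect_lte(ratio, 1.05)
  }
})

test_that("the search is deterministic given the seed", {
  img <- phantom_crop_48(3)
  f <- zernike_field(img, 8, 5)
  a <- patchmatch_nnf(f, iterations = 8, min_offset_px = 16, seed = 7)
  b <- patchmatch_nnf(f, iterations = 8, min_offset_px = 16, seed = 7)
  expect_identical(a, b)
  c <- patchmatch_nnf(f, iterations = 8, min_offset_px = 16, seed = 8)
  expect_false(identical(a$dr, c$dr) && identical(a$dc, c$dc))
})

test_that("absence of admissible offsets is a validation error", {
  feats <- array(runif(40 * 40 * 2), c(40, 40, 2))
  valid <- matrix(FALSE, 40, 40)
  valid[18:22, 18:22] <- TRUE  # all valid pixels within min_offset reach
  fld <- structure(list(features = feats, valid = valid, d = 2L),
                   class = "dense_field")
  expect_error(patchmatch_nnf(fld, 2, min_offset_px = 16, seed = 0),
               "no admissible offset")
  expect_error(patchmatch_nnf(fld, 2, min_offset_px = 64, seed = 0),
               "smaller than the image extent")
})
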