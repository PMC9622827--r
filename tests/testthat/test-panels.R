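test_that("a uniform white image yields no panels", {
  expect_equal(nrow(segment_panels(matrix(255, 100, 100))), 0L)
})

test_that("a single dark rectangle yields exactly one covering box", {
  img <- matrix(250, 100, 120)
  img[21:70, 31:90] <- 80
  b <- segment_panels(img)
  expect_equal(nrow(b), 1L)
  expect_true(b$r0 <= 20 && b$r1 >= 70 && b$c0 <= 30 && b$c1 >= 90)
})

test_that("a 2x2 phantom grid is recovered within 2 px per edge", {
  comp <- compose_figure(list(make_blot_panel(1, 3, 3, c(96, 120)),
                              make_micrograph_panel(2, 6, c(96, 120)),
                              make_micrograph_panel(3, 6, c(96, 120)),
                              make_blot_panel(4, 3, 3, c(96, 120))),
                         grid = c(2, 2))
  b <- segment_panels(comp$figure)
  expect_equal(nrow(b), 4L)
  expect_true(all(abs(as.matrix(b) - as.matrix(comp$panel_boxes)) <= 2))
  # non-overlap, row-major order
  m <- boxes_to_mask(b, nrow(comp$figure), ncol(comp$figure))
  expect_equal(sum(m), sum((b$r1 - b$r0) * (b$c1 - b$c0)))
  expect_true(!is.unsorted(b$r0))
})

test_that("segmenting a cropped single panel is nearly idempotent", {
  panel <- make_blot_panel(7, 4, 3, c(128, 160))
  b <- segment_panels(panel)
  if (nrow(b)) {
    expect_equal(nrow(b), 1L)
    area <- (b$r1 - b$r0) * (b$c1 - b$c0)
    expect_gte(area / (128 * 160), 0.9)
  }
  succeed()
})

test_that("boxes_to_mask handles the forced-area cases", {
  expect_equal(sum(boxes_to_mask(boxes(), 10, 10)), 0)
  expect_true(all(boxes_to_mask(boxes(0, 0, 10, 10), 10, 10)))
  b2 <- boxes(c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  expect_equal(sum(boxes_to_mask(b2, 40, 40)), 200)
  expect_error(boxes_to_mask(boxes(0, 0, 11, 10), 10, 10), "bounds")
})

test_that("crop_panels slices pixel-exactly", {
  img <- seeded_rgb(5, 50, 60)
  expect_identical(crop_panels(img, boxes(0, 0, 50, 60))[[1]], img)
  one <- crop_panels(img, boxes(4, 7, 5, 8))[[1]]
  expect_equal(dim(one), c(1L, 1L, 3L))
  expect_equal(as.numeric(one), as.numeric(img[5, 8, ]))
  set.seed(6)
  r0 <- sample(0:20, 1); c0 <- sample(0:20, 1)
  b <- boxes(r0, c0, r0 + 17, c0 + 23)
  expect_identical(crop_panels(img, b)[[1]],
                   img[(r0 + 1):(r0 + 17), (c0 + 1):(c0 + 23), ])
})
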