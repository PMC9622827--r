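test_that("phantom panels are bit-identical across reruns", {
  expect_identical(make_blot_panel(5), make_blot_panel(5))
  expect_identical(make_micrograph_panel(5), make_micrograph_panel(5))
  expect_identical(make_isoluminant_panel(5), make_isoluminant_panel(5))
  expect_false(identical(make_blot_panel(5), make_blot_panel(6)))
})

test_that("lanes = 0 and n_cells = 0 give blank noise panels", {
  blank <- make_blot_panel(1, lanes = 0)
  expect_lt(mean(as_gray(blank) < 128), 0.001)
  empty <- make_micrograph_panel(1, n_cells = 0)
  expect_equal(nrow(attr(empty, "cells")), 0L)
})

test_that("dark band mass matches the analytic band-area prediction", {
  # the blur moves the 128-level set inward from the ellipse edge: the
  # blurred profile crosses 128 at a normal offset of sigma * z, where z
  # is the standard-normal quantile of the step fraction below 128
  for (s in 1:5) {
    panel <- make_blot_panel(s, 4, 3, c(128, 160))
    bands <- attr(panel, "bands")
    bg <- attr(panel, "background")
    sg <- attr(panel, "blur_sigma")
    inset <- -sg * qnorm((128 - bands$amp) / (bg - bands$amp))
    predicted <- sum(pi * pmax(bands$rx - inset, 0) *
                       pmax(bands$ry - inset, 0))
    observed <- sum(panel < 128)
    expect_lt(abs(observed - predicted) / predicted, 0.2)
  }
})

test_that("sparse blob counts are recovered by threshold and labeling", {
  for (s in 1:3) {
    panel <- make_micrograph_panel(s, 6, c(128, 160))
    lab <- EBImage::bwlabel(panel > 110)
    big <- sum(tabulate(lab[lab > 0]) >= 20)
    expect_equal(big, nrow(attr(panel, "cells")))
  }
})

test_that("the iso-luminant panel has flat luma but real chroma", {
  pan <- make_isoluminant_panel(2, c(96, 96))
  expect_lt(stats::sd(as_gray(pan)), 1)
  expect_gt(stats::sd(pan[, , 1]), 10)
})

test_that("composition preserves panel pixels inside the truth boxes", {
  p1 <- make_blot_panel(1, 3, 3, c(80, 100))
  p2 <- make_micrograph_panel(2, 5, c(70, 90))
  comp <- compose_figure(list(p1, p2), grid = c(1, 2))
  expect_equal(nrow(comp$panel_boxes), 2L)
  crops <- crop_panels(comp$figure, comp$panel_boxes)
  expect_equal(crops[[1]], p1, ignore_attr = TRUE)
  expect_equal(crops[[2]], p2, ignore_attr = TRUE)
  one <- compose_figure(list(p1), grid = c(1, 1))
  expect_equal(nrow(one$panel_boxes), 1L)
  # boxes are pairwise disjoint
  m <- boxes_to_mask(comp$panel_boxes, nrow(comp$figure),
                     ncol(comp$figure))
  areas <- sum((comp$panel_boxes$r1 - comp$panel_boxes$r0) *
                 (comp$panel_boxes$c1 - comp$panel_boxes$c0))
  expect_equal(sum(m), areas)
})

test_that("planted clones copy pixels exactly and mark both footprints", {
  img <- seeded_gray(3, 100, 120)
  src <- boxes(10, 10, 40, 50)
  out <- plant_clone(img, src, c(55, 60), "none")
  expect_identical(out$image[56:85, 61:100], img[11:40, 11:50])
  expect_equal(sum(out$mask), 2 * 30 * 40)
  mh <- plant_clone(img, src, c(55, 60), "mirror_h")
  expect_identical(mh$image[56:85, 61:100], img[11:40, 50:11])
  r9 <- plant_clone(img, src, c(50, 60), "rot90")
  expect_equal(sum(r9$mask), 2 * 30 * 40)
  expect_error(plant_clone(img, src, c(95, 60), "none"), "bounds")
  expect_error(plant_clone(img, src, c(20, 30), "none"), "overlaps")
})

test_that("reuse cases are deterministic dated DAGs", {
  c1 <- make_reuse_case(4, 1, seed = 2)
  c2 <- make_reuse_case(4, 1, seed = 2)
  expect_identical(c1$figures[[3]]$image, c2$figures[[3]]$image)
  expect_equal(c1$truth_graph, c2$truth_graph)
  g <- c1$truth_graph
  expect_equal(nrow(g$edges), 3L)
  ds <- g$nodes$date[match(g$edges$source, g$nodes$figure_id)]
  dt <- g$nodes$date[match(g$edges$target, g$nodes$figure_id)]
  expect_true(all(ds < dt))
  # two chains double the node and edge count
  c3 <- make_reuse_case(3, 2, seed = 1)
  expect_equal(length(c3$figures), 6L)
  expect_equal(nrow(c3$truth_graph$edges), 4L)
  # minimal case: one edge old -> new
  c4 <- make_reuse_case(2, 1, seed = 0)
  expect_equal(nrow(c4$truth_graph$edges), 1L)
})

test_that("derivation steps stay within their crop and resize bounds", {
  case <- make_reuse_case(4, 1, seed = 5)
  for (i in 2:4) {
    a_parent <- prod(dim(case$figures[[i - 1]]$image)[1:2])
    a_child <- prod(dim(case$figures[[i]]$image)[1:2])
    # crop area >= 0.56 x parent, resize in 0.8-1.2x per side
    expect_gte(a_child / a_parent, 0.56 * 0.8^2 - 0.02)
    expect_lte(a_child / a_parent, 0.85 * 1.2^2 + 0.02)
  }
})
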