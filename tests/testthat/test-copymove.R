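test_that("a pristine self pair produces almost no detections", {
  panel <- make_blot_panel(21, 4, 3, c(128, 160))
  res <- detect_pair(panel, panel)
  expect_lt(mean(res$fused$a), 0.01)
})

test_that("a clone planted across two panels is found in both", {
  pa <- make_micrograph_panel(31, 7, c(128, 160))
  pb <- make_micrograph_panel(32, 7, c(128, 160))
  pb[41:76, 61:108] <- pa[41:76, 61:108]
  truth_a <- truth_b <- matrix(FALSE, 128, 160)
  truth_a[41:76, 61:108] <- TRUE
  truth_b[41:76, 61:108] <- TRUE
  res <- detect_pair(pa, pb)
  expect_gt(sum(res$fused$a), 0)
  expect_gt(sum(res$fused$b), 0)
  f1 <- pixel_f1(res$fused$a | res$fused$b, truth_a | truth_b)
  expect_gte(f1, 0.8)
})

test_that("unrelated noise panels yield (near-)empty masks", {
  pa <- seeded_gray(41, 96, 128)
  pb <- seeded_gray(42, 96, 128)
  res <- detect_pair(pa, pb)
  expect_lt(mean(res$fused$a), 0.01)
  expect_lt(mean(res$fused$b), 0.01)
})

test_that("panels below the feature support are skipped with a warning", {
  tiny <- seeded_gray(5, 12, 12)
  expect_warning(res <- detect_pair(tiny, tiny), "skipped")
  expect_equal(sum(res$fused$a), 0)
})

test_that("detection is deterministic and fusion contains both branches", {
  cc <- make_clone_case(2, "none", "blot")
  r1 <- detect_copy_move(cc$figure)
  r2 <- detect_copy_move(cc$figure)
  expect_identical(r1, r2)
  expect_true(all(r1$final_mask[r1$zernike_mask]))
  expect_true(all(r1$final_mask[r1$rgb_mask]))
  expect_gte(pixel_f1(r1$final_mask, cc$mask), 0.8)
})

test_that("a mirrored blot clone is caught through the Zernike branch", {
  cc <- make_clone_case(1, "mirror_h", "blot")
  rep <- detect_copy_move(cc$figure)
  expect_gte(pixel_f1(rep$final_mask, cc$mask), 0.7)
  expect_gt(sum(rep$zernike_mask), 0)
})

test_that("an iso-luminant color clone is caught through the RGB branch", {
  cc <- make_clone_case(1, "none", "color")
  rep <- detect_copy_move(cc$figure)
  expect_gte(pixel_f1(rep$final_mask, cc$mask), 0.7)
  expect_gt(sum(rep$rgb_mask), 0)
  expect_equal(sum(rep$zernike_mask), 0)  # luma branch is blind here
})

test_that("identical text labels in two panels do not trigger detections", {
  comp <- compose_figure(list(make_blot_panel(51, 4, 3, c(128, 160)),
                              make_micrograph_panel(52, 7, c(128, 160))),
                         grid = c(1, 2), label_text = TRUE, seed = 5,
                         labels = c("ABCA", "ABCA"))
  fig <- figure_record("textfig", comp$figure, panels = comp$panel_boxes)
  rep <- detect_copy_move(fig)
  expect_lt(mean(rep$final_mask), 0.01)
})

test_that("every detected pixel lies inside a panel box", {
  cc <- make_clone_case(3, "none", "blot")
  rep <- detect_copy_move(cc$figure)
  d <- dim(cc$figure$image)[1:2]
  inside <- boxes_to_mask(rep$panels, d[1], d[2])
  expect_true(all(inside[rep$final_mask]))
})
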