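mk <- function(...) {
  m <- matrix(FALSE, 20, 20)
  for (b in list(...)) m[b[1]:b[2], b[3]:b[4]] <- TRUE
  m
}

test_that("iou reproduces its closed forms", {
  a <- mk(c(1, 10, 1, 10))
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, mk(c(11, 20, 11, 20))), 0.0)
  # two 10x10 boxes overlapping on a 5x10 strip: 50 / 150
  expect_equal(iou(mk(c(1, 10, 1, 10)), mk(c(6, 15, 1, 10))), 1 / 3)
  expect_equal(iou(mk(), mk()), 1)
  expect_error(iou(a, matrix(TRUE, 5, 5)), "same shape")
})

test_that("pixel_f1 reproduces its closed forms", {
  t_ <- mk(c(1, 10, 1, 10))
  expect_equal(pixel_f1(t_, t_), 1.0)
  expect_equal(pixel_f1(mk(), mk()), 1)
  expect_equal(pixel_f1(mk(), t_), 0)
  expect_equal(pixel_f1(t_, mk()), 0)
  # pred covers truth plus an equal area of false positives: 2A/(2A+A)
  expect_equal(pixel_f1(mk(c(1, 10, 1, 20)), t_), 2 / 3)
  # TP=30, FP=10, FN=20
  pred <- mk(c(1, 2, 1, 20))                  # 40 px: rows 1-2
  truth <- mk(c(1, 1, 1, 20), c(2, 2, 1, 10), c(3, 3, 1, 20))
  expect_equal(sum(pred & truth), 30)
  expect_equal(sum(pred & !truth), 10)
  expect_equal(sum(!pred & truth), 20)
  expect_equal(pixel_f1(pred, truth), 60 / 90)
})

test_that("Jaccard never exceeds Dice on the same pair", {
  set.seed(17)
  for (i in 1:20) {
    a <- matrix(runif(400) > 0.6, 20, 20)
    b <- matrix(runif(400) > 0.6, 20, 20)
    expect_lte(iou(a, b), pixel_f1(a, b))
    expect_equal(iou(a, b), iou(b, a))
  }
})

test_that("precision at N counts relevant slots out of N", {
  rk <- paste0("f", 1:10)
  expect_equal(precision_at_n(rk[1:5], rk[1:5], 5), 1.0)
  expect_equal(precision_at_n(rk, character(0), 5), 0.0)
  rel <- rk[c(1, 3, 7)]
  expect_equal(precision_at_n(rk, rel, 5), 0.4)
  expect_equal(precision_at_n(rk, rel, 10), 0.3)
  # short ranks keep the denominator at N
  expect_equal(precision_at_n(rk[1:2], rk[1:2], 5), 0.4)
})

pg <- function(ids, e_from = character(), e_to = character()) {
  nodes <- data.frame(figure_id = ids, doi = rep("", length(ids)),
                      stringsAsFactors = FALSE)
  nodes$date <- as.Date(rep(NA, length(ids)))
  provenance_graph(nodes, data.frame(source = e_from, target = e_to,
                                     weight = rep(1L, length(e_from)),
                                     stringsAsFactors = FALSE))
}

test_that("graph overlap reproduces its closed forms", {
  g <- pg(c("a", "b", "c"), c("a", "b"), c("b", "c"))
  expect_equal(graph_overlap(g, g), c(vo = 1, eo = 1, veo = 1))
  h <- pg(c("x", "y"))
  expect_equal(unname(graph_overlap(pg(c("a", "b")), h)[1]), 0)
  h2 <- pg(c("a", "b", "c", "d"), "a", "b")
  ov <- graph_overlap(g, h2)
  expect_equal(ov[["vo"]], 6 / 7)
  expect_equal(ov[["eo"]], 2 / 3)
  expect_equal(ov[["veo"]], 8 / 10)
})

test_that("graph overlap ignores edge direction and argument order", {
  g <- pg(c("a", "b", "c"), c("a", "b"), c("b", "c"))
  rev_g <- pg(c("a", "b", "c"), c("b", "c"), c("a", "b"))
  h <- pg(c("a", "b", "c", "d"), "a", "b")
  expect_equal(graph_overlap(g, h), graph_overlap(rev_g, h))
  expect_equal(graph_overlap(g, h), graph_overlap(h, g))
  empty <- pg(character())
  expect_equal(graph_overlap(empty, empty), c(vo = 1, eo = 1, veo = 1))
})
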