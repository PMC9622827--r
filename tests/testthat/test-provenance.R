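test_that("a figure matches itself with a near-identity transform", {
  fig <- figure_record("a", make_micrograph_panel(1, 6, c(96, 128)))
  m <- match_pair(fig, fig, n_points = 400, seed = 1)
  ds <- describe_figure(fig, n_points = 400)
  usable <- sum(!ds$keypoints$mirrored)
  expect_gte(m$count, 0.8 * usable)
  ident <- cbind(diag(2), c(0, 0))
  expect_lt(max(abs(m$transform - ident)), 0.05)
})

test_that("a mirrored crop is matched through the mirror augmentation", {
  img <- make_micrograph_panel(2, 6, c(96, 128))
  crop <- img[10:90, 15:115]
  crop <- crop[, rev(seq_len(ncol(crop)))]
  m <- match_pair(figure_record("a", img), figure_record("b", crop),
                  n_points = 400, seed = 1)
  expect_gte(m$count, 20)
  expect_gt(mean(m$inliers$mirrored), 0.5)
})

test_that("independent figures share almost no consistent matches", {
  a <- figure_record("a", make_micrograph_panel(3, 6, c(96, 128)))
  b <- figure_record("b", make_micrograph_panel(4, 6, c(96, 128)))
  m <- match_pair(a, b, n_points = 400, seed = 1)
  expect_lt(m$count, 8)
})

test_that("the adjacency matrix is symmetric, thresholded and hollow", {
  a <- figure_record("a", make_micrograph_panel(5, 6, c(96, 128)))
  b <- figure_record("b", a$image)
  c_ <- figure_record("c", make_blot_panel(6, 3, 3, c(96, 128)))
  adj <- build_adjacency(list(a, b, c_), min_inliers = 8,
                         n_points = 300, seed = 0)
  expect_true(isSymmetric(unname(adj$counts)))
  expect_equal(diag(adj$counts), setNames(rep(0L, 3), adj$ids))
  expect_gt(adj$counts["a", "b"], 0)
  expect_error(build_adjacency(list(a), min_inliers = 8), "at least 2")
})

test_that("content loss is monotone along a crop chain", {
  root <- make_micrograph_panel(7, 8, c(128, 160))
  crop1 <- root[11:110, 16:140]
  crop2 <- crop1[11:85, 11:105]
  figs <- list(figure_record("f0", root), figure_record("f1", crop1),
               figure_record("f2", crop2))
  adj <- build_adjacency(figs, min_inliers = 8, n_points = 500, seed = 0)
  expect_gt(adj$counts["f0", "f1"], 0)
  expect_gt(adj$counts["f1", "f2"], 0)
  expect_lte(adj$counts["f0", "f2"], adj$counts["f0", "f1"])
})

manual_adjacency <- function(W, ids, dates) {
  dimnames(W) <- list(ids, ids)
  structure(list(counts = W, ids = ids,
                 dates = as.Date(dates), dois = rep("", length(ids))),
            class = "adjacency_matrix")
}

test_that("a two-figure adjacency orients by date", {
  W <- matrix(c(0L, 30L, 30L, 0L), 2, 2)
  adj <- manual_adjacency(W, c("A", "B"), c("2014-01-01", "2015-01-01"))
  g <- span_and_orient(adj)
  expect_equal(g$edges, data.frame(source = "A", target = "B",
                                   weight = 30L))
})

test_that("Kruskal keeps the heavy edges of a triangle", {
  W <- matrix(0L, 3, 3)
  W[1, 2] <- W[2, 1] <- 10L
  W[2, 3] <- W[3, 2] <- 8L
  W[1, 3] <- W[3, 1] <- 3L
  adj <- manual_adjacency(W, c("a", "b", "c"),
                          c("2014-01-01", "2014-06-01", "2015-01-01"))
  g <- span_and_orient(adj)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sum(g$edges$weight), 18L)
  expect_false(any(g$edges$source == "a" & g$edges$target == "c"))
})

test_that("the forest agrees with an independent maximum-spanning-tree", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    W <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.7)
        W[i, j] <- W[j, i] <- sample(1:50, 1)
    ids <- paste0("v", seq_len(n))
    adj <- manual_adjacency(W, ids,
                            as.Date("2014-01-01") + sample(0:999, n))
    g <- span_and_orient(adj)
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
    mst <- igraph::mst(ig, weights = -igraph::E(ig)$weight)
    expect_equal(sum(g$edges$weight),
                 sum(igraph::E(mst)$weight))
  }
})

test_that("no output edge ever violates date order, over fuzzed inputs", {
  skip_if_not_installed("igraph")
  set.seed(29)
  for (rep in 1:100) {
    n <- sample(3:9, 1)
    W <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.5) W[i, j] <- W[j, i] <- sample(1:40, 1)
    ids <- paste0("v", seq_len(n))
    dates <- as.Date("2010-01-01") + sample(0:2000, n, replace = TRUE)
    dates[runif(n) < 0.2] <- NA
    adj <- manual_adjacency(W, ids, dates)
    g <- span_and_orient(adj)
    expect_lte(nrow(g$edges), n - 1)
    if (nrow(g$edges)) {
      ds <- g$nodes$date[match(g$edges$source, g$nodes$figure_id)]
      dt <- g$nodes$date[match(g$edges$target, g$nodes$figure_id)]
      ok <- is.na(ds) | is.na(dt) | ds <= dt
      expect_true(all(ok))
      ig <- igraph::graph_from_data_frame(g$edges[, 1:2])
      expect_true(igraph::is_dag(ig))
    }
  }
})

test_that("graph JSON round-trips identically", {
  tmp <- withr::local_tempfile(fileext = ".json")
  empty <- provenance_graph(
    data.frame(figure_id = character(), doi = character(),
               date = as.Date(character())),
    data.frame(source = character(), target = character(),
               weight = integer()))
  export_graph(empty, tmp)
  expect_equal(import_graph(tmp), empty)
  single <- provenance_graph(
    data.frame(figure_id = "a", doi = "10.1/x",
               date = as.Date("2014-01-01")),
    data.frame(source = character(), target = character(),
               weight = integer()))
  export_graph(single, tmp)
  expect_equal(import_graph(tmp), single)
  set.seed(31)
  n <- 10
  nodes <- data.frame(figure_id = paste0("n", 1:n),
                      doi = paste0("10.0000/synthetic.", 1:n),
                      stringsAsFactors = FALSE)
  nodes$date <- as.Date("2014-01-01") + sample(0:999, n)
  nodes$date[2] <- NA
  edges <- data.frame(source = paste0("n", 1:5),
                      target = paste0("n", 6:10),
                      weight = sample(1:99, 5),
                      stringsAsFactors = FALSE)
  g <- provenance_graph(nodes, edges)
  export_graph(g, tmp)
  expect_equal(import_graph(tmp), g)
  expect_error(import_graph(withr::local_tempfile(fileext = ".json")),
               "cannot parse")
})

test_that("reuse chains are recovered from the generator truth", {
  case <- make_reuse_case(n_papers = 4, reuses_per_paper = 1, seed = 3)
  adj <- build_adjacency(case$figures, min_inliers = 8, n_points = 800,
                         seed = 3)
  g <- span_and_orient(adj)
  ov <- graph_overlap(g, case$truth_graph)
  expect_equal(ov[["vo"]], 1.0)
  expect_gte(ov[["eo"]], 0.8)
})
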