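retrieval_bench <- function(n = 8, n_points = 200) {
  figs <- lapply(seq_len(n), function(i) {
    img <- if (i %% 2) make_micrograph_panel(i, 6, c(96, 128))
    else make_blot_panel(i, 3, 3, c(96, 128))
    figure_record(paste0("fig", i), img)
  })
  dups <- lapply(seq_len(n), function(i) {
    img <- figs[[i]]$image
    if (i <= n / 2) figure_record(paste0("dup", i), img)
    else figure_record(paste0("dup", i),
                       img[, rev(seq_len(ncol(img)))])
  })
  list(figs = figs, dups = dups,
       index = build_index(c(figs, dups), n_points = n_points))
}

test_that("index construction validates ids and counts entries", {
  fig <- figure_record("a", make_micrograph_panel(1, 5, c(64, 64)))
  expect_error(build_index(list(fig, fig)), "duplicate")
  idx <- build_index(list(fig), n_points = 50)
  ds <- describe_figure(fig, n_points = 50)
  expect_equal(length(idx$figure_id), nrow(ds$descriptors))
  expect_true(all(idx$figure_id == "a"))
})

test_that("an exactly stored descriptor is its own 1-NN at distance 0", {
  fig <- figure_record("a", make_micrograph_panel(2, 6, c(96, 128)))
  other <- figure_record("b", make_blot_panel(3, 3, 3, c(96, 128)))
  idx <- build_index(list(fig, other), n_points = 100)
  q <- idx$descriptors[5, , drop = FALSE]
  d2 <- scifig:::cross_dist2(q, idx$descriptors)
  expect_equal(which.min(d2), 5L)
  expect_lt(min(d2), 1e-12)
})

test_that("plain and mirrored duplicates rank first", {
  b <- retrieval_bench()
  for (i in seq_along(b$figs)) {
    rk <- query_rank(b$index, b$figs[[i]], k_nn = 8, n_points = 200)
    expect_equal(rk$entries$figure_id[1], paste0("dup", i))
    expect_false(rk$query_id %in% rk$entries$figure_id)
    expect_lte(nrow(rk$entries), 10L)
    expect_true(!is.unsorted(-rk$entries$votes))
  }
})

test_that("voting equals a brute-force all-pairs distance scan", {
  b <- retrieval_bench(n = 4)
  q <- b$figs[[1]]
  rk <- query_rank(b$index, q, k_nn = 8, n_points = 200)
  # independent oracle: flat scan with insertion-order tie-breaks
  ds <- describe_figure(q, n_points = 200)
  usable <- b$index$figure_id != q$id
  store <- b$index$descriptors[usable, , drop = FALSE]
  ids <- b$index$figure_id[usable]
  votes <- setNames(integer(0), character(0))
  dist_sum <- setNames(numeric(0), character(0))
  for (i in seq_len(nrow(ds$descriptors))) {
    d2 <- colSums((t(store) - ds$descriptors[i, ])^2)
    nn <- order(d2)[1:8]
    for (j in nn) {
      id <- ids[j]
      votes[id] <- (if (is.na(votes[id])) 0L else votes[id]) + 1L
      dist_sum[id] <- (if (is.na(dist_sum[id])) 0 else dist_sum[id]) +
        sqrt(d2[j])
    }
  }
  ord <- order(-votes, dist_sum[names(votes)], names(votes))
  expected <- utils::head(names(votes)[ord], 10)
  expect_equal(rk$entries$figure_id, expected)
  expect_equal(rk$entries$votes,
               as.integer(votes[expected]), ignore_attr = TRUE)
  # vote conservation: every query descriptor casts exactly k votes
  expect_equal(sum(votes), nrow(ds$descriptors) * 8L)
})

test_that("degenerate queries and empty indexes are handled", {
  fig <- figure_record("a", make_micrograph_panel(4, 6, c(96, 128)))
  idx <- build_index(list(fig), n_points = 50)
  flat <- figure_record("flat", matrix(100, 64, 64))
  rk <- query_rank(idx, flat)
  expect_equal(nrow(rk$entries), 0L)
  # a query that is the only indexed figure finds nothing
  rk2 <- query_rank(idx, fig, n_points = 50)
  expect_equal(nrow(rk2$entries), 0L)
})
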