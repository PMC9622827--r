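# Provenance analysis: geometrically consistent keypoint matching between
# figure pairs, a date-constrained adjacency matrix of match counts, and a
# maximum-spanning-forest provenance graph whose edges run from earlier-
# to later-published figures.

#' Geometrically consistent matches between two figures
#'
#' Both figures are described with mirror-augmented RootSIFT keypoints
#' (text regions excluded); the plain keypoints of `a` are matched against
#' both the plain and the mirrored keypoints of `b` by mutual nearest
#' neighbors with Lowe's ratio test, and an affine transform `A -> B` is
#' estimated by seeded RANSAC. Inliers are tentative matches within
#' `ransac_tol_px` of the model; a mirrored reuse shows up as a dominant
#' set of inliers carrying the mirrored flag (their B-side coordinates
#' live in the mirrored frame).
#'
#' @param a,b [figure_record()]s.
#' @param n_points per-side keypoint budget.
#' @param ratio Lowe ratio-test threshold.
#' @param ransac_tol_px inlier tolerance, px.
#' @param ransac_iters RANSAC iterations.
#' @param seed RANSAC seed.
#' @return a `geometric_match`: list with `count`, `inliers` (data frame
#'   `row_a`, `col_a`, `row_b`, `col_b`, `mirrored`) and `transform`
#'   (2 x 3 affine matrix mapping A pixel coords to B, or `NULL`).
#' @export
match_pair <- function(a, b, n_points = 2000L, ratio = 0.8,
                       ransac_tol_px = 5.0, ransac_iters = 1000L,
                       seed = 0L) {
  da <- describe_figure(a, n_points)
  db <- describe_figure(b, n_points)
  no_match <- list(count = 0L,
                   inliers = data.frame(row_a = numeric(), col_a = numeric(),
                                        row_b = numeric(), col_b = numeric(),
                                        mirrored = logical()),
                   transform = NULL)
  keep_a <- !da$keypoints$mirrored
  if (sum(keep_a) < 4L || nrow(db$descriptors) < 4L)
    return(structure(no_match, class = "geometric_match"))
  qa <- da$descriptors[keep_a, , drop = FALSE]
  ka <- da$keypoints[keep_a, , drop = FALSE]
  d2 <- cross_dist2(qa, db$descriptors)
  # nearest and second-nearest neighbor per A keypoint
  nn1 <- apply(d2, 1, which.min)
  d1 <- d2[cbind(seq_len(nrow(d2)), nn1)]
  d2m <- d2
  d2m[cbind(seq_len(nrow(d2)), nn1)] <- Inf
  dsecond <- apply(d2m, 1, min)
  pass_ratio <- sqrt(d1) < ratio * sqrt(dsecond)
  # mutual check: A_i's neighbor must have A_i as its own nearest
  back <- apply(d2, 2, which.min)
  mutual <- back[nn1] == seq_len(nrow(d2))
  sel <- which(pass_ratio & mutual)
  if (length(sel) < 4L) return(structure(no_match, class = "geometric_match"))
  pts_a <- cbind(ka$row[sel], ka$col[sel])
  pts_b <- cbind(db$keypoints$row[nn1[sel]], db$keypoints$col[nn1[sel]])
  mirr <- db$keypoints$mirrored[nn1[sel]]
  fit <- ransac_affine(pts_a, pts_b, tol = ransac_tol_px,
                       iters = ransac_iters, seed = seed)
  if (is.null(fit)) return(structure(no_match, class = "geometric_match"))
  inl <- fit$inliers
  structure(list(count = length(inl),
                 inliers = data.frame(row_a = pts_a[inl, 1],
                                      col_a = pts_a[inl, 2],
                                      row_b = pts_b[inl, 1],
                                      col_b = pts_b[inl, 2],
                                      mirrored = mirr[inl]),
                 transform = fit$transform),
            class = "geometric_match")
}

#' @export
print.geometric_match <- function(x, ...) {
  cat(sprintf("<geometric_match: %d inlier(s)%s>\n", x$count,
              if (x$count && any(x$inliers$mirrored)) ", mirrored content"
              else ""))
  invisible(x)
}

# Affine transform through 3 point pairs; rows of the 2x3 matrix map
# (row_a, col_a, 1) to row_b and col_b.
affine_from_points <- function(pa, pb) {
  M <- cbind(pa, 1)
  if (abs(det(M)) < 1e-9) return(NULL)
  t(solve(M, pb))  # 2 x 3
}

affine_apply <- function(Tm, pts) {
  cbind(pts, 1) %*% t(Tm)
}

ransac_affine <- function(pa, pb, tol, iters, seed) {
  n <- nrow(pa)
  best <- integer(0)
  with_seed(seed, {
    for (it in seq_len(iters)) {
      tri <- sample.int(n, 3L)
      Tm <- affine_from_points(pa[tri, , drop = FALSE],
                               pb[tri, , drop = FALSE])
      if (is.null(Tm)) next
      pred <- affine_apply(Tm, pa)
      err <- sqrt(rowSums((pred - pb)^2))
      inl <- which(err <= tol)
      if (length(inl) > length(best)) best <- inl
    }
  })
  if (length(best) < 4L) return(NULL)
  # least-squares refit on the consensus set, then recount
  M <- cbind(pa[best, , drop = FALSE], 1)
  Tm <- t(qr.solve(M, pb[best, , drop = FALSE]))
  err <- sqrt(rowSums((affine_apply(Tm, pa) - pb)^2))
  inl <- which(err <= tol)
  if (length(inl) < 4L) return(NULL)
  list(transform = Tm, inliers = inl)
}

#' Pairwise match-count adjacency matrix
#'
#' Entry `(i, j)` holds the inlier count of [match_pair()] between figures
#' `i` and `j` when it reaches `min_inliers`, and 0 otherwise; each
#' unordered pair is computed once and mirrored, the diagonal is zero.
#'
#' @param figures list of [figure_record()]s with unique ids.
#' @param min_inliers minimum inlier count for a nonzero entry.
#' @param ... passed on to [match_pair()].
#' @return an `adjacency_matrix`: list with the integer `counts` matrix,
#'   `ids`, `dates` and `dois`.
#' @export
build_adjacency <- function(figures, min_inliers = 8L, ...) {
  if (length(figures) < 2L) stop("need at least 2 figures", call. = FALSE)
  ids <- vapply(figures, function(f) f$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate figure id(s)", call. = FALSE)
  n <- length(figures)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- match_pair(figures[[i]], figures[[j]], ...)
    if (m$count >= min_inliers) counts[i, j] <- counts[j, i] <- m$count
  }
  structure(list(counts = counts, ids = ids,
                 dates = do.call(c, lapply(figures, function(f) f$date)),
                 dois = vapply(figures, function(f) f$doi, character(1))),
            class = "adjacency_matrix")
}

#' Maximum spanning forest, oriented by publication date
#'
#' Kruskal's algorithm on the undirected weighted graph of the adjacency
#' matrix (edges sorted by descending weight, ties by lexicographic id
#' pair) yields a maximum-weight spanning forest; each chosen edge is then
#' oriented from the earlier-dated figure to the later-dated one, so no
#' edge ever runs from a later to an earlier publication. Pairs with
#' equal or missing dates are oriented by ascending figure id. Isolated
#' figures remain as singleton nodes.
#'
#' @param adj an [build_adjacency()] result.
#' @return a `provenance_graph`; see [provenance_graph()].
#' @export
span_and_orient <- function(adj) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  n <- length(adj$ids)
  W <- adj$counts
  stopifnot(isSymmetric(unname(W)), all(diag(W) == 0))
  pairs <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  nodes <- data.frame(figure_id = adj$ids, doi = adj$dois,
                      stringsAsFactors = FALSE)
  nodes$date <- adj$dates
  edges <- data.frame(source = character(), target = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    lo_id <- pmin(adj$ids[pairs[, 1]], adj$ids[pairs[, 2]])
    hi_id <- pmax(adj$ids[pairs[, 1]], adj$ids[pairs[, 2]])
    w <- W[pairs]
    ord <- order(-w, lo_id, hi_id)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in ord) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      parent[max(ri, rj)] <- min(ri, rj)
      di <- adj$dates[i]; dj <- adj$dates[j]
      flip <- if (!is.na(di) && !is.na(dj) && di != dj) dj < di
      else adj$ids[j] < adj$ids[i]
      src <- if (flip) j else i
      tgt <- if (flip) i else j
      edges <- rbind(edges,
                     data.frame(source = adj$ids[src],
                                target = adj$ids[tgt],
                                weight = as.integer(W[i, j]),
                                stringsAsFactors = FALSE))
    }
  }
  provenance_graph(nodes, edges)
}

#' Construct a provenance graph
#'
#' A provenance graph is a directed acyclic forest over figures: nodes
#' carry `(figure_id, doi, date)` and each edge expresses probable content
#' donation from its earlier source to its later target. Nodes and edges
#' are kept in canonical order (by id, and by source/target), so equal
#' graphs compare identical.
#'
#' @param nodes data frame with `figure_id`, `doi`, `date` columns.
#' @param edges data frame with `source`, `target`, `weight` columns.
#' @return an object of class `provenance_graph`.
#' @export
provenance_graph <- function(nodes, edges) {
  stopifnot(all(c("figure_id", "doi", "date") %in% names(nodes)),
            all(c("source", "target", "weight") %in% names(edges)))
  if (anyDuplicated(nodes$figure_id))
    stop("duplicate node ids", call. = FALSE)
  if (nrow(edges)) {
    if (!all(edges$source %in% nodes$figure_id) ||
        !all(edges$target %in% nodes$figure_id))
      stop("edge endpoint not among nodes", call. = FALSE)
    if (nrow(edges) > nrow(nodes) - 1L)
      stop("edge set is not a forest", call. = FALSE)
  }
  nodes <- nodes[order(nodes$figure_id),
                 c("figure_id", "doi", "date"), drop = FALSE]
  edges <- edges[order(edges$source, edges$target),
                 c("source", "target", "weight"), drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "provenance_graph")
}

#' @export
print.provenance_graph <- function(x, ...) {
  cat(sprintf("<provenance_graph: %d node(s), %d edge(s)>\n",
              nrow(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s (w=%d)\n", x$edges$source[i],
                x$edges$target[i], x$edges$weight[i]))
  invisible(x)
}

#' Write a provenance graph to JSON
#'
#' Schema: `{"nodes": [{"id", "doi", "date"}], "edges": [{"source",
#' "target", "weight"}]}`, with nodes sorted by id and edges by
#' source/target, so output is deterministic and [import_graph()] gives
#' back an identical graph.
#'
#' @param g a [provenance_graph()].
#' @param path output path.
#' @export
export_graph <- function(g, path) {
  stopifnot(inherits(g, "provenance_graph"))
  nodes <- lapply(seq_len(nrow(g$nodes)), function(i) {
    list(id = g$nodes$figure_id[i], doi = g$nodes$doi[i],
         date = if (is.na(g$nodes$date[i])) NULL
         else format(g$nodes$date[i]))
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(i) {
    list(source = g$edges$source[i], target = g$edges$target[i],
         weight = g$edges$weight[i])
  })
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(NULL)
}

#' Read a provenance graph from JSON
#'
#' @param path path to a JSON file written by [export_graph()].
#' @return a [provenance_graph()].
#' @export
import_graph <- function(path) {
  if (!file.exists(path))
    stop("cannot parse graph JSON ", path, ": file not found",
         call. = FALSE)
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e)
                  stop("cannot parse graph JSON ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  nodes <- data.frame(
    figure_id = vapply(j$nodes, function(x) x$id, character(1)),
    doi = vapply(j$nodes, function(x) x$doi %||% "", character(1)),
    stringsAsFactors = FALSE)
  nodes$date <- do.call(c, lapply(j$nodes, function(x)
    parse_pub_date(x$date)))
  if (!length(j$nodes)) {
    nodes <- data.frame(figure_id = character(), doi = character())
    nodes$date <- as.Date(character())
  }
  edges <- data.frame(
    source = vapply(j$edges, function(x) x$source, character(1)),
    target = vapply(j$edges, function(x) x$target, character(1)),
    weight = vapply(j$edges, function(x) as.integer(x$weight), integer(1)),
    stringsAsFactors = FALSE)
  provenance_graph(nodes, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
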