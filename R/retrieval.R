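# Flat inverted-file indexing and vote-based image ranking. The index is
# an exact (flat) L2 store: every descriptor keeps a back-pointer to its
# source figure, and a query retrieves, for each of its descriptors, the
# k nearest stored descriptors, each of which casts one vote for its
# source figure. Figures are ranked by votes.

#' Build a flat inverted-file index over a set of figures
#'
#' All mirror-augmented RootSIFT descriptors of all figures are stored in
#' one flat matrix with per-entry back-pointers `(figure_id, mirrored)`.
#' Search is exact: the k nearest entries under Euclidean distance, ties
#' broken by insertion order.
#'
#' @param figures list of [figure_record()]s with unique ids.
#' @param n_points per-side keypoint budget passed to [describe_figure()].
#' @return an object of class `inverted_index`.
#' @export
build_index <- function(figures, n_points = 500L) {
  ids <- vapply(figures, function(f) f$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate figure id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  descs <- vector("list", length(figures))
  src <- vector("list", length(figures))
  mir <- vector("list", length(figures))
  for (i in seq_along(figures)) {
    ds <- describe_figure(figures[[i]], n_points)
    descs[[i]] <- ds$descriptors
    src[[i]] <- rep(ids[i], nrow(ds$descriptors))
    mir[[i]] <- ds$keypoints$mirrored
  }
  structure(list(descriptors = do.call(rbind, descs),
                 figure_id = unlist(src),
                 mirrored = unlist(mir),
                 n_figures = length(figures)),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat(sprintf("<inverted_index: %d descriptors from %d figure(s)>\n",
              length(x$figure_id), x$n_figures))
  invisible(x)
}

# Exact squared Euclidean distances between the rows of two matrices.
cross_dist2 <- function(q, x) {
  d2 <- outer(rowSums(q^2), rowSums(x^2), "+") - 2 * tcrossprod(q, x)
  pmax(d2, 0)
}

#' Rank the indexed figures against a query figure
#'
#' For each descriptor of the query, its `k_nn` nearest stored entries
#' each add one vote to their source figure; entries pointing back to the
#' query's own id are skipped without consuming a neighbor slot. Figures
#' are sorted by descending votes, ties broken by ascending summed
#' neighbor distance and then by id, and the rank is truncated to
#' `rank_cap` entries.
#'
#' @param index an [build_index()] result.
#' @param query a [figure_record()].
#' @param k_nn neighbors retrieved per query descriptor.
#' @param n_points keypoint budget for describing the query.
#' @param rank_cap maximum rank length.
#' @return a `figure_rank`: list with `query_id` and `entries` (data frame
#'   `figure_id`, `votes`, `sum_dist`).
#' @export
query_rank <- function(index, query, k_nn = 8L, n_points = 500L,
                       rank_cap = 10L) {
  stopifnot(inherits(index, "inverted_index"))
  if (!length(index$figure_id)) stop("index is empty", call. = FALSE)
  ds <- describe_figure(query, n_points)
  empty <- data.frame(figure_id = character(), votes = integer(),
                      sum_dist = numeric())
  if (!nrow(ds$descriptors)) {
    return(structure(list(query_id = query$id, entries = empty),
                     class = "figure_rank"))
  }
  usable <- index$figure_id != query$id
  if (!any(usable)) {
    return(structure(list(query_id = query$id, entries = empty),
                     class = "figure_rank"))
  }
  store <- index$descriptors[usable, , drop = FALSE]
  store_id <- index$figure_id[usable]
  d2 <- cross_dist2(ds$descriptors, store)
  k <- min(k_nn, ncol(d2))
  votes <- numeric(0)
  hit_id <- character(0)
  hit_d <- numeric(0)
  for (i in seq_len(nrow(d2))) {
    # ties broken by insertion order: sort is stable on the index order
    nn <- order(d2[i, ])[seq_len(k)]
    hit_id <- c(hit_id, store_id[nn])
    hit_d <- c(hit_d, sqrt(d2[i, nn]))
  }
  votes <- table(hit_id)
  sum_d <- tapply(hit_d, hit_id, sum)
  ids <- names(votes)
  ent <- data.frame(figure_id = ids, votes = as.integer(votes),
                    sum_dist = as.numeric(sum_d[ids]),
                    stringsAsFactors = FALSE)
  ent <- ent[order(-ent$votes, ent$sum_dist, ent$figure_id), , drop = FALSE]
  ent <- utils::head(ent, rank_cap)
  rownames(ent) <- NULL
  structure(list(query_id = query$id, entries = ent), class = "figure_rank")
}

#' @export
print.figure_rank <- function(x, ...) {
  cat(sprintf("<figure_rank for '%s': %d entr%s>\n", x$query_id,
              nrow(x$entries), if (nrow(x$entries) == 1) "y" else "ies"))
  if (nrow(x$entries)) print(x$entries)
  invisible(x)
}
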