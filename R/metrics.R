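# Evaluation metrics for clone masks, retrieval ranks and provenance
# graphs. Empty-vs-empty comparisons return 1 by convention so that
# pristine-figure evaluations are well defined.

#' Intersection over union of two masks
#'
#' @param a,b logical matrices of the same shape.
#' @return `|a & b| / |a | b|` in `[0, 1]`; 1 when both masks are empty.
#' @export
iou <- function(a, b) {
  check_same_shape(a, b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Pixel-wise F1 score of a predicted mask
#'
#' Harmonic mean of precision and recall of in-agreement pixels:
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @param pred,truth logical matrices of the same shape.
#' @return value in `[0, 1]`; 1 when both masks are empty, 0 when exactly
#'   one is.
#' @export
pixel_f1 <- function(pred, truth) {
  check_same_shape(pred, truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

check_same_shape <- function(a, b) {
  if (!is.logical(a) || !is.logical(b) || !all(dim(a) == dim(b)))
    stop("masks must be logical matrices of the same shape", call. = FALSE)
}

#' Precision at N of a retrieval rank
#'
#' Fraction of the top-`n` rank entries that are relevant. A rank shorter
#' than `n` counts its missing slots as non-relevant (the denominator
#' stays `n`, penalizing under-retrieval).
#'
#' @param rank a `figure_rank` from [query_rank()], or a character vector
#'   of ranked figure ids.
#' @param relevant character vector of relevant figure ids.
#' @param n cutoff (typically 1, 5 or 10).
#' @return value in `[0, 1]`.
#' @export
precision_at_n <- function(rank, relevant, n) {
  stopifnot(n >= 1)
  ids <- if (inherits(rank, "figure_rank")) rank$entries$figure_id
  else as.character(rank)
  top <- utils::head(ids, n)
  sum(top %in% relevant) / n
}

#' Vertex, edge, and combined overlap of two provenance graphs
#'
#' The overlap F-measures used to compare provenance graphs:
#' `VO = 2 |Vg vertcap Vh| / (|Vg| + |Vh|)`, `EO` likewise on edges compared as
#' unordered id pairs (direction is ignored), and `VEO` on the union of
#' both element sets. Empty denominators give 1.
#'
#' @param g,h [provenance_graph()]s.
#' @return named numeric vector `c(vo, eo, veo)`, each in `[0, 1]`.
#' @export
graph_overlap <- function(g, h) {
  stopifnot(inherits(g, "provenance_graph"),
            inherits(h, "provenance_graph"))
  vg <- g$nodes$figure_id; vh <- h$nodes$figure_id
  und <- function(e) {
    if (!nrow(e)) return(character())
    unique(paste(pmin(e$source, e$target), pmax(e$source, e$target),
                 sep = "\r"))
  }
  eg <- und(g$edges); eh <- und(h$edges)
  vo_num <- 2 * length(intersect(vg, vh)); vo_den <- length(vg) + length(vh)
  eo_num <- 2 * length(intersect(eg, eh)); eo_den <- length(eg) + length(eh)
  c(vo = if (vo_den == 0) 1 else vo_num / vo_den,
    eo = if (eo_den == 0) 1 else eo_num / eo_den,
    veo = if (vo_den + eo_den == 0) 1
    else (vo_num + eo_num) / (vo_den + eo_den))
}
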