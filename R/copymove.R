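# The copy-move detector: randomized nearest-neighbor-field search over a
# dense feature field, a bidirectional match constraint, dense-linear-
# fitting post-processing, panel-pairwise orchestration and Zernike/RGB
# branch fusion.

#' Approximate nearest-neighbor field over a dense feature field
#'
#' Runs the randomized search (seeded uniform initialization, alternating
#' raster/anti-raster propagation of the causal neighbors' offsets plus
#' mirror-adjusted variants, and a random search with window radius halving
#' from `max(rows, cols)` down to 1) under squared Euclidean feature
#' distance. Offsets shorter than `min_offset_px` are inadmissible, which
#' suppresses trivial near-self matches. Deterministic given `seed`.
#'
#' @param field a `dense_field` from [zernike_field()] or [rgb_field()].
#' @param iterations number of propagation/search sweeps.
#' @param min_offset_px minimum admissible offset length, px.
#' @param seed integer seed of the randomized search.
#' @param match_mirrored also match each patch against horizontally
#'   mirrored targets (only possible for fields carrying a
#'   `mirror_perm`, i.e. the RGB branch; Zernike magnitudes are mirror
#'   invariant by construction, so their field needs no augmentation).
#' @return an `offset_field`: list with integer matrices `dr`, `dc`, the
#'   squared feature distance `cost`, a logical `valid` mask, and (when
#'   `match_mirrored`) a logical `mirrored` matrix flagging matches that
#'   hold under patch mirroring.
#' @export
patchmatch_nnf <- function(field, iterations = 8L, min_offset_px = 16L,
                           seed = 0L, match_mirrored = FALSE) {
  stopifnot(inherits(field, "dense_field"))
  rows <- nrow(field$valid); cols <- ncol(field$valid)
  if (min_offset_px >= max(rows, cols))
    stop("min_offset_px must be smaller than the image extent",
         call. = FALSE)
  perm <- if (match_mirrored && !is.null(field$mirror_perm))
    as.integer(field$mirror_perm) else integer(0)
  res <- pm_nnf(field$features, field$valid, as.integer(iterations),
                as.integer(min_offset_px), as.integer(seed), perm)
  if (any(field$valid) && !any(res$valid))
    stop("no admissible offset exists under min_offset_px = ",
         min_offset_px, call. = FALSE)
  structure(list(dr = res$dr, dc = res$dc, cost = res$cost,
                 valid = res$valid,
                 mirrored = if (length(perm)) res$mirrored,
                 min_offset_px = as.integer(min_offset_px)),
            class = "offset_field")
}

#' @export
print.offset_field <- function(x, ...) {
  cat(sprintf("<offset_field %d x %d, %d valid px, median cost %.3g>\n",
              nrow(x$dr), ncol(x$dr), sum(x$valid),
              median(x$cost[x$valid])))
  invisible(x)
}

#' Bidirectional match constraint
#'
#' A pixel `p` is kept only if its match is confirmed both ways: with
#' `q = p + f(p)`, the reverse offset must point back within tolerance,
#' `max(|f(q) + f(p)|) <= tol_px` (Chebyshev norm). This culls the random
#' false matches that plague low-contrast scientific imagery, where many
#' regions are weakly similar: a coincidental A->B match is rarely mirrored
#' by a B->A match.
#'
#' @param nnf an `offset_field` from [patchmatch_nnf()].
#' @param tol_px tolerance in pixels.
#' @return logical matrix of retained pixels.
#' @export
bidirectional_filter <- function(nnf, tol_px = 2L) {
  stopifnot(inherits(nnf, "offset_field"))
  rows <- nrow(nnf$dr); cols <- ncol(nnf$dr)
  keep <- matrix(FALSE, rows, cols)
  idx <- which(nnf$valid)
  if (!length(idx)) return(keep)
  r <- (idx - 1L) %% rows
  c <- (idx - 1L) %/% rows
  qr <- r + nnf$dr[idx]
  qc <- c + nnf$dc[idx]
  inb <- qr >= 0L & qr < rows & qc >= 0L & qc < cols
  qidx <- qr + rows * qc + 1L
  ok <- inb
  ok[inb] <- nnf$valid[qidx[inb]] &
    pmax(abs(nnf$dr[qidx[inb]] + nnf$dr[idx[inb]]),
         abs(nnf$dc[qidx[inb]] + nnf$dc[idx[inb]])) <= tol_px
  if (!is.null(nnf$mirrored))  # both directions must agree on mirroring
    ok[inb] <- ok[inb] &
      (nnf$mirrored[qidx[inb]] == nnf$mirrored[idx[inb]])
  keep[idx[ok]] <- TRUE
  keep
}

#' Dense-linear-fitting and morphological post-processing
#'
#' Cleans the bidirectionally confirmed match set into a clone mask:
#' offsets are median-filtered over kept pixels, each pixel is tested
#' against a local affine offset model (the dense-linear-fitting test;
#' squared residual above `cfg$dlf_error_thresh` drops the pixel),
#' connected regions smaller than `cfg$min_region_px` are removed, every
#' surviving pixel's partner `p + f(p)` is marked so source and destination
#' both appear, and the result is dilated by `cfg$dilation_radius_px`.
#'
#' The returned mask carries attributes for auditability: `filtered` (the
#' mask of pixels surviving the affine test and region-size pruning),
#' `pre_dilation` (the mask before dilation, in which every `filtered`
#' pixel's partner is marked) and `offsets` (the median-filtered
#' `dr`/`dc`).
#'
#' @param nnf an `offset_field`.
#' @param keep logical matrix from [bidirectional_filter()].
#' @param cfg a [copymove_config()].
#' @return logical clone mask.
#' @export
dlf_postprocess <- function(nnf, keep, cfg = copymove_config()) {
  stopifnot(inherits(nnf, "offset_field"), is.logical(keep),
            all(dim(keep) == dim(nnf$dr)))
  rows <- nrow(keep); cols <- ncol(keep)
  empty <- matrix(FALSE, rows, cols)
  if (!any(keep)) {
    return(structure(empty, pre_dilation = empty, filtered = empty,
                     offsets = list(dr = nnf$dr, dc = nnf$dc)))
  }
  # plain and mirrored matches follow different local offset models, so
  # the median filter and affine fit run separately per flag
  parts <- if (is.null(nnf$mirrored) || !any(nnf$mirrored & keep))
    list(keep)
  else list(keep & !nnf$mirrored, keep & nnf$mirrored)
  m <- matrix(FALSE, rows, cols)
  fdr <- nnf$dr; fdc <- nnf$dc
  for (part in parts) {
    if (!any(part)) next
    f <- dlf_filter(nnf$dr, nnf$dc, part,
                    as.integer(cfg$median_window_px),
                    cfg$dlf_error_thresh, 6L)
    m <- m | f$keep
    fdr[part] <- f$dr[part]
    fdc[part] <- f$dc[part]
  }
  m <- drop_small_regions(m, cfg$min_region_px)
  # mark partners so source and destination are both in the mask
  pre <- mark_partners(m, fdr, fdc)
  out <- dilate_mask(pre, cfg$dilation_radius_px)
  structure(out, pre_dilation = pre, filtered = m,
            offsets = list(dr = fdr, dc = fdc))
}

# Noise-floor rejection: cloned pixels match their copy at near-zero
# cost (the pixel noise was copied along), whereas coincidental matches
# between unrelated regions cost at least the noise floor, estimated by
# the median match cost over the field.
below_noise_floor <- function(nnf, frac) {
  floor_est <- median(nnf$cost[nnf$valid])
  nnf$cost <= frac * floor_est
}

drop_small_regions <- function(m, min_px) {
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m)
  cnt <- tabulate(lab[lab > 0])
  small <- which(cnt < min_px)
  if (length(small)) m[lab %in% small] <- FALSE
  m
}

mark_partners <- function(m, dr, dc) {
  idx <- which(m)
  if (!length(idx)) return(m)
  rows <- nrow(m)
  r <- (idx - 1L) %% rows + dr[idx]
  c <- (idx - 1L) %/% rows + dc[idx]
  inb <- r >= 0L & r < rows & c >= 0L & c < ncol(m)
  m[r[inb] + rows * c[inb] + 1L] <- TRUE
  m
}

dilate_mask <- function(m, radius) {
  if (!any(m) || radius < 1L) return(m)
  EBImage::dilate(m, EBImage::makeBrush(2L * radius + 1L, "disc")) > 0
}

#' Copy-move detection on a pair of panels
#'
#' The two panels are placed side by side on a canvas separated by a
#' neutral gutter wide enough that no patch spans both, and the full branch
#' pipeline (dense features, nearest-neighbor field, bidirectional
#' constraint, dense-linear-fitting post-processing) runs on the canvas for
#' the Zernike and the RGB branch; the canvas masks are then split back
#' into panel-local masks. When `panel_a` and `panel_b` are the same panel
#' (a self pair), the panel is analyzed alone, which finds clones within
#' it.
#'
#' @param panel_a,panel_b images (text-erased panels); pass the identical
#'   object, or set `self = TRUE`, for a self pair.
#' @param cfg a [copymove_config()].
#' @param self force self-pair treatment.
#' @return list with per-branch panel masks:
#'   `zernike = list(a, b)`, `rgb = list(a, b)`, and `fused = list(a, b)`
#'   combined according to `cfg$fusion`. For a self pair the `b` masks
#'   equal the `a` masks.
#' @export
detect_pair <- function(panel_a, panel_b, cfg = copymove_config(),
                        self = identical(panel_a, panel_b)) {
  assert_image(panel_a)
  da <- img_dims(panel_a)
  support_min <- max(2L * cfg$zernike_radius_px + 1L, cfg$rgb_patch_px + 1L)
  mka <- function() matrix(FALSE, da[1], da[2])
  if (self) {
    if (min(da) < support_min || max(da) <= cfg$min_offset_px) {
      warning("panel smaller than the feature support; pair skipped")
      e <- mka()
      return(list(zernike = list(a = e, b = e), rgb = list(a = e, b = e),
                  fused = list(a = e, b = e)))
    }
    za <- branch_mask(panel_a, NULL, cfg, "zernike")
    ra <- branch_mask(panel_a, NULL, cfg, "rgb")
    fa <- fuse_masks(za$a, ra$a, cfg$fusion)
    return(list(zernike = list(a = za$a, b = za$a),
                rgb = list(a = ra$a, b = ra$a),
                fused = list(a = fa, b = fa)))
  }
  assert_image(panel_b)
  db <- img_dims(panel_b)
  mkb <- function() matrix(FALSE, db[1], db[2])
  if (min(da) < support_min || min(db) < support_min) {
    warning("panel smaller than the feature support; pair skipped")
    return(list(zernike = list(a = mka(), b = mkb()),
                rgb = list(a = mka(), b = mkb()),
                fused = list(a = mka(), b = mkb())))
  }
  z <- branch_mask(panel_a, panel_b, cfg, "zernike")
  r <- branch_mask(panel_a, panel_b, cfg, "rgb")
  list(zernike = z, rgb = r,
       fused = list(a = fuse_masks(z$a, r$a, cfg$fusion),
                    b = fuse_masks(z$b, r$b, cfg$fusion)))
}

fuse_masks <- function(a, b, fusion) if (fusion == "and") a & b else a | b

# Run one feature branch on a panel (panel_b = NULL) or a panel pair
# composed onto a shared canvas, and return panel-local masks.
branch_mask <- function(panel_a, panel_b, cfg, branch) {
  if (is.null(panel_b)) {
    canvas <- panel_a
    support <- NULL
    split_a <- list(rows = 1:nrow(as_gray(panel_a)), cols = 1:ncol(as_gray(panel_a)))
    split_b <- NULL
  } else {
    comp <- compose_pair_canvas(panel_a, panel_b, 2L * cfg$zernike_radius_px)
    canvas <- comp$canvas; support <- comp$support
    split_a <- comp$a; split_b <- comp$b
  }
  field <- if (branch == "zernike") {
    zernike_field(canvas, cfg$zernike_radius_px, cfg$zernike_order,
                  min_patch_sd = cfg$min_patch_sd, support = support)
  } else {
    rgb_field(canvas, cfg$rgb_patch_px, min_patch_sd = cfg$min_patch_sd,
              support = support)
  }
  mask <- if (!any(field$valid)) {
    matrix(FALSE, nrow(field$valid), ncol(field$valid))
  } else {
    nnf <- patchmatch_nnf(field, cfg$pm_iterations, cfg$min_offset_px,
                          cfg$seed, match_mirrored = (branch == "rgb"))
    keep <- bidirectional_filter(nnf, cfg$bidir_tol_px)
    keep <- keep & below_noise_floor(nnf, cfg$max_cost_frac)
    dlf_postprocess(nnf, keep, cfg)
  }
  if (is.null(split_b)) return(list(a = mask[split_a$rows, split_a$cols, drop = FALSE]))
  list(a = mask[split_a$rows, split_a$cols, drop = FALSE],
       b = mask[split_b$rows, split_b$cols, drop = FALSE])
}

# Side-by-side composition of two panels with a neutral gutter; the
# support mask excludes gutter and height-padding pixels.
compose_pair_canvas <- function(panel_a, panel_b, gutter) {
  nch <- max(img_channels(panel_a), img_channels(panel_b))
  if (nch == 3L) { panel_a <- as_rgb(panel_a); panel_b <- as_rgb(panel_b) }
  da <- img_dims(panel_a); db <- img_dims(panel_b)
  rows <- max(da[1], db[1])
  cols <- da[2] + gutter + db[2]
  neutral <- median(c(as_gray(panel_a), as_gray(panel_b)))
  canvas <- if (nch == 3L) array(neutral, c(rows, cols, 3L))
  else matrix(neutral, rows, cols)
  support <- matrix(FALSE, rows, cols)
  a_rows <- 1:da[1]; a_cols <- 1:da[2]
  b_rows <- 1:db[1]; b_cols <- (da[2] + gutter + 1L):cols
  if (nch == 3L) {
    canvas[a_rows, a_cols, ] <- panel_a
    canvas[b_rows, b_cols, ] <- panel_b
  } else {
    canvas[a_rows, a_cols] <- panel_a
    canvas[b_rows, b_cols] <- panel_b
  }
  support[a_rows, a_cols] <- TRUE
  support[b_rows, b_cols] <- TRUE
  list(canvas = canvas, support = support,
       a = list(rows = a_rows, cols = a_cols),
       b = list(rows = b_rows, cols = b_cols))
}

#' Copy-move detection on a whole figure
#'
#' End-to-end detector: the figure is split into panels (the record's
#' `panels` if present, otherwise [segment_panels()]; the whole figure is
#' used as a single panel when nothing is found), text is localized and
#' erased per panel, every unordered panel pair (including self pairs) goes
#' through [detect_pair()], and the per-branch masks are assembled by OR in
#' figure coordinates. The final mask combines the Zernike and RGB branch
#' masks according to `cfg$fusion` (union by default: each branch catches
#' cases the other misses).
#'
#' @param figure a [figure_record()].
#' @param cfg a [copymove_config()].
#' @return a `clone_report`: list with `figure_id`, `final_mask`,
#'   `zernike_mask`, `rgb_mask`, `panels` (the box table used) and
#'   `pair_details` (per-pair panel indices and branch masks).
#' @export
detect_copy_move <- function(figure, cfg = copymove_config()) {
  stopifnot(inherits(figure, "figure_record"))
  d <- img_dims(figure$image)
  panels <- figure$panels
  if (!nrow(panels)) panels <- segment_panels(figure$image)
  if (!nrow(panels)) panels <- boxes(0L, 0L, d[1], d[2])
  crops <- crop_panels(figure$image, panels)
  cleaned <- lapply(crops, function(p) {
    erase_regions(p, detect_text_regions(p))
  })
  zmask <- matrix(FALSE, d[1], d[2])
  rmask <- matrix(FALSE, d[1], d[2])
  pair_details <- list()
  n <- length(cleaned)
  for (i in seq_len(n)) for (j in i:n) {
    res <- withCallingHandlers(
      detect_pair(cleaned[[i]], cleaned[[j]], cfg, self = (i == j)),
      warning = function(w) invokeRestart("muffleWarning"))
    zmask <- paste_mask(zmask, res$zernike$a, panels[i, ])
    rmask <- paste_mask(rmask, res$rgb$a, panels[i, ])
    if (j != i) {
      zmask <- paste_mask(zmask, res$zernike$b, panels[j, ])
      rmask <- paste_mask(rmask, res$rgb$b, panels[j, ])
    }
    pair_details[[length(pair_details) + 1L]] <-
      list(i = i, j = j, zernike = res$zernike, rgb = res$rgb)
  }
  structure(list(figure_id = figure$id,
                 final_mask = fuse_masks(zmask, rmask, cfg$fusion),
                 zernike_mask = zmask, rgb_mask = rmask,
                 panels = panels, pair_details = pair_details),
            class = "clone_report")
}

paste_mask <- function(full, panel_mask, box) {
  ri <- (box$r0 + 1L):box$r1
  ci <- (box$c0 + 1L):box$c1
  full[ri, ci] <- full[ri, ci] | panel_mask
  full
}

#' @export
print.clone_report <- function(x, ...) {
  cat(sprintf("<clone_report '%s': %d panel(s), final mask %d px (%.2f%%), zernike %d px, rgb %d px>\n",
              x$figure_id, nrow(x$panels), sum(x$final_mask),
              100 * mean(x$final_mask), sum(x$zernike_mask),
              sum(x$rgb_mask)))
  invisible(x)
}
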