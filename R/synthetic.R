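# Seeded generator of scientific-figure phantoms with full ground truth:
# western-blot-like band panels, micrograph-like blob panels, iso-luminant
# chroma panels, multi-panel composition with rendered labels, planted
# clones, and cross-"paper" reuse chains with publication dates. All
# appearance parameters are fixture constants chosen to resemble the
# imagery class, not claims about real data; every op is bit-reproducible
# from its seed.

#' Western-blot-like phantom panel
#'
#' Light background (base intensity drawn from 220-240) with dark,
#' Gaussian-blurred elliptical bands arranged in lanes, plus additive
#' Gaussian noise of sd 3. Band geometry is recorded in the `bands`
#' attribute (`row`, `col` center, `rx`, `ry` half-axes, `amp` intensity).
#'
#' @param seed integer seed; the panel is a deterministic function of it.
#' @param lanes number of lanes (0 gives a blank noise panel).
#' @param bands_per_lane bands per lane.
#' @param size `c(rows, cols)`, at least 64 x 64.
#' @return grayscale image matrix.
#' @export
make_blot_panel <- function(seed, lanes = 4L, bands_per_lane = 3L,
                            size = c(128L, 160L)) {
  stopifnot(all(size >= 64L))
  rows <- size[1]; cols <- size[2]
  with_seed(seed, {
    base <- runif(1, 220, 240)
    img <- matrix(base, rows, cols)
    meta <- list()
    lane_w <- cols / max(lanes, 1L)
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    for (lane in seq_len(lanes)) {
      cx <- (lane - 0.5) * lane_w
      for (b in seq_len(bands_per_lane)) {
        cy <- (b - 0.5) * rows / bands_per_lane + runif(1, -4, 4)
        rx <- runif(1, 0.30, 0.45) * lane_w
        ry <- runif(1, 3, 6)
        amp <- runif(1, 40, 110)
        inside <- ((cc - cx) / rx)^2 + ((rr - cy) / ry)^2 <= 1
        img[inside] <- pmin(img[inside], amp)
        meta[[length(meta) + 1L]] <-
          data.frame(row = cy, col = cx, rx = rx, ry = ry, amp = amp)
      }
    }
    img <- EBImage::gblur(img, 1.2)
    img <- clamp8(img + rnorm(rows * cols, 0, 3))
    attr(img, "bands") <- if (length(meta)) do.call(rbind, meta)
    else data.frame(row = numeric(), col = numeric(), rx = numeric(),
                    ry = numeric(), amp = numeric())
    attr(img, "background") <- base
    attr(img, "blur_sigma") <- 1.2
    img
  })
}

#' Micrograph-like phantom panel
#'
#' Textured dark background with `n_cells` bright Gaussian blobs of random
#' radius 5-15 px placed with enough separation to stay countable, under
#' Poisson noise. Blob geometry is recorded in the `cells` attribute.
#'
#' @param seed integer seed.
#' @param n_cells number of blobs (0 gives a blank textured panel).
#' @param size `c(rows, cols)`, at least 64 x 64.
#' @return grayscale image matrix.
#' @export
make_micrograph_panel <- function(seed, n_cells = 8L,
                                  size = c(128L, 160L)) {
  stopifnot(all(size >= 64L))
  rows <- size[1]; cols <- size[2]
  with_seed(seed, {
    tex <- EBImage::gblur(matrix(rnorm(rows * cols), rows, cols), 3)
    tex <- tex / stats::sd(tex) * 6
    img <- 30 + tex
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    placed <- data.frame(row = numeric(), col = numeric(),
                         radius = numeric(), amp = numeric())
    for (i in seq_len(n_cells)) {
      for (try in 1:200) {
        rad <- runif(1, 5, 15)
        cy <- runif(1, rad + 2, rows - rad - 2)
        cx <- runif(1, rad + 2, cols - rad - 2)
        if (!nrow(placed) ||
            all(sqrt((placed$row - cy)^2 + (placed$col - cx)^2) >
                placed$radius + rad + 6)) {
          amp <- runif(1, 160, 220)
          img <- img + amp * exp(-((rr - cy)^2 + (cc - cx)^2) /
                                   (2 * (rad / 2)^2))
          placed <- rbind(placed, data.frame(row = cy, col = cx,
                                             radius = rad, amp = amp))
          break
        }
      }
    }
    img <- clamp8(rpois(rows * cols, lambda = pmax(img, 0)))
    img <- matrix(img, rows, cols)
    attr(img, "cells") <- placed
    img
  })
}

#' Iso-luminant chroma phantom panel
#'
#' A color panel whose luma is constant (smooth chroma noise around a
#' fixed luminance of 128): luminance-based features are blind to it, so
#' clones planted here can only be caught by a branch that looks at the
#' actual color values. Used to exercise the RGB branch of the copy-move
#' fusion in isolation.
#'
#' @param seed integer seed.
#' @param size `c(rows, cols)`, at least 64 x 64.
#' @return rows x cols x 3 image array.
#' @export
make_isoluminant_panel <- function(seed, size = c(128L, 160L)) {
  stopifnot(all(size >= 64L))
  rows <- size[1]; cols <- size[2]
  with_seed(seed, {
    smooth_field <- function() {
      f <- EBImage::gblur(matrix(rnorm(rows * cols), rows, cols), 2.5)
      f / stats::sd(f) * 20
    }
    cb <- smooth_field(); cr <- smooth_field()
    y <- 128
    img <- array(0, c(rows, cols, 3L))
    img[, , 1] <- y + 1.402 * cr
    img[, , 2] <- y - 0.344136 * cb - 0.714136 * cr
    img[, , 3] <- y + 1.772 * cb
    clamp8(img)
  })
}

# 5x7 bitmap glyphs used for phantom labels (no font dependency).
label_glyphs <- function() {
  dec <- function(s) {
    m <- matrix(as.integer(strsplit(gsub("\n", "", s), "")[[1]]), 7, 5,
                byrow = TRUE)
    m > 0
  }
  list(
    A = dec("01110100011000111111100011000110001"),
    B = dec("11110100011000111110100011000111110"),
    C = dec("01111100001000010000100001000001111"),
    E = dec("11111100001000011110100001000011111"),
    F = dec("11111100001000011110100001000010000"),
    H = dec("10001100011000111111100011000110001"))
}

render_label <- function(canvas, r0, c0, text, scale = 2L, ink = 20) {
  glyphs <- label_glyphs()
  chars <- strsplit(text, "")[[1]]
  c_at <- c0
  nch <- img_channels(canvas)
  for (ch in chars) {
    gl <- glyphs[[ch]]
    big <- gl[rep(seq_len(7), each = scale), rep(seq_len(5), each = scale)]
    ri <- r0 + seq_len(nrow(big)) - 1L
    ci <- c_at + seq_len(ncol(big)) - 1L
    if (max(ri) <= nrow(canvas) && max(ci) <= ncol(canvas)) {
      if (nch == 1L) {
        block <- canvas[ri, ci]
        block[big] <- ink
        canvas[ri, ci] <- block
      } else {
        for (k in 1:3) {
          block <- canvas[ri, ci, k]
          block[big] <- ink
          canvas[ri, ci, k] <- block
        }
      }
    }
    c_at <- c_at + ncol(big) + 2L
  }
  canvas
}

#' Compose panels into a multi-panel figure
#'
#' Panels are placed on a white canvas in an `nr x nc` grid with 12-px
#' gutters and margins; with `label_text = TRUE` a short glyph label is
#' rendered above each panel. Returns the figure together with the ground
#' truth: the panel boxes and the text boxes.
#'
#' @param panels list of images (grayscale and color may be mixed).
#' @param grid `c(nr, nc)`; `nr * nc` must cover `length(panels)`.
#' @param label_text render a label strip above each panel.
#' @param seed seed for label glyph choice.
#' @param labels optional character vector (over glyphs A,B,C,E,F,H) of
#'   per-panel labels, overriding the random ones.
#' @return list with `figure` (image), `panel_boxes` and `text_boxes`
#'   (box tables).
#' @export
compose_figure <- function(panels, grid, label_text = FALSE, seed = 0L,
                           labels = NULL) {
  nr <- grid[1]; nc <- grid[2]
  stopifnot(length(panels) <= nr * nc, length(panels) >= 1L)
  color <- any(vapply(panels, img_channels, integer(1)) == 3L)
  margin <- 12L; gutter <- 12L
  strip <- if (label_text) 18L else 0L
  ph <- vapply(panels, function(p) img_dims(p)[1], integer(1))
  pw <- vapply(panels, function(p) img_dims(p)[2], integer(1))
  at <- function(i, j) (i - 1L) * nc + j
  row_h <- vapply(seq_len(nr), function(i) {
    ks <- at(i, seq_len(nc)); ks <- ks[ks <= length(panels)]
    if (!length(ks)) 0L else max(ph[ks])
  }, integer(1))
  col_w <- vapply(seq_len(nc), function(j) {
    ks <- at(seq_len(nr), j); ks <- ks[ks <= length(panels)]
    if (!length(ks)) 0L else max(pw[ks])
  }, integer(1))
  rows <- 2L * margin + sum(row_h) + (nr - 1L) * gutter + nr * strip
  cols <- 2L * margin + sum(col_w) + (nc - 1L) * gutter
  canvas <- if (color) array(255, c(rows, cols, 3L)) else
    matrix(255, rows, cols)
  panel_boxes <- empty_boxes()
  text_boxes <- empty_boxes()
  with_seed(seed, {
    glyph_names <- names(label_glyphs())
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      k <- at(i, j)
      if (k > length(panels)) next
      r0 <- margin + if (i > 1L) sum(row_h[1:(i - 1L)]) +
        (i - 1L) * gutter else 0L
      r0 <- r0 + i * strip
      c0 <- margin + if (j > 1L) sum(col_w[1:(j - 1L)]) +
        (j - 1L) * gutter else 0L
      p <- panels[[k]]
      ri <- r0 + seq_len(ph[k]); ci <- c0 + seq_len(pw[k])
      if (color) {
        p3 <- as_rgb(p)
        for (ch in 1:3) canvas[ri, ci, ch] <- p3[, , ch]
      } else canvas[ri, ci] <- p
      panel_boxes <- rbind(panel_boxes,
                           boxes(r0, c0, r0 + ph[k], c0 + pw[k]))
      if (label_text) {
        lab <- if (!is.null(labels)) labels[k] else
          paste(sample(glyph_names, 4L, replace = TRUE), collapse = "")
        tr0 <- r0 - strip + 2L
        canvas <- render_label(canvas, tr0 + 1L, c0 + 1L, lab)
        tw <- nchar(lab) * (10L + 2L)
        text_boxes <- rbind(text_boxes,
                            boxes(tr0, c0, tr0 + 14L,
                                  min(c0 + tw, cols)))
      }
    }
  })
  list(figure = canvas, panel_boxes = panel_boxes, text_boxes = text_boxes)
}

#' Plant a clone inside a figure
#'
#' Copies the `src` region, applies the requested transform, and pastes it
#' with its top-left corner at `dst_anchor`. The returned mask is true
#' exactly on the source region and the destination footprint, which must
#' be disjoint from the source and inside the image.
#'
#' @param figure image.
#' @param src single-row box table: the source region.
#' @param dst_anchor `c(row, col)` 0-based top-left corner of the pasted
#'   region.
#' @param transform `"none"`, `"mirror_h"`, `"rot90"` or `"rot180"`.
#' @param seed reserved for future appearance jitter; unused.
#' @return list with `image` and logical `mask`.
#' @export
plant_clone <- function(figure, src, dst_anchor,
                        transform = c("none", "mirror_h", "rot90",
                                      "rot180"),
                        seed = 0L) {
  assert_image(figure)
  transform <- match.arg(transform)
  d <- img_dims(figure)
  src <- validate_boxes(src, d[1], d[2])
  stopifnot(nrow(src) == 1L)
  nch <- img_channels(figure)
  take <- function(img) {
    ri <- (src$r0 + 1L):src$r1; ci <- (src$c0 + 1L):src$c1
    if (nch == 1L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
  }
  tf1 <- function(m) switch(transform,
                            none = m,
                            mirror_h = m[, rev(seq_len(ncol(m))), drop = FALSE],
                            rot90 = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
                            rot180 = m[rev(seq_len(nrow(m))),
                                       rev(seq_len(ncol(m))), drop = FALSE])
  block <- take(figure)
  tblock <- if (nch == 1L) tf1(block) else {
    ch <- lapply(1:3, function(k) tf1(block[, , k]))
    array(c(ch[[1]], ch[[2]], ch[[3]]), c(dim(ch[[1]]), 3L))
  }
  th <- dim(tblock)[1]; tw <- dim(tblock)[2]
  dst <- boxes(dst_anchor[1], dst_anchor[2], dst_anchor[1] + th,
               dst_anchor[2] + tw)
  if (dst$r1 > d[1] || dst$c1 > d[2])
    stop("clone destination exceeds image bounds", call. = FALSE)
  overlap <- max(src$r0, dst$r0) < min(src$r1, dst$r1) &&
    max(src$c0, dst$c0) < min(src$c1, dst$c1)
  if (overlap)
    stop("clone destination overlaps the source region", call. = FALSE)
  out <- figure
  ri <- (dst$r0 + 1L):dst$r1; ci <- (dst$c0 + 1L):dst$c1
  if (nch == 1L) out[ri, ci] <- tblock else out[ri, ci, ] <- tblock
  mask <- boxes_to_mask(rbind(src, dst), d[1], d[2])
  list(image = out, mask = mask)
}

resize_bilinear <- function(img, rows, cols) {
  d <- img_dims(img)
  mapn <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(x, 0), n_in - 1)
  }
  r <- mapn(rows, d[1]); c <- mapn(cols, d[2])
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, d[1] - 1); c1 <- pmin(c0 + 1, d[2] - 1)
  one <- function(m) {
    a <- m[r0 + 1, c0 + 1, drop = FALSE] * outer(1 - fr, 1 - fc)
    b <- m[r0 + 1, c1 + 1, drop = FALSE] * outer(1 - fr, fc)
    cte <- m[r1 + 1, c0 + 1, drop = FALSE] * outer(fr, 1 - fc)
    dd <- m[r1 + 1, c1 + 1, drop = FALSE] * outer(fr, fc)
    a + b + cte + dd
  }
  if (img_channels(img) == 1L) one(img)
  else {
    ch <- lapply(1:3, function(k) one(img[, , k]))
    array(c(ch[[1]], ch[[2]], ch[[3]]), c(rows, cols, 3L))
  }
}

# One derivation step of a reuse chain: crop (>= 50% area), resize
# (0.8-1.2x), brightness shift (+/-10), optional horizontal mirror.
derive_figure <- function(img) {
  d <- img_dims(img)
  s <- runif(2, 0.75, 0.92)           # per-side crop scale; area >= 0.56
  h <- max(32L, round(d[1] * s[1])); w <- max(32L, round(d[2] * s[2]))
  r0 <- sample.int(d[1] - h + 1L, 1L) - 1L
  c0 <- sample.int(d[2] - w + 1L, 1L) - 1L
  out <- crop_panels(img, boxes(r0, c0, r0 + h, c0 + w))[[1]]
  f <- runif(1, 0.8, 1.2)
  out <- resize_bilinear(out, max(32L, round(h * f)),
                         max(32L, round(w * f)))
  out <- out + round(runif(1, -10, 10))
  if (runif(1) < 0.3) {
    out <- if (img_channels(out) == 1L)
      out[, rev(seq_len(ncol(out))), drop = FALSE]
    else out[, rev(seq_len(ncol(out))), , drop = FALSE]
  }
  clamp8(out)
}

#' Generate a cross-paper figure-reuse case
#'
#' Builds `reuses_per_paper` reuse chains: each chain starts from its own
#' root figure (micrograph plus blot panels) in the first "paper", and
#' every later paper's figure in the chain is derived from the previous
#' paper's by a composed crop/resize/brightness/mirror step, so content
#' degrades monotonically along the chain. Paper dates increase strictly
#' with paper index, DOIs are `10.0000/synthetic.<paper>`, and the
#' generation edges (parent to child, which always runs earlier to later)
#' form the ground-truth provenance graph.
#'
#' @param n_papers number of papers (>= 2).
#' @param reuses_per_paper number of parallel reuse chains.
#' @param seed integer seed; the whole case is deterministic in it.
#' @return a `synthetic_case`: list with `figures` (list of
#'   [figure_record()]), `truth_masks`, `truth_boxes`, `truth_graph` and
#'   `seed`.
#' @export
make_reuse_case <- function(n_papers, reuses_per_paper = 1L, seed = 0L) {
  stopifnot(n_papers >= 2L)
  with_seed(seed, {
    dates <- as.Date("2014-01-01") + cumsum(c(0L, sample(30:120,
                                                         n_papers - 1L,
                                                         replace = TRUE)))
    figures <- list()
    edges <- data.frame(source = character(), target = character(),
                        weight = integer(), stringsAsFactors = FALSE)
    truth_boxes <- list()
    k <- 0L
    for (u in seq_len(reuses_per_paper)) {
      comp <- compose_figure(list(make_micrograph_panel(seed + 2L * u, 7L,
                                                        c(120L, 150L)),
                                  make_blot_panel(seed + 2L * u + 1L, 4L,
                                                  3L, c(120L, 150L))),
                             grid = c(1L, 2L))
      k <- k + 1L
      root_id <- paste0("fig", k)
      figures[[k]] <- figure_record(root_id, comp$figure,
                                    doi = "10.0000/synthetic.1",
                                    date = dates[1],
                                    panels = comp$panel_boxes)
      truth_boxes[[root_id]] <- comp$panel_boxes
      parent <- k
      for (p in 2L:n_papers) {
        k <- k + 1L
        id <- paste0("fig", k)
        img <- derive_figure(figures[[parent]]$image)
        figures[[k]] <- figure_record(id, img,
                                      doi = paste0("10.0000/synthetic.", p),
                                      date = dates[p])
        edges <- rbind(edges,
                       data.frame(source = figures[[parent]]$id,
                                  target = id, weight = 1L,
                                  stringsAsFactors = FALSE))
        truth_boxes[[id]] <- empty_boxes()
        parent <- k
      }
    }
    nodes <- data.frame(
      figure_id = vapply(figures, function(f) f$id, character(1)),
      doi = vapply(figures, function(f) f$doi, character(1)),
      stringsAsFactors = FALSE)
    nodes$date <- do.call(c, lapply(figures, function(f) f$date))
    structure(list(figures = figures,
                   truth_masks = list(),
                   truth_boxes = truth_boxes,
                   truth_graph = provenance_graph(nodes, edges),
                   seed = seed),
              class = "synthetic_case")
  })
}

#' Generate a figure with a planted clone
#'
#' Convenience constructor of the copy-move study conditions: a two-panel
#' figure with a clone planted from the first panel into the second
#' (`kind = "blot"` or `"micrograph"`), or a single iso-luminant chroma
#' panel with an internal clone (`kind = "color"`, catchable only through
#' the raw color values). The source region is centered on generated
#' content (a band or a cell) so the clone carries real structure.
#'
#' @param seed integer seed.
#' @param transform clone transform, as in [plant_clone()].
#' @param kind `"blot"`, `"micrograph"` or `"color"`.
#' @return list with `figure` (a [figure_record()] whose `panels` are the
#'   truth boxes) and the truth `mask`.
#' @export
make_clone_case <- function(seed,
                            transform = c("none", "mirror_h", "rot90",
                                          "rot180"),
                            kind = c("blot", "micrograph", "color")) {
  transform <- match.arg(transform)
  kind <- match.arg(kind)
  with_seed(seed + 1000L, {
    if (kind == "color") {
      panel <- make_isoluminant_panel(seed, c(128L, 170L))
      comp <- compose_figure(list(panel), grid = c(1L, 1L))
      pb <- comp$panel_boxes
      src <- boxes(pb$r0[1] + 24L, pb$c0[1] + 20L,
                   pb$r0[1] + 24L + 36L, pb$c0[1] + 20L + 48L)
      dst <- c(pb$r0[1] + 68L, pb$c0[1] + 98L)
    } else {
      mk <- function(s) {
        if (kind == "blot") make_blot_panel(s, 4L, 3L, c(128L, 160L))
        else make_micrograph_panel(s, 7L, c(128L, 160L))
      }
      p1 <- mk(seed); p2 <- mk(seed + 1L)
      comp <- compose_figure(list(p1, p2), grid = c(1L, 2L))
      pb <- comp$panel_boxes
      # center the source on generated content inside panel 1
      ctr <- if (kind == "blot") {
        b <- attr(p1, "bands"); b[which.min(b$amp), ]
      } else {
        cl <- attr(p1, "cells"); cl[which.max(cl$radius), ]
      }
      h <- 36L; w <- 48L
      r0 <- round(min(max(ctr$row - h / 2, 10), 128 - h - 10))
      c0 <- round(min(max(ctr$col - w / 2, 10), 160 - w - 10))
      src <- boxes(pb$r0[1] + r0, pb$c0[1] + c0,
                   pb$r0[1] + r0 + h, pb$c0[1] + c0 + w)
      dst <- c(pb$r0[2] + sample(15:70, 1L), pb$c0[2] + sample(15:100, 1L))
      if (transform == "rot90") dst <- c(pb$r0[2] + sample(15:60, 1L),
                                         pb$c0[2] + sample(15:110, 1L))
    }
    planted <- plant_clone(comp$figure, src, dst, transform)
    fig <- figure_record(paste0("clone", seed), planted$image,
                         panels = comp$panel_boxes)
    list(figure = fig, mask = planted$mask)
  })
}

#' Generate a pristine multi-panel phantom figure
#'
#' A labelled two-panel figure (blot plus micrograph) with no planted
#' manipulation; used to measure false-positive rates.
#'
#' @param seed integer seed.
#' @param label_text render glyph labels above the panels.
#' @return a [figure_record()] with truth `panels` and `text_regions`.
#' @export
make_pristine_figure <- function(seed, label_text = TRUE) {
  comp <- compose_figure(list(make_blot_panel(seed, 4L, 3L, c(128L, 160L)),
                              make_micrograph_panel(seed + 1L, 7L,
                                                    c(128L, 160L))),
                         grid = c(1L, 2L), label_text = label_text,
                         seed = seed)
  figure_record(paste0("pristine", seed), comp$figure,
                panels = comp$panel_boxes,
                text_regions = comp$text_boxes)
}
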