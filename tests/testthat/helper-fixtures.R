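# Independent flood-fill oracle for connected-component labeling, written
# against the definition: repeatedly pick the first unlabeled foreground
# pixel in raster-scan order (by row, then column) and flood its region via
# a FIFO queue. Kept deliberately separate from the package's labeling code.
oracle_label <- function(fg, connectivity = 8L) {
  h <- nrow(fg)
  w <- ncol(fg)
  lab <- matrix(0L, h, w)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  k <- 0L
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      if (!fg[r, cc] || lab[r, cc] != 0L) next
      k <- k + 1L
      qr <- integer(h * w)
      qc <- integer(h * w)
      qr[1] <- r
      qc[1] <- cc
      head_i <- 1L
      tail_i <- 1L
      lab[r, cc] <- k
      while (head_i <= tail_i) {
        cr <- qr[head_i]
        ccur <- qc[head_i]
        head_i <- head_i + 1L
        for (d in seq_along(dr)) {
          r2 <- cr + dr[d]
          c2 <- ccur + dc[d]
          if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w &&
            fg[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- k
            tail_i <- tail_i + 1L
            qr[tail_i] <- r2
            qc[tail_i] <- c2
          }
        }
      }
    }
  }
  lab
}

random_mask <- function(h, w, p = 0.35) {
  px <- matrix(0, h, w)
  px[matrix(runif(h * w) < p, h, w)] <- 128
  mask_map(px)
}

# Page with a hollow-rectangle "structure" outline, useful when a test
# needs exact, hand-checkable geometry rather than a procedural glyph.
rect_outline_page <- function(h = 400, w = 400, boxes, stroke = 4L) {
  px <- matrix(255, h, w)
  for (b in boxes) {
    x0 <- b[1]; y0 <- b[2]; x1 <- b[3]; y1 <- b[4]
    px[(y0 + 1):(y0 + stroke), (x0 + 1):x1] <- 0
    px[(y1 - stroke + 1):y1, (x0 + 1):x1] <- 0
    px[(y0 + 1):y1, (x0 + 1):(x0 + stroke)] <- 0
    px[(y0 + 1):y1, (x1 - stroke + 1):x1] <- 0
  }
  page_raster(px, source_id = "test", page_index = 0L)
}

as_crop <- function(pixels, box = NULL) {
  h <- dim(pixels)[1]
  w <- dim(pixels)[2]
  box <- box %||% detection_boxes(0L, 0L, w, h, expanded = TRUE)
  structure(
    list(pixels = pixels + 0, lineage = list(source_id = "test", page_index = 0L, box = box)),
    class = "crop_image"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
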