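#' Specification for synthetic document-page fixtures
#'
#' Describes the synthetic pages the fixture generator emulates: line-drawn
#' structure glyphs (procedurally fused 6-rings with pendant bond strokes) of
#' varying size, pseudo-text blocks, and small noise blobs planted adjacent
#' to glyphs, all with exact ground-truth boxes and masks. Generation is
#' fully deterministic for a fixed (spec, seed).
#'
#' @param page_width,page_height Page size in pixels (default 850 x 1100).
#' @param structures_per_page Inclusive range for the number of glyphs per
#'   page (default `c(1, 5)`).
#' @param glyph_size Target glyph extent range in px (default `c(120, 200)`).
#' @param stroke_width Stroke width of glyph line art in px (default 5).
#' @param text_blocks Range for the number of pseudo-text blocks (default
#'   `c(1, 3)`).
#' @param noise_blobs Range for the number of noise blobs per page (default
#'   `c(0, 2)`); each blob is planted inside some glyph's bounding box with
#'   clearance from its strokes, so it lands in the detector's crop and must
#'   be removed by PR filtering.
#' @param noise_radius Blob radius range in px (default `c(5, 7)`); blob area
#'   stays strictly below half the smallest glyph's pixel count, keeping the
#'   corpus separable at the default pixel-ratio threshold.
#' @param color_mode `"binary"` (black ink on white), `"grayscale"` (ink
#'   intensities 0-80) or `"colored"` (RGB page, ink randomly hued).
#' @param seed Corpus seed; per-page seeds are derived by fixed splitting.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(page_width = 850L, page_height = 1100L,
                         structures_per_page = c(1L, 5L),
                         glyph_size = c(120L, 200L), stroke_width = 5L,
                         text_blocks = c(1L, 3L), noise_blobs = c(0L, 2L),
                         noise_radius = c(5L, 7L), color_mode = "binary",
                         seed = 1L) {
  stopifnot(
    page_width >= 64, page_height >= 64, stroke_width >= 1,
    color_mode %in% c("binary", "grayscale", "colored")
  )
  structure(
    list(
      page_width = as.integer(page_width), page_height = as.integer(page_height),
      structures_per_page = as.integer(structures_per_page),
      glyph_size = as.integer(glyph_size), stroke_width = as.integer(stroke_width),
      text_blocks = as.integer(text_blocks), noise_blobs = as.integer(noise_blobs),
      noise_radius = as.integer(noise_radius), color_mode = color_mode,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# sample() treats a length-1 vector as 1:n; this draws safely from [a, b]
sample_range <- function(a, b) if (a >= b) a else sample(a:b, 1)

with_page_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# A glyph is a set of line segments: fused regular hexagons plus pendant
# bond strokes. Returns segment endpoints (in an arbitrary local frame) and
# the circumradius used.
glyph_segments <- function(size) {
  n_rings <- sample(1:3, 1)
  s <- size / (2 + 0.9 * (n_rings - 1))
  hex <- function(cx, cy) {
    ang <- (0:5) * pi / 3
    cbind(cx + s * cos(ang), cy + s * sin(ang))
  }
  centers <- matrix(c(0, 0), ncol = 2)
  apo2 <- sqrt(3) * s  # center distance of edge-fused hexagons
  while (nrow(centers) < n_rings) {
    base <- centers[sample(nrow(centers), 1), ]
    dir <- (pi / 6) + sample(0:5, 1) * pi / 3
    cand <- c(base[1] + apo2 * cos(dir), base[2] + apo2 * sin(dir))
    if (all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) > 0.5 * s)) {
      centers <- rbind(centers, cand)
    }
  }
  segs <- NULL
  verts <- NULL
  for (i in seq_len(nrow(centers))) {
    v <- hex(centers[i, 1], centers[i, 2])
    verts <- rbind(verts, v)
    segs <- rbind(segs, cbind(v, v[c(2:6, 1), ]))
  }
  # fused rings contribute their shared edge twice; canonicalize endpoint
  # order and deduplicate so segment lengths reflect actual coverage
  canon <- t(apply(segs, 1, function(sg) {
    a <- sg[1:2]
    b <- sg[3:4]
    if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) c(b, a) else c(a, b)
  }))
  segs <- unique(round(canon, 2))
  # pendant bond strokes from random vertices, pointing away from the centroid
  ctr <- colMeans(verts)
  n_pend <- sample(1:3, 1)
  vi <- sample(nrow(verts), n_pend)
  for (i in vi) {
    d <- verts[i, ] - ctr
    d <- d / max(sqrt(sum(d^2)), 1e-9)
    segs <- rbind(segs, c(verts[i, ], verts[i, ] + 0.55 * s * d))
  }
  list(segments = segs, side = s, n_rings = n_rings)
}

# Rasterize segments at the given stroke width; returns 0-based (x, y)
# pixel offsets relative to the glyph bounding box plus the box size.
rasterize_segments <- function(segments, stroke_width) {
  pts <- NULL
  for (i in seq_len(nrow(segments))) {
    a <- segments[i, 1:2]
    b <- segments[i, 3:4]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len * 2.5)))
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  r <- max(0L, floor(stroke_width / 2))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.5, ]
  px <- cbind(
    rep(round(pts[, 1]), each = nrow(off)) + off$dx,
    rep(round(pts[, 2]), each = nrow(off)) + off$dy
  )
  px <- unique(px)
  px[, 1] <- px[, 1] - min(px[, 1])
  px[, 2] <- px[, 2] - min(px[, 2])
  list(xy = px, width = max(px[, 1]) + 1L, height = max(px[, 2]) + 1L)
}

# Lower bound on a glyph's pixel count from its geometry: total stroke
# length times width minus a vertex-overlap allowance.
glyph_pixel_lower_bound <- function(segments, stroke_width) {
  lens <- sqrt((segments[, 3] - segments[, 1])^2 + (segments[, 4] - segments[, 2])^2)
  max(0, sum(lens) * stroke_width - nrow(segments) * stroke_width^2)
}

draw_text_block <- function(ink, x, y, width, n_lines) {
  h <- nrow(ink); w <- ncol(ink)
  line_h <- 10L
  spacing <- 30L  # line gap > detector merge gap, so lines stay separate blobs
  for (li in seq_len(n_lines)) {
    ly <- y + (li - 1L) * spacing
    if (ly + line_h > h) break
    cur <- x
    while (cur < x + width) {
      dash <- sample(5:14, 1)
      gap <- if (runif(1) < 0.2) sample(7:10, 1) else sample(2:4, 1)
      x2 <- min(cur + dash, x + width, w)
      if (x2 > cur) ink[(ly + 1L):(ly + line_h), (cur + 1L):x2] <- TRUE
      cur <- cur + dash + gap
    }
  }
  ink
}

disc_offsets <- function(r) {
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off[off$dx^2 + off$dy^2 <= r^2 + 0.5, ]
}

# Chebyshev gap between two 0-based half-open boxes.
box_gap <- function(a, b) {
  dx <- max(0L, a["x0"] - b["x1"], b["x0"] - a["x1"])
  dy <- max(0L, a["y0"] - b["y1"], b["y0"] - a["y1"])
  max(dx, dy)
}

#' Render one synthetic page with ground truth
#'
#' Deterministically draws a page per the spec: glyphs placed with pairwise
#' bounding-box gaps of at least 60 px, pseudo-text blocks at least 40 px
#' from any glyph box, and noise blobs planted in empty corners of a glyph's
#' bounding box with at least 12 px clearance from its strokes. Ground-truth
#' masks are exact — they are the very pixel sets that were stamped.
#'
#' @param spec A [fixture_spec()].
#' @param page_seed Seed for this page (see [derive_seed()] splitting).
#' @param page_index Page index recorded in the raster.
#' @return List with `page` (a [page_raster()]) and `truth`: a list with
#'   `boxes` (tibble of glyph boxes), `glyph_masks` and `noise_masks`
#'   (lists of logical page-size matrices).
#' @export
render_fixture_page <- function(spec, page_seed, page_index = 0L) {
  with_page_seed(page_seed, {
    h <- spec$page_height
    w <- spec$page_width
    ink <- matrix(FALSE, h, w)
    n_glyphs <- sample_range(spec$structures_per_page[1], spec$structures_per_page[2])
    glyph_masks <- list()
    boxes <- NULL
    counts <- integer()
    border <- 30L
    sep <- 60L
    for (g in seq_len(n_glyphs)) {
      size <- runif(1, spec$glyph_size[1], spec$glyph_size[2])
      gs <- glyph_segments(size)
      ras <- rasterize_segments(gs$segments, spec$stroke_width)
      placed <- FALSE
      xmax <- w - border - ras$width
      ymax <- h - border - ras$height
      n_attempts <- if (xmax < border || ymax < border) 0L else 300L
      for (attempt in seq_len(n_attempts)) {
        x0 <- sample_range(border, xmax)
        y0 <- sample_range(border, ymax)
        cand <- c(x0 = x0, y0 = y0, x1 = x0 + ras$width, y1 = y0 + ras$height)
        ok <- TRUE
        if (!is.null(boxes)) {
          for (i in seq_len(nrow(boxes))) {
            if (box_gap(cand, unlist(boxes[i, c("x0", "y0", "x1", "y1")])) < sep) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          gm <- matrix(FALSE, h, w)
          gm[cbind(y0 + ras$xy[, 2] + 1L, x0 + ras$xy[, 1] + 1L)] <- TRUE
          glyph_masks[[g]] <- gm
          ink <- ink | gm
          boxes <- rbind(boxes, tibble(
            x0 = x0, y0 = y0, x1 = x0 + ras$width, y1 = y0 + ras$height
          ))
          counts[g] <- sum(gm)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "Infeasible packing: could not place glyph %d of %d (size ~%d px) on a %dx%d page with %d px separation.",
          g, n_glyphs, round(size), w, h, sep
        ))
      }
    }
    boxes <- boxes %||% tibble(x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer())

    # pseudo-text blocks, at least 40 px away from every glyph box
    n_text <- sample_range(spec$text_blocks[1], spec$text_blocks[2])
    text_boxes <- list()
    for (tb in seq_len(n_text)) {
      bw <- min(sample(150:300, 1), w - 40L)
      n_lines <- sample(2:4, 1)
      bh <- (n_lines - 1L) * 30L + 10L
      if (w - 10L - bw < 10L || h - 10L - bh < 10L) next
      for (attempt in 1:200) {
        x0 <- sample_range(10L, w - 10L - bw)
        y0 <- sample_range(10L, h - 10L - bh)
        cand <- c(x0 = x0, y0 = y0, x1 = x0 + bw, y1 = y0 + bh)
        clear <- TRUE
        if (nrow(boxes) > 0) {
          for (i in seq_len(nrow(boxes))) {
            if (box_gap(cand, unlist(boxes[i, ])) < 40L) {
              clear <- FALSE
              break
            }
          }
        }
        # keep text blocks apart from each other too: interleaved blocks
        # would fuse into dense blobs no longer rejected by the text windows
        if (clear && length(text_boxes) > 0) {
          for (prev in text_boxes) {
            if (box_gap(cand, prev) < 20L) {
              clear <- FALSE
              break
            }
          }
        }
        if (clear) {
          ink <- draw_text_block(ink, x0, y0, bw, n_lines)
          text_boxes[[length(text_boxes) + 1L]] <- cand
          break
        }
      }
    }

    # noise blobs in empty corners of glyph boxes, clear of the strokes
    noise_masks <- list()
    n_noise <- if (n_glyphs == 0) 0L else sample_range(spec$noise_blobs[1], spec$noise_blobs[2])
    min_glyph <- if (length(counts)) min(counts) else Inf
    for (b in seq_len(n_noise)) {
      r <- sample_range(spec$noise_radius[1], spec$noise_radius[2])
      if ((pi * r^2) >= 0.5 * min_glyph) next  # keep the corpus PR-separable
      gi <- sample(n_glyphs, 1)
      bx <- boxes[gi, ]
      corners <- rbind(
        c(bx$x0 + r + 2, bx$y0 + r + 2), c(bx$x1 - r - 3, bx$y0 + r + 2),
        c(bx$x0 + r + 2, bx$y1 - r - 3), c(bx$x1 - r - 3, bx$y1 - r - 3)
      )
      gm_idx <- which(glyph_masks[[gi]], arr.ind = TRUE)  # (row=y+1, col=x+1)
      for (ci in sample(4)) {
        cx <- corners[ci, 1]
        cy <- corners[ci, 2]
        d <- sqrt((gm_idx[, 2] - 1 - cx)^2 + (gm_idx[, 1] - 1 - cy)^2)
        if (min(d) - r >= 12) {
          off <- disc_offsets(r)
          nm <- matrix(FALSE, h, w)
          nm[cbind(cy + off$dy + 1L, cx + off$dx + 1L)] <- TRUE
          noise_masks[[length(noise_masks) + 1L]] <- nm
          ink <- ink | nm
          break
        }
      }
    }

    pixels <- render_ink(ink, spec$color_mode)
    list(
      page = page_raster(pixels,
        source_id = "fixture", page_index = page_index, dpi = 300
      ),
      truth = list(boxes = boxes, glyph_masks = glyph_masks, noise_masks = noise_masks)
    )
  })
}

render_ink <- function(ink, color_mode) {
  h <- nrow(ink); w <- ncol(ink)
  if (color_mode == "binary") {
    px <- matrix(255, h, w)
    px[ink] <- 0
    return(px)
  }
  if (color_mode == "grayscale") {
    px <- matrix(255, h, w)
    px[ink] <- sample(0:80, sum(ink), replace = TRUE)
    return(px)
  }
  # colored: RGB page, ink pixels given random dark hues
  px <- array(255, dim = c(h, w, 3))
  n <- sum(ink)
  hues <- grDevices::col2rgb(grDevices::hsv(runif(n), 0.9, 0.55))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[ink] <- hues[ch, ]
    px[, , ch] <- plane
  }
  px
}

#' Construct a mask map with exact component pixel counts
#'
#' Builds a `{0, 128}` mask containing one connected component per requested
#' count, with exactly the requested number of foreground pixels, pairwise
#' separated by at least 2 px. Components are near-square rectangles with a
#' partial final row, so each is connected under both 4- and 8-adjacency.
#' This reconstructs figure-style worked cases (e.g. components of 89,872
#' and 5,725 pixels) with exact arithmetic.
#'
#' @param counts Integer vector of component pixel counts, each >= 1.
#' @param layout_seed Deterministic jitter seed for vertical offsets.
#' @param canvas Optional `c(height, width)`; auto-sized when `NULL`. An
#'   infeasible canvas is a fatal error.
#' @return List with `mask` (a [mask_map()]) and `truth`: tibble of
#'   requested counts and component bounding boxes.
#' @export
make_mask_case <- function(counts, layout_seed = 1L, canvas = NULL) {
  if (length(counts) == 0L || any(counts < 1)) {
    abort("make_mask_case() needs counts >= 1.")
  }
  counts <- as.integer(counts)
  shapes <- purrr::map(counts, function(cnt) {
    w <- max(1L, as.integer(floor(sqrt(cnt))))
    full <- cnt %/% w
    rem <- cnt %% w
    list(w = w, full = full, rem = rem, h = as.integer(full + (rem > 0L)))
  })
  gap <- 3L
  widths <- vapply(shapes, function(s) s$w, integer(1))
  heights <- vapply(shapes, function(s) s$h, integer(1))
  jitter <- vapply(seq_along(counts), function(i) {
    derive_seed(layout_seed, i) %% 5L
  }, integer(1))
  need_w <- sum(widths) + gap * (length(counts) + 1L)
  need_h <- max(heights + jitter) + 2L * gap
  if (is.null(canvas)) {
    canvas <- c(need_h, need_w)
  } else if (canvas[1] < need_h || canvas[2] < need_w) {
    abort(sprintf(
      "Infeasible canvas %dx%d for requested counts (needs at least %dx%d).",
      canvas[2], canvas[1], need_w, need_h
    ))
  }
  if (sum(as.numeric(counts)) > as.numeric(canvas[1]) * canvas[2]) {
    abort("Total requested count exceeds canvas area.")
  }
  px <- matrix(0, canvas[1], canvas[2])
  x <- gap
  truth <- NULL
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    y <- gap + jitter[i]
    px[(y + 1L):(y + s$full), (x + 1L):(x + s$w)] <- 128
    if (s$rem > 0L) px[y + s$full + 1L, (x + 1L):(x + s$rem)] <- 128
    truth <- rbind(truth, tibble(
      requested = counts[i],
      x0 = x, y0 = y, x1 = x + s$w, y1 = y + s$h
    ))
    x <- x + s$w + gap
  }
  list(mask = mask_map(px), truth = truth)
}

#' Corrupt a page to emulate degraded source material
#'
#' Emulates the two degradation modes that hurt structure extraction in real
#' documents: `"low_res"` downscales by `factor` then upscales back
#' (bilinear), blurring strokes; `"colored"` recolors a fraction of ink
#' pixels with random hues, which can push their luminance past ink
#' thresholds. Ground truth is unchanged by design. `factor = 1` and
#' `fraction = 0` are identities.
#'
#' @param page A [page_raster()].
#' @param mode `"low_res"` or `"colored"`.
#' @param factor Downscale factor (>= 1) for `"low_res"`.
#' @param fraction Fraction in `[0, 1]` of ink pixels to recolor for
#'   `"colored"`.
#' @param ink_threshold Intensity below which a pixel counts as ink for
#'   recoloring (default 200).
#' @return A corrupted [page_raster()].
#' @export
corrupt <- function(page, mode = c("low_res", "colored"), factor = 2,
                    fraction = 0.3, ink_threshold = 200) {
  mode <- match.arg(mode)
  if (mode == "low_res") {
    if (factor < 1) abort("low_res factor must be >= 1.")
    if (factor == 1) return(page)
    scale_plane <- function(m) {
      small <- EBImage::resize(as_ebi(m),
        w = max(1L, round(ncol(m) / factor)), h = max(1L, round(nrow(m) / factor))
      )
      big <- EBImage::resize(small, w = ncol(m), h = nrow(m))
      pmin(pmax(from_ebi(big), 0), 255)
    }
    px <- page$pixels
    if (is_rgb(px)) {
      for (ch in 1:3) px[, , ch] <- scale_plane(px[, , ch])
    } else {
      px <- scale_plane(px)
    }
    out <- page
    out$pixels <- px
    return(out)
  }
  if (fraction < 0 || fraction > 1) abort("colored fraction must lie in [0, 1].")
  if (fraction == 0) return(page)
  px <- page$pixels
  if (!is_rgb(px)) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  }
  lum <- luminance(px)
  ink_idx <- which(lum < ink_threshold)
  n <- ceiling(fraction * length(ink_idx))
  if (n > 0) {
    pick <- sample(ink_idx, n)
    hues <- grDevices::col2rgb(grDevices::hsv(runif(n), 1, 1))
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[pick] <- hues[ch, ]
      px[, , ch] <- plane
    }
  }
  out <- page
  out$pixels <- px
  out
}

#' Write a synthetic fixture corpus to disk
#'
#' Renders `n_pages` pages under the spec (per-page seeds derived from the
#' corpus seed by fixed splitting, so any page regenerates independently),
#' writes them as PNG and stores ground truth (glyph boxes plus
#' run-length-encoded exact masks) as `ground_truth.json`.
#'
#' @param spec A [fixture_spec()].
#' @param n_pages Number of pages to generate.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
synth_corpus <- function(spec, n_pages, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pages <- purrr::map(seq_len(n_pages), function(i) {
    pg <- render_fixture_page(spec, derive_seed(spec$seed, i), page_index = i - 1L)
    file <- sprintf("page-%04d.png", i - 1L)
    save_raster(pg$page, file.path(dir, file))
    list(
      page_index = i - 1L,
      file = file,
      glyphs = purrr::map(seq_along(pg$truth$glyph_masks), function(g) {
        c(
          as.list(pg$truth$boxes[g, ]),
          list(
            pixel_count = sum(pg$truth$glyph_masks[[g]]),
            mask_rle = mask_to_rle(pg$truth$glyph_masks[[g]])
          )
        )
      }),
      noise = purrr::map(pg$truth$noise_masks, function(nm) {
        list(pixel_count = sum(nm), mask_rle = mask_to_rle(nm))
      })
    )
  })
  truth <- list(
    page_width = spec$page_width,
    page_height = spec$page_height,
    n_pages = n_pages,
    seed = spec$seed,
    pages = pages
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fixture corpus's ground truth
#'
#' @param dir Corpus directory written by [synth_corpus()].
#' @return The decoded ground-truth list; each page's glyph and noise masks
#'   are re-inflated from their run-length encoding into 0-based row-major
#'   pixel index vectors (`y * page_width + x`).
#' @export
read_ground_truth <- function(dir) {
  path <- file.path(dir, "ground_truth.json")
  if (!file.exists(path)) abort(sprintf("No ground_truth.json in %s", dir))
  gt <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  gt$pages <- purrr::map(gt$pages, function(pg) {
    pg$glyphs <- purrr::map(pg$glyphs, function(g) {
      g$mask_idx <- rle_to_indices(g$mask_rle)
      g
    })
    pg$noise <- purrr::map(pg$noise, function(nmk) {
      nmk$mask_idx <- rle_to_indices(nmk$mask_rle)
      nmk
    })
    pg
  })
  gt
}

# Run-length encoding of a logical page mask over 0-based row-major pixel
# indices (y * width + x): lists of run starts and lengths.
mask_to_rle <- function(mask) {
  idx <- which(t(mask)) - 1L  # t() makes which() row-major
  if (length(idx) == 0L) return(list(starts = integer(), lengths = integer()))
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  starts <- idx[breaks[-length(breaks)] + 1L]
  lengths <- diff(breaks)
  list(starts = starts, lengths = as.integer(lengths))
}

rle_to_indices <- function(rle) {
  starts <- as.integer(unlist(rle$starts))
  lengths <- as.integer(unlist(rle$lengths))
  if (length(starts) == 0L) return(integer())
  unlist(purrr::map2(starts, lengths, function(s, l) s + 0:(l - 1L)))
}
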