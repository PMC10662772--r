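#' Build a tibble of detection boxes
#'
#' Detection boxes are axis-aligned rectangles in 0-based, half-open page
#' pixel coordinates: a box covers columns `[x0, x1)` and rows `[y0, y1)`
#' with the origin at the top-left corner. They are carried as tibble rows so
#' detection output chains directly into dplyr verbs.
#'
#' @param x0,y0,x1,y1 Integer pixel coordinates, `0 <= x0 < x1 <= width`,
#'   `0 <= y0 < y1 <= height`.
#' @param confidence Detector confidence in `[0, 1]`.
#' @param expanded Whether the box has already been expanded by a margin.
#' @return A tibble with columns `x0, y0, x1, y1, confidence, expanded`.
#' @export
detection_boxes <- function(x0 = integer(), y0 = integer(), x1 = integer(),
                            y1 = integer(), confidence = 1, expanded = FALSE) {
  tb <- tibble(
    x0 = as.integer(x0), y0 = as.integer(y0),
    x1 = as.integer(x1), y1 = as.integer(y1),
    confidence = as.numeric(confidence),
    expanded = as.logical(expanded)
  )
  validate_boxes(tb)
  tb
}

validate_boxes <- function(boxes, page_width = NULL, page_height = NULL) {
  if (nrow(boxes) == 0L) return(invisible(boxes))
  with(boxes, {
    if (any(x0 < 0L | y0 < 0L | x0 >= x1 | y0 >= y1)) {
      abort("Invalid detection box: need 0 <= x0 < x1 and 0 <= y0 < y1.")
    }
    if (any(confidence < 0 | confidence > 1)) {
      abort("Detection confidence must lie in [0, 1].")
    }
  })
  if (!is.null(page_width) && any(boxes$x1 > page_width)) {
    abort("Detection box exceeds page width.")
  }
  if (!is.null(page_height) && any(boxes$y1 > page_height)) {
    abort("Detection box exceeds page height.")
  }
  invisible(boxes)
}

#' Expand detection boxes by a fixed margin
#'
#' Moves each side of each box outward by `margin` pixels, then clips to the
#' page. The default margin of 20 px enlarges the detector's prediction frame
#' enough that peripheral atoms and bond ends sit inside the crop; 10 and 30
#' are the natural settings for a smaller/larger-margin comparison. Expansion
#' is monotone in `margin`, the identity at `margin = 0`, and always returns
#' boxes inside the page; a full-page box is a fixed point.
#'
#' @param boxes Tibble of boxes as from [detection_boxes()].
#' @param margin Non-negative expansion in pixels (default 20).
#' @param page_width,page_height Page dimensions used for clipping.
#' @return The boxes, expanded, clipped, with `expanded = TRUE`.
#' @export
expand_box <- function(boxes, margin = 20L, page_width, page_height) {
  stopifnot(margin >= 0)
  validate_boxes(boxes, page_width, page_height)
  dplyr::mutate(boxes,
    x0 = pmax(0L, .data$x0 - as.integer(margin)),
    y0 = pmax(0L, .data$y0 - as.integer(margin)),
    x1 = pmin(as.integer(page_width), .data$x1 + as.integer(margin)),
    y1 = pmin(as.integer(page_height), .data$y1 + as.integer(margin)),
    expanded = TRUE
  )
}

#' Crop a page to a detection box
#'
#' Extracts the sub-raster covered by `box` (one tibble row). The crop
#' carries lineage — source document, page index and the box it came from —
#' so every downstream extraction is traceable to its origin.
#'
#' @param page A [page_raster()].
#' @param box A single-row box tibble.
#' @return A `crop_image`: list with `pixels` and `lineage`.
#' @export
crop_page <- function(page, box) {
  stopifnot(nrow(box) == 1L)
  validate_boxes(box, page$width, page$height)
  rows <- (box$y0 + 1L):box$y1
  cols <- (box$x0 + 1L):box$x1
  px <- if (is_rgb(page$pixels)) {
    page$pixels[rows, cols, , drop = FALSE]
  } else {
    page$pixels[rows, cols, drop = FALSE]
  }
  structure(
    list(
      pixels = px,
      lineage = list(
        source_id = page$source_id,
        page_index = page$page_index,
        box = box
      )
    ),
    class = "crop_image"
  )
}

#' @export
print.crop_image <- function(x, ...) {
  b <- x$lineage$box
  cat(sprintf(
    "<crop_image> %dx%d px from %s page %d, box (%d,%d,%d,%d)\n",
    pixel_width(x$pixels), pixel_height(x$pixels),
    x$lineage$source_id, x$lineage$page_index, b$x0, b$y0, b$x1, b$y1
  ))
  invisible(x)
}

#' Create a detector backend
#'
#' A detector backend is a named procedure `page_raster -> box tibble`
#' returning unexpanded boxes that satisfy the box invariants on that page,
#' deterministically for a fixed raster. The built-in `"baseline"` backend is
#' [baseline_detect()]; trained-model backends can be registered with the
#' same contract.
#'
#' @param name Backend identifier.
#' @param detect Function taking a [page_raster()] and returning a box tibble.
#' @return A `detector_backend` object.
#' @export
detector_backend <- function(name, detect) {
  stopifnot(is.character(name), is.function(detect))
  structure(list(name = name, detect = detect), class = "detector_backend")
}

#' Resolve a detector backend by name
#'
#' @param name `"baseline"` or a `detector_backend` object.
#' @param params Named list of parameter overrides for the baseline detector.
#' @return A `detector_backend`.
#' @export
get_detector <- function(name = "baseline", params = list()) {
  if (inherits(name, "detector_backend")) return(name)
  if (identical(name, "baseline")) {
    return(detector_backend("baseline", function(page) {
      do.call(baseline_detect, c(list(page = page), params))
    }))
  }
  abort(sprintf("Unknown detector backend: %s", name))
}

#' Detect candidate structure regions on a page
#'
#' Runs a detector backend and returns its boxes sorted by descending
#' confidence (ties keep the backend's order). An empty tibble is a
#' legitimate result for a page with no structures.
#'
#' @param page A [page_raster()].
#' @param backend A [detector_backend()] (default: the baseline detector).
#' @return Tibble of unexpanded detection boxes.
#' @export
detect_structures <- function(page, backend = get_detector("baseline")) {
  boxes <- backend$detect(page)
  validate_boxes(boxes, page$width, page$height)
  dplyr::arrange(boxes, dplyr::desc(.data$confidence))
}

#' Rule-based baseline structure detector
#'
#' A desk-scale detector for line-drawn structure depictions: binarize the
#' page by a global intensity threshold, label 8-connected ink blobs, merge
#' blobs whose bounding boxes lie within a gap tolerance, and keep merged
#' boxes that pass area, aspect-ratio and ink-density windows. The default
#' windows accept ring-and-bond line art and reject dense text lines (long,
#' thin) and solid blobs (ink density too high). Every surviving box is
#' reported with confidence 1.0.
#'
#' @param page A [page_raster()]; RGB pages are reduced to luminance
#'   internally.
#' @param threshold Global binarization threshold: ink is intensity
#'   `< threshold` (default 200).
#' @param merge_gap Boxes closer than this (Chebyshev gap, px) are merged
#'   (default 15).
#' @param min_area Minimum merged-box area in px^2 (default 900).
#' @param aspect_limits Allowed width/height ratio window (default
#'   `c(0.2, 5)`).
#' @param ink_density_limits Allowed ink-pixel fraction within the box
#'   (default `c(0.01, 0.5)`).
#' @return Tibble of unexpanded detection boxes.
#' @export
baseline_detect <- function(page, threshold = 200, merge_gap = 15L,
                            min_area = 900, aspect_limits = c(0.2, 5.0),
                            ink_density_limits = c(0.01, 0.5)) {
  gray <- luminance(page$pixels)
  ink <- gray < threshold
  if (!any(ink)) return(detection_boxes())
  lab <- cc_label(ink, 8L)
  boxes <- component_bboxes(lab)
  boxes <- merge_boxes(boxes, merge_gap)
  # Filter windows on the merged boxes.
  w <- boxes$x1 - boxes$x0
  h <- boxes$y1 - boxes$y0
  area <- as.numeric(w) * as.numeric(h)
  aspect <- w / h
  density <- purrr::map2_dbl(seq_len(nrow(boxes)), area, function(i, a) {
    sum(ink[(boxes$y0[i] + 1L):boxes$y1[i], (boxes$x0[i] + 1L):boxes$x1[i]]) / a
  })
  keep <- area >= min_area &
    aspect >= aspect_limits[1] & aspect <= aspect_limits[2] &
    density >= ink_density_limits[1] & density <= ink_density_limits[2]
  out <- boxes[keep, , drop = FALSE]
  detection_boxes(out$x0, out$y0, out$x1, out$y1, confidence = 1, expanded = FALSE)
}

# Bounding boxes (0-based half-open) of the labeled regions of `lab`.
component_bboxes <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(tibble(x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer()))
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab))      # 0-based y
  cols <- ((idx - 1L) %/% nrow(lab))     # 0-based x
  tibble(
    x0 = as.integer(tapply(cols, labs, min)),
    y0 = as.integer(tapply(rows, labs, min)),
    x1 = as.integer(tapply(cols, labs, max)) + 1L,
    y1 = as.integer(tapply(rows, labs, max)) + 1L
  )
}

# Transitively merge boxes whose rectangles are within `gap` px of each other
# (Chebyshev distance between rectangles), via union-find.
merge_boxes <- function(boxes, gap) {
  n <- nrow(boxes)
  if (n <= 1L) return(boxes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- max(0L, boxes$x0[i] - boxes$x1[j], boxes$x0[j] - boxes$x1[i])
      dy <- max(0L, boxes$y0[i] - boxes$y1[j], boxes$y0[j] - boxes$y1[i])
      if (dx <= gap && dy <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- split(seq_len(n), root)
  out <- purrr::map(grp, function(ix) {
    tibble(
      x0 = min(boxes$x0[ix]), y0 = min(boxes$y0[ix]),
      x1 = max(boxes$x1[ix]), y1 = max(boxes$y1[ix])
    )
  })
  dplyr::bind_rows(out)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Single-row box tibbles (or lists with `x0, y0, x1, y1`).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- as.numeric(ix) * iy
  area_a <- as.numeric(a$x1 - a$x0) * (a$y1 - a$y0)
  area_b <- as.numeric(b$x1 - b$x0) * (b$y1 - b$y0)
  inter / (area_a + area_b - inter)
}

#' Drop near-duplicate boxes by IoU
#'
#' Optional dedup for overlapping frames after expansion: boxes whose IoU
#' with an already-kept, higher-confidence box exceeds `iou_threshold` are
#' dropped. Off by default in the pipeline.
#'
#' @param boxes Box tibble sorted or not; processed by descending confidence.
#' @param iou_threshold IoU above which a box is a duplicate (default 0.9).
#' @return Filtered box tibble.
#' @export
dedup_boxes <- function(boxes, iou_threshold = 0.9) {
  if (nrow(boxes) <= 1L) return(boxes)
  ord <- order(-boxes$confidence)
  keep <- integer()
  for (i in ord) {
    dup <- any(vapply(keep, function(j) {
      box_iou(boxes[i, ], boxes[j, ]) > iou_threshold
    }, logical(1)))
    if (!dup) keep <- c(keep, i)
  }
  boxes[sort(keep), , drop = FALSE]
}
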