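#' Construct a mask map
#'
#' A mask map is a single-channel raster over a crop whose pixel alphabet is
#' exactly `{0, 128}`: 128 marks putative molecular-structure pixels, 0 is
#' background. The two-value convention keeps saved masks directly comparable
#' with the pipeline's intermediate artifacts.
#'
#' @param pixels Numeric matrix with values in `{0, 128}`.
#' @param lineage Optional crop lineage (source, page, box), as carried by a
#'   `crop_image`.
#' @return A `mask_map` object.
#' @export
mask_map <- function(pixels, lineage = NULL) {
  if (!is.matrix(pixels)) abort("A mask map is a single-channel matrix.")
  vals <- unique(as.vector(pixels))
  if (!all(vals %in% c(0, 128))) {
    abort("Mask alphabet must be a subset of {0, 128}; use normalize_mask() first.")
  }
  structure(list(pixels = pixels + 0, lineage = lineage), class = "mask_map")
}

#' @export
print.mask_map <- function(x, ...) {
  cat(sprintf(
    "<mask_map> %dx%d px, %d foreground px\n",
    pixel_width(x$pixels), pixel_height(x$pixels), sum(x$pixels == 128)
  ))
  invisible(x)
}

#' Normalize a raw raster to the mask alphabet
#'
#' Maps every nonzero value to 128 and leaves 0 untouched, so the zero set is
#' preserved exactly. A warning is raised if any value outside `{0, 128}` was
#' present. Idempotent on already-normalized masks.
#'
#' @param raw Single-channel matrix of any 8-bit values, or a `mask_map`.
#' @param lineage Optional lineage for the result.
#' @return A [mask_map()].
#' @export
normalize_mask <- function(raw, lineage = NULL) {
  if (inherits(raw, "mask_map")) return(raw)
  if (!is.matrix(raw)) abort("normalize_mask() expects a single-channel matrix.")
  vals <- unique(as.vector(raw))
  if (!all(vals %in% c(0, 128))) {
    warn(sprintf(
      "Mask contained values outside {0, 128} (%s); nonzero mapped to 128.",
      paste(utils::head(sort(setdiff(vals, c(0, 128))), 5), collapse = ", ")
    ))
  }
  out <- matrix(0, nrow(raw), ncol(raw))
  out[raw != 0] <- 128
  mask_map(out, lineage)
}

#' Create a segmenter backend
#'
#' A segmenter backend is a named procedure `crop_image -> mask_map`,
#' deterministic for a fixed crop. A backend may resize internally but must
#' return a mask at the crop's native size; [generate_mask()] enforces the
#' mask invariants on whatever the backend returns.
#'
#' @param name Backend identifier.
#' @param segment Function taking a `crop_image` and returning a
#'   [mask_map()] (or a raw matrix, which will be normalized).
#' @return A `segmenter_backend` object.
#' @export
segmenter_backend <- function(name, segment) {
  stopifnot(is.character(name), is.function(segment))
  structure(list(name = name, segment = segment), class = "segmenter_backend")
}

#' Resolve a segmenter backend by name
#'
#' @param name `"baseline"` or a `segmenter_backend` object.
#' @param params Named list of overrides for the baseline segmenter.
#' @return A `segmenter_backend`.
#' @export
get_segmenter <- function(name = "baseline", params = list()) {
  if (inherits(name, "segmenter_backend")) return(name)
  if (identical(name, "baseline")) {
    return(segmenter_backend("baseline", function(crop) {
      do.call(baseline_segment, c(list(crop = crop), params))
    }))
  }
  abort(sprintf("Unknown segmenter backend: %s", name))
}

#' Generate a mask map for a crop
#'
#' Runs a segmenter backend on the crop and normalizes its output to the
#' `{0, 128}` alphabet at the crop's native size. An all-zero mask (no
#' structure found) is a legitimate result.
#'
#' @param crop A `crop_image`.
#' @param backend A [segmenter_backend()] (default: the baseline segmenter).
#' @return A [mask_map()] with the crop's lineage.
#' @export
generate_mask <- function(crop, backend = get_segmenter("baseline")) {
  out <- backend$segment(crop)
  m <- if (inherits(out, "mask_map")) out else normalize_mask(out, crop$lineage)
  if (pixel_height(m$pixels) != pixel_height(crop$pixels) ||
    pixel_width(m$pixels) != pixel_width(crop$pixels)) {
    abort(sprintf(
      "Segmenter '%s' returned a mask of the wrong size (%dx%d for a %dx%d crop).",
      backend$name, pixel_width(m$pixels), pixel_height(m$pixels),
      pixel_width(crop$pixels), pixel_height(crop$pixels)
    ))
  }
  m$lineage <- crop$lineage
  m
}

#' Rule-based baseline segmenter
#'
#' A desk-scale segmenter for line art: binarize the crop's luminance (ink is
#' intensity strictly below `threshold`), then morphologically close with a
#' disc brush so that nearby strokes fuse into solid regions, and map
#' foreground to 128. The default closing radius of 4 px fuses the strokes of
#' a drawn ring system into a single connected region while leaving
#' well-separated noise blobs as their own components.
#'
#' @param crop A `crop_image` (RGB crops are reduced to luminance
#'   internally; the crop itself is untouched).
#' @param threshold Ink threshold (default 200); at `threshold = 0` no pixel
#'   is ink and the mask is all-zero.
#' @param close_radius Disc radius in px for morphological closing
#'   (default 4); 0 disables closing.
#' @return A [mask_map()] over the crop.
#' @export
baseline_segment <- function(crop, threshold = 200, close_radius = 4L) {
  gray <- luminance(crop$pixels)
  ink <- gray < threshold
  if (any(ink) && close_radius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(t(ink * 1)), brush)
    ink <- t(EBImage::imageData(closed)) > 0
  }
  out <- matrix(0, nrow(gray), ncol(gray))
  out[ink] <- 128
  mask_map(out, crop$lineage)
}

#' Save a mask map next to its crop
#'
#' Masks are written as single-channel PNG with the raw `{0, 128}` values, so
#' a reload reproduces the alphabet exactly.
#'
#' @param mask A [mask_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) save_raster(mask$pixels, path)

#' Load a mask map from PNG
#'
#' @param path PNG path; values are normalized to `{0, 128}` with a warning
#'   if anything else is present.
#' @return A [mask_map()].
#' @export
load_mask <- function(path) {
  r <- load_raster(path)
  px <- if (is_rgb(r$pixels)) luminance(r$pixels) else r$pixels
  normalize_mask(px)
}
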