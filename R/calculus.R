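#' Configuration for the mask-calculus stage
#'
#' Holds the tunables of the denoising/separation stage. `prt` is the
#' pixel-ratio threshold: a component whose PR strictly exceeds `prt` is a
#' genuine structure mask, otherwise noise. The default 0.5 sits between the
#' empirically observed PR ranges of genuine structure masks (0.55-1) and
#' noise masks (0-0.2) in multi-mask prediction frames.
#'
#' @param prt Pixel-ratio threshold in `[0, 1]` (default 0.5; strict
#'   comparison).
#' @param connectivity Pixel adjacency for region labeling, 4 or 8 (default
#'   8, so diagonal bond strokes remain single regions).
#' @param tight_crop If `TRUE`, extractions are re-framed to the component
#'   bounding box plus `tight_margin`; default `FALSE` keeps the full crop
#'   extent.
#' @param tight_margin Margin in px for tight cropping (default 5).
#' @param background_fill Intensity written outside the component (default
#'   255, white).
#' @param min_pixels Optional absolute floor on component pixel count
#'   (default 0, disabled); components below it are noise regardless of PR.
#' @return A `calculus_config` list.
#' @export
calculus_config <- function(prt = 0.5, connectivity = 8L, tight_crop = FALSE,
                            tight_margin = 5L, background_fill = 255,
                            min_pixels = 0L) {
  stopifnot(prt >= 0, prt <= 1, connectivity %in% c(4L, 8L), tight_margin >= 0)
  structure(
    list(
      prt = prt, connectivity = as.integer(connectivity),
      tight_crop = isTRUE(tight_crop), tight_margin = as.integer(tight_margin),
      background_fill = background_fill, min_pixels = as.integer(min_pixels)
    ),
    class = "calculus_config"
  )
}

#' Label connected foreground regions of a mask map
#'
#' Region filling: every maximal connected set of foreground (128) pixels
#' under the given connectivity becomes one component, labeled `1..k` in
#' raster-scan order (by row, then column) of its first-encountered pixel.
#' Per-component pixel counts and bounding boxes are tallied; counts sum
#' exactly to the mask's total foreground count.
#'
#' @param mask A [mask_map()].
#' @param connectivity 4 or 8 (default 8).
#' @return A tibble with one row per component: `label`, `pixel_count`,
#'   `x0, y0, x1, y1` (bounding box in crop coordinates), and unset `pr`,
#'   `pr_reported`, `verdict` columns. The integer label matrix and the
#'   connectivity are attached as attributes `label_matrix` and
#'   `connectivity`. Empty tibble for an all-zero mask.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(inherits(mask, "mask_map"), connectivity %in% c(4L, 8L))
  fg <- mask$pixels == 128
  lab <- cc_label(fg, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) {
    out <- tibble(
      label = integer(), pixel_count = integer(),
      x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer(),
      pr = numeric(), pr_reported = numeric(), verdict = character()
    )
  } else {
    boxes <- component_bboxes(lab)
    counts <- tabulate(lab[lab > 0L], nbins = k)
    out <- tibble(
      label = seq_len(k), pixel_count = as.integer(counts),
      x0 = boxes$x0, y0 = boxes$y0, x1 = boxes$x1, y1 = boxes$y1,
      pr = NA_real_, pr_reported = NA_real_, verdict = NA_character_
    )
  }
  attr(out, "label_matrix") <- lab
  attr(out, "connectivity") <- as.integer(connectivity)
  out
}

#' Pixel ratio of a mask component
#'
#' PR = p_mask / p_largest_mask: a component's foreground pixel count divided
#' by the largest component's count within the same mask map. The quotient is
#' computed at full precision; reported values are truncated (not rounded) to
#' three decimals via [truncate_pr()], so 5725/89872 = 0.0637... is reported
#' as 0.063.
#'
#' @param pixel_count Component pixel count, `1 <= pixel_count <=
#'   largest_count`.
#' @param largest_count Pixel count of the largest component (> 0).
#' @return The exact quotient in `(0, 1]`.
#' @export
pixel_ratio <- function(pixel_count, largest_count) {
  if (any(largest_count <= 0)) {
    abort("pixel_ratio() needs a positive largest_count (mask has no components).")
  }
  if (any(pixel_count < 1 | pixel_count > largest_count)) {
    abort("pixel_count must lie in [1, largest_count].")
  }
  pixel_count / largest_count
}

#' Truncate a pixel ratio to three decimals for reporting
#'
#' Truncation, not rounding: 0.0637 reports as 0.063, 0.9999 as 0.999.
#' Classification always uses the full-precision ratio.
#'
#' @param pr Numeric vector of ratios.
#' @return Ratios truncated to 3 decimal places.
#' @export
truncate_pr <- function(pr) trunc(pr * 1000) / 1000

#' Classify mask components as genuine structures or noise
#'
#' Computes each component's PR against the maximal pixel count in the mask
#' and applies the pixel-ratio threshold: verdict is `"genuine"` iff
#' `pr > prt` (strictly — a component at exactly the threshold is noise).
#' The largest component always has PR exactly 1 and is therefore genuine
#' whenever the mask is nonempty; ties for largest all get PR 1. If
#' `min_pixels` is set, components below it are noise regardless of PR.
#'
#' @param components Component tibble from [label_components()].
#' @param config A [calculus_config()].
#' @return The tibble with `pr`, `pr_reported` (3-decimal truncated) and
#'   `verdict` filled in; label-matrix attributes preserved.
#' @export
classify_components <- function(components, config = calculus_config()) {
  if (nrow(components) == 0L) return(components)
  largest <- max(components$pixel_count)
  pr_full <- pixel_ratio(components$pixel_count, largest)
  verdict <- ifelse(pr_full > config$prt, "genuine", "noise")
  if (config$min_pixels > 0L) {
    verdict[components$pixel_count < config$min_pixels] <- "noise"
  }
  out <- components
  out$pr <- pr_full
  out$pr_reported <- truncate_pr(pr_full)
  out$verdict <- verdict
  attr(out, "label_matrix") <- attr(components, "label_matrix")
  attr(out, "connectivity") <- attr(components, "connectivity")
  out
}

#' Separate a multi-structure mask into single-component masks
#'
#' Produces one mask map per genuine component: same dimensions as the input,
#' that component's pixels at 128 and 0 elsewhere. Noise components appear in
#' no output, which is where denoising happens; a mask holding several
#' genuine structures yields several disjoint single-structure masks.
#'
#' @param mask The classified mask's [mask_map()].
#' @param classified Component tibble from [classify_components()] (must
#'   carry the `label_matrix` attribute from [label_components()] on this
#'   mask).
#' @return List of [mask_map()]s, one per genuine component, in label order;
#'   each carries the source lineage plus its component row as attribute
#'   `component`.
#' @export
separate_masks <- function(mask, classified) {
  lab <- attr(classified, "label_matrix")
  if (is.null(lab)) {
    cls <- classify_components(
      label_components(mask, attr(classified, "connectivity") %||% 8L)
    )
    lab <- attr(cls, "label_matrix")
  }
  stopifnot(all(dim(lab) == dim(mask$pixels)))
  genuine <- classified[!is.na(classified$verdict) & classified$verdict == "genuine", ]
  purrr::map(seq_len(nrow(genuine)), function(i) {
    lbl <- genuine$label[i]
    px <- matrix(0, nrow(lab), ncol(lab))
    px[lab == lbl] <- 128
    m <- mask_map(px, mask$lineage)
    attr(m, "component") <- genuine[i, ]
    m
  })
}

#' Apply a single-structure mask to its crop
#'
#' The extraction operation: wherever the mask is 128 the output keeps the
#' crop's pixel, everywhere else it is `background_fill`, yielding a clean
#' structure image free of neighbouring noise. With `tight_crop` the result
#' is additionally re-framed to the component's bounding box plus
#' `tight_margin`, clipped to the crop.
#'
#' @param crop The `crop_image` the mask was generated from.
#' @param single_mask A single-component [mask_map()] (separate first if the
#'   mask holds several components).
#' @param config A [calculus_config()].
#' @return An `extraction_result`: list with `image` (8-bit raster),
#'   `component` (one-row tibble), `lineage`, and `config` echo.
#' @export
apply_mask <- function(crop, single_mask, config = calculus_config()) {
  stopifnot(all(dim(single_mask$pixels) == c(
    pixel_height(crop$pixels), pixel_width(crop$pixels)
  )))
  comp_tb <- attr(single_mask, "component")
  if (is.null(comp_tb)) {
    comps <- label_components(single_mask, config$connectivity)
    if (nrow(comps) != 1L) {
      abort("apply_mask() requires a single-component mask; run separate_masks() first.")
    }
    comp_tb <- classify_components(comps, config)[1, ]
  }
  fg <- single_mask$pixels == 128
  px <- crop$pixels
  if (is_rgb(px)) {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[!fg] <- config$background_fill
      px[, , ch] <- plane
    }
  } else {
    px[!fg] <- config$background_fill
  }
  if (config$tight_crop) {
    h <- pixel_height(px); w <- pixel_width(px)
    y0 <- max(0L, comp_tb$y0 - config$tight_margin)
    x0 <- max(0L, comp_tb$x0 - config$tight_margin)
    y1 <- min(h, comp_tb$y1 + config$tight_margin)
    x1 <- min(w, comp_tb$x1 + config$tight_margin)
    px <- if (is_rgb(px)) px[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE] else px[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
  }
  structure(
    list(
      image = px,
      component = comp_tb,
      lineage = crop$lineage,
      config = unclass(config)
    ),
    class = "extraction_result"
  )
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf(
    "<extraction_result> %dx%d px, component label %d (%d px, PR %.3f, %s) from %s page %s\n",
    pixel_width(x$image), pixel_height(x$image),
    x$component$label, x$component$pixel_count,
    x$component$pr, x$component$verdict,
    x$lineage$source_id %||% "?", x$lineage$page_index %||% "?"
  ))
  invisible(x)
}

#' Denoise, separate and extract all structures from one crop
#'
#' Convenience wrapper over the full calculation stage for one crop/mask
#' pair: label components, classify by PR, separate genuine components into
#' single-structure masks and apply each to the crop. An empty mask yields
#' zero extractions with a warning (a detector false positive is a
#' legitimate outcome, not an error).
#'
#' @param crop A `crop_image`.
#' @param mask Its [mask_map()].
#' @param config A [calculus_config()].
#' @return List with `extractions` (list of `extraction_result`) and
#'   `components` (the classified component tibble).
#' @export
calculate_crop <- function(crop, mask, config = calculus_config()) {
  comps <- label_components(mask, config$connectivity)
  comps <- classify_components(comps, config)
  if (nrow(comps) == 0L) {
    warn("Empty mask: no components, no extraction.")
    return(list(extractions = list(), components = comps))
  }
  singles <- separate_masks(mask, comps)
  extractions <- purrr::map(singles, function(m) apply_mask(crop, m, config))
  list(extractions = extractions, components = comps)
}

#' Tidy per-component report for one crop
#'
#' One row per component in the style of the pipeline's CSV/JSON report:
#' label, pixel count, truncated PR, verdict.
#'
#' @param components Classified component tibble.
#' @param crop_id Identifier column value.
#' @return A tibble.
#' @export
component_report <- function(components, crop_id = NA_character_) {
  tibble(
    crop_id = crop_id,
    label = components$label,
    pixel_count = components$pixel_count,
    pr = components$pr_reported,
    verdict = components$verdict
  )
}
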