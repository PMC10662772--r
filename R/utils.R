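# Internal helpers shared across modules.

# EBImage stores images x-major (first dim = x); the package stores rasters as
# numeric matrices with dim = (height, width), i.e. row = y. These two wrappers
# keep the transposition in one place. Values are carried in [0, 255].
as_ebi <- function(m) EBImage::Image(t(m) / 255)

from_ebi <- function(img) round(t(EBImage::imageData(img)) * 255)

# Luminance transform for RGB arrays (h x w x 3, 0..255). Grayscale matrices
# pass through untouched; backends that need grayscale call this, never the
# pipeline itself, so RGB inputs stay RGB through cropping and extraction.
luminance <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  stopifnot(length(dim(pixels)) == 3L)
  round(0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3])
}

is_rgb <- function(pixels) !is.matrix(pixels) && length(dim(pixels)) == 3L

pixel_height <- function(pixels) dim(pixels)[1]
pixel_width <- function(pixels) dim(pixels)[2]

#' Derive a per-item seed from a corpus seed
#'
#' Fixed seed splitting: one corpus seed deterministically derives per-page
#' (or per-case) seeds, so any page of a corpus regenerates independently.
#' Results stay below 2^31 - 1.
#'
#' @param seed Corpus seed (integer).
#' @param index Item index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
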