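#' Construct a page raster
#'
#' A `page_raster` is one document page held as an 8-bit raster: a numeric
#' matrix (grayscale, `height x width`) or a 3-plane array (RGB,
#' `height x width x 3`) of intensities in `[0, 255]`, together with its
#' provenance (document identifier, 0-based page index, rendering dpi).
#' Pixel coordinates throughout the package are 0-based with the origin at
#' the top-left corner, x rightward and y downward.
#'
#' @param pixels Numeric matrix or `h x w x 3` array of intensities in
#'   `[0, 255]`.
#' @param source_id Document identifier (character scalar).
#' @param page_index 0-based page number within the document.
#' @param dpi Rendering resolution in dots per inch.
#' @return An object of class `page_raster` with fields `pixels`, `width`,
#'   `height`, `source_id`, `page_index`, `dpi`.
#' @examples
#' pg <- page_raster(matrix(255, 40, 60), source_id = "doc", page_index = 0)
#' pg$width
#' @export
page_raster <- function(pixels, source_id = "unknown", page_index = 0L, dpi = 300) {
  if (!is.numeric(pixels) || !(is.matrix(pixels) || length(dim(pixels)) == 3L)) {
    abort("`pixels` must be a numeric matrix (grayscale) or h x w x 3 array (RGB).")
  }
  if (any(pixels < 0 | pixels > 255)) {
    abort("Raster intensities must lie in [0, 255].")
  }
  h <- pixel_height(pixels)
  w <- pixel_width(pixels)
  if (h < 1L || w < 1L) abort("Raster must be at least 1 x 1.")
  structure(
    list(
      pixels = pixels + 0, # store as double for consistent arithmetic
      width = as.integer(w),
      height = as.integer(h),
      source_id = as.character(source_id),
      page_index = as.integer(page_index),
      dpi = dpi
    ),
    class = "page_raster"
  )
}

#' @export
print.page_raster <- function(x, ...) {
  kind <- if (is_rgb(x$pixels)) "RGB" else "grayscale"
  cat(sprintf(
    "<page_raster> %s %dx%d px, %s page %d (%g dpi)\n",
    kind, x$width, x$height, x$source_id, x$page_index, x$dpi
  ))
  invisible(x)
}

#' Load a raster image from disk
#'
#' Reads PNG (canonical), JPEG or TIFF into a [page_raster()]. Grayscale files
#' load as 2-D matrices, color files as 3-plane RGB arrays (an alpha channel,
#' if present, is dropped).
#'
#' @param path Path to an image file.
#' @param source_id,page_index,dpi Provenance attached to the raster;
#'   `source_id` defaults to the file name.
#' @return A [page_raster()].
#' @export
load_raster <- function(path, source_id = NULL, page_index = 0L, dpi = 300) {
  if (!file.exists(path)) abort(sprintf("No such image file: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) {
      abort(sprintf("Corrupt or unreadable PNG: %s (%s)", path, conditionMessage(e)))
    }),
    jpg = ,
    jpeg = ,
    tif = ,
    tiff = tryCatch(
      EBImage::imageData(EBImage::transpose(EBImage::readImage(path))),
      error = function(e) {
        abort(sprintf("Corrupt or unreadable image: %s (%s)", path, conditionMessage(e)))
      }
    ),
    abort(sprintf("Unsupported image format '.%s': %s", ext, path))
  )
  px <- round(arr * 255)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) {
      px <- px[, , 1:3, drop = FALSE]
      # collapse to grayscale only if the three planes are identical? No:
      # plane count follows the file, an RGB file stays RGB.
    } else {
      px <- px[, , 1]
    }
  }
  page_raster(px,
    source_id = source_id %||% basename(path),
    page_index = page_index, dpi = dpi
  )
}

#' Save a raster image to disk
#'
#' Writes 8-bit non-interlaced PNG. PNG round trips are bit-exact for every
#' raster the pipeline produces, including `{0, 128}` mask maps.
#'
#' @param raster A [page_raster()], [mask_map()], or bare matrix/array with
#'   values in `[0, 255]`.
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
save_raster <- function(raster, path) {
  px <- raster_pixels(raster)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Parent directory does not exist: %s", dirname(path)))
  }
  png::writePNG(px / 255, path)
  invisible(path)
}

raster_pixels <- function(x) {
  if (inherits(x, c("page_raster", "crop_image", "mask_map"))) x$pixels else x
}

#' Render a document into page rasters
#'
#' Converts a document into an ordered list of [page_raster()]s. Two inputs
#' are supported: a directory of page images (PNG/JPEG/TIFF, ordered
#' lexicographically by file name) and a PDF file. PDF rendering shells out to
#' the first of `pdftoppm`, `mutool` or `gs` found on `PATH`; if none is
#' available a fatal error names the file.
#'
#' @param document_path Path to a PDF file or a directory of page images.
#' @param dpi Rendering resolution for PDF input (default 300); attached as
#'   provenance for directory input.
#' @return List of [page_raster()]s with `page_index` `0..n-1`.
#' @export
render_document <- function(document_path, dpi = 300) {
  if (dir.exists(document_path)) {
    files <- list.files(document_path,
      pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
      ignore.case = TRUE, full.names = TRUE
    )
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L) {
      abort(sprintf("Document has zero pages: %s", document_path))
    }
    src <- basename(normalizePath(document_path))
    return(purrr::imap(files, function(f, i) {
      load_raster(f, source_id = src, page_index = i - 1L, dpi = dpi)
    }))
  }
  if (!file.exists(document_path)) {
    abort(sprintf("No such document: %s", document_path))
  }
  ext <- tolower(tools::file_ext(document_path))
  if (ext %in% c("png", "jpg", "jpeg", "tif", "tiff")) {
    return(list(load_raster(document_path,
      source_id = basename(document_path),
      page_index = 0L, dpi = dpi
    )))
  }
  if (ext == "pdf") {
    return(render_pdf(document_path, dpi))
  }
  abort(sprintf("Unsupported document type '.%s': %s", ext, document_path))
}

render_pdf <- function(path, dpi) {
  out <- tempfile("pdfpages")
  dir.create(out)
  ok <- FALSE
  if (nzchar(Sys.which("pdftoppm"))) {
    status <- system2("pdftoppm",
      c("-png", "-r", dpi, shQuote(path), shQuote(file.path(out, "page"))),
      stdout = FALSE, stderr = FALSE
    )
    ok <- status == 0L
  } else if (nzchar(Sys.which("mutool"))) {
    status <- system2("mutool",
      c("draw", "-r", dpi, "-o", shQuote(file.path(out, "page-%03d.png")), shQuote(path)),
      stdout = FALSE, stderr = FALSE
    )
    ok <- status == 0L
  } else if (nzchar(Sys.which("gs"))) {
    status <- system2("gs",
      c(
        "-dBATCH", "-dNOPAUSE", "-sDEVICE=png16m", paste0("-r", dpi),
        paste0("-sOutputFile=", shQuote(file.path(out, "page-%03d.png"))), shQuote(path)
      ),
      stdout = FALSE, stderr = FALSE
    )
    ok <- status == 0L
  } else {
    abort(sprintf(
      "Cannot render PDF %s: no PDF rasterizer (pdftoppm, mutool or gs) found on PATH. Render pages to a directory of PNGs instead.",
      path
    ))
  }
  if (!ok) abort(sprintf("PDF rendering failed (unreadable or encrypted?): %s", path))
  pages <- render_document(out, dpi = dpi)
  src <- basename(path)
  purrr::map(pages, function(p) {
    p$source_id <- src
    p
  })
}
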