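test_that("page rendering is deterministic for a fixed (spec, seed)", {
  spec <- fixture_spec(seed = 7L)
  a <- render_fixture_page(spec, 7001L)
  b <- render_fixture_page(spec, 7001L)
  expect_identical(a$page$pixels, b$page$pixels)
  expect_identical(a$truth$boxes, b$truth$boxes)
  c <- render_fixture_page(spec, 7002L)
  expect_false(identical(a$page$pixels, c$page$pixels))
})

test_that("a zero-structure spec renders text-only pages with empty ground truth", {
  spec <- fixture_spec(seed = 3L, structures_per_page = c(0L, 0L))
  pg <- render_fixture_page(spec, 301L)
  expect_equal(nrow(pg$truth$boxes), 0)
  expect_length(pg$truth$glyph_masks, 0)
  expect_true(any(pg$page$pixels == 0)) # text ink is present
})

test_that("ground-truth boxes are exactly the glyph masks' bounding boxes", {
  spec <- fixture_spec(seed = 13L)
  pg <- render_fixture_page(spec, 1301L)
  for (g in seq_len(nrow(pg$truth$boxes))) {
    idx <- which(pg$truth$glyph_masks[[g]], arr.ind = TRUE)
    expect_equal(pg$truth$boxes$y0[g], min(idx[, 1]) - 1L)
    expect_equal(pg$truth$boxes$y1[g], max(idx[, 1]))
    expect_equal(pg$truth$boxes$x0[g], min(idx[, 2]) - 1L)
    expect_equal(pg$truth$boxes$x1[g], max(idx[, 2]))
  }
})

test_that("glyph pixel counts respect the geometric lower bound from the segments", {
  withr::with_seed(55, {
    for (i in 1:8) {
      size <- runif(1, 120, 200)
      gs <- molseg:::glyph_segments(size)
      ras <- molseg:::rasterize_segments(gs$segments, 5L)
      bound <- molseg:::glyph_pixel_lower_bound(gs$segments, 5L)
      expect_gte(nrow(ras$xy), bound)
    }
  })
})

test_that("planted noise blobs stay separable and clear of glyph strokes", {
  spec <- fixture_spec(seed = 17L, noise_blobs = c(1L, 2L))
  for (i in 1:5) {
    pg <- render_fixture_page(spec, derive_seed(17L, i))
    if (length(pg$truth$noise_masks) == 0) next
    min_glyph <- min(purrr::map_int(pg$truth$glyph_masks, sum))
    for (nm in pg$truth$noise_masks) {
      expect_lt(sum(nm), 0.5 * min_glyph)
      # clearance: no glyph pixel within 8 px (the closing diameter)
      bl <- which(nm, arr.ind = TRUE)
      for (gm in pg$truth$glyph_masks) {
        gi <- which(gm, arr.ind = TRUE)
        d2 <- outer(bl[, 1], gi[, 1], "-")^2 + outer(bl[, 2], gi[, 2], "-")^2
        expect_gt(sqrt(min(d2)), 8)
      }
    }
  }
})

test_that("make_mask_case produces exact, well-separated component counts", {
  mc <- make_mask_case(c(89872L, 5725L))
  comps <- label_components(mc$mask, 8L)
  expect_setequal(comps$pixel_count, c(89872L, 5725L))
  mc2 <- make_mask_case(c(63060L, 47419L))
  expect_setequal(label_components(mc2$mask)$pixel_count, c(63060L, 47419L))
  # the same counts measured under 4-connectivity too (shapes are 4-connected)
  expect_setequal(label_components(mc2$mask, 4L)$pixel_count, c(63060L, 47419L))

  one <- make_mask_case(c(1L))
  expect_equal(label_components(one$mask)$pixel_count, 1L)

  expect_error(make_mask_case(c(100L), canvas = c(5, 5)), "Infeasible")
  expect_error(make_mask_case(integer()), "counts >= 1")
})

test_that("corrupt: identity edge cases and degradation direction", {
  spec <- fixture_spec(seed = 9L, structures_per_page = c(1L, 1L))
  pg <- render_fixture_page(spec, 901L)
  expect_identical(corrupt(pg$page, "low_res", factor = 1)$pixels, pg$page$pixels)
  expect_identical(corrupt(pg$page, "colored", fraction = 0)$pixels, pg$page$pixels)
  expect_error(corrupt(pg$page, "low_res", factor = 0.5), ">= 1")
  expect_error(corrupt(pg$page, "colored", fraction = 2), "\\[0, 1\\]")

  lo <- corrupt(pg$page, "low_res", factor = 3)
  expect_equal(dim(lo$pixels), dim(pg$page$pixels))
  expect_false(identical(lo$pixels, pg$page$pixels))

  withr::with_seed(99, {
    col <- corrupt(pg$page, "colored", fraction = 0.5)
  })
  expect_length(dim(col$pixels), 3)
})

test_that("low-resolution corruption never improves recovery", {
  spec <- fixture_spec(seed = 21L, structures_per_page = c(1L, 3L),
                       noise_blobs = c(0L, 0L))
  clean_dir <- withr::local_tempdir()
  low_dir <- withr::local_tempdir()
  truth_pages <- list()
  for (i in 1:4) {
    pg <- render_fixture_page(spec, derive_seed(21L, i), page_index = i - 1L)
    save_raster(pg$page, file.path(clean_dir, sprintf("p%02d.png", i)))
    save_raster(corrupt(pg$page, "low_res", factor = 3),
                file.path(low_dir, sprintf("p%02d.png", i)))
    truth_pages[[i]] <- pg$truth
  }
  score <- function(dir) {
    pages <- render_document(dir)
    res <- run_pipeline(pages, pipeline_config())
    hits <- 0L
    total <- 0L
    for (i in seq_along(pages)) {
      feet <- purrr::map(
        purrr::keep(res$extractions, function(e) e$lineage$page_index == i - 1L),
        molseg:::extraction_footprint, page_width = pages[[i]]$width
      )
      for (gm in truth_pages[[i]]$glyph_masks) {
        total <- total + 1L
        gset <- which(t(gm)) - 1L
        ious <- purrr::map_dbl(feet, molseg:::set_iou, b = gset)
        if (length(ious) && max(ious) >= 0.9) hits <- hits + 1L
      }
    }
    hits / total
  }
  expect_lte(score(low_dir), score(clean_dir))
})

test_that("RLE mask encoding round-trips through ground_truth.json", {
  d <- withr::local_tempdir()
  spec <- fixture_spec(seed = 29L, noise_blobs = c(1L, 1L))
  synth_corpus(spec, 2, d)
  gt <- read_ground_truth(d)
  expect_equal(gt$n_pages, 2)
  for (i in 1:2) {
    pg <- render_fixture_page(spec, derive_seed(29L, i), page_index = i - 1L)
    for (g in seq_along(pg$truth$glyph_masks)) {
      expect_identical(
        sort(gt$pages[[i]]$glyphs[[g]]$mask_idx),
        sort(which(t(pg$truth$glyph_masks[[g]])) - 1L)
      )
    }
  }
})

test_that("infeasible glyph packing fails loudly", {
  spec <- fixture_spec(page_width = 260L, page_height = 260L,
                       structures_per_page = c(6L, 6L), seed = 2L)
  expect_error(render_fixture_page(spec, 42L), "Infeasible packing")
})
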