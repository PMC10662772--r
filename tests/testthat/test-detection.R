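test_that("expand_box moves sides outward, clips at the page, flags expansion", {
  b <- detection_boxes(100L, 100L, 200L, 200L)
  e <- expand_box(b, 20L, 1000L, 1000L)
  expect_equal(unlist(e[, c("x0", "y0", "x1", "y1")]), c(x0 = 80L, y0 = 80L, x1 = 220L, y1 = 220L))
  expect_true(e$expanded)

  near_origin <- expand_box(detection_boxes(5L, 5L, 50L, 50L), 20L, 1000L, 1000L)
  expect_equal(unlist(near_origin[, 1:4]), c(x0 = 0L, y0 = 0L, x1 = 70L, y1 = 70L))

  full <- expand_box(detection_boxes(0L, 0L, 1000L, 1000L), 20L, 1000L, 1000L)
  expect_equal(unlist(full[, 1:4]), c(x0 = 0L, y0 = 0L, x1 = 1000L, y1 = 1000L))
})

test_that("expansion is monotone in margin, identity at 0, and stays on the page", {
  withr::with_seed(3, {
    for (i in 1:25) {
      w <- sample(50:500, 1)
      h <- sample(50:500, 1)
      x0 <- sample(0:(w - 2), 1)
      y0 <- sample(0:(h - 2), 1)
      b <- detection_boxes(x0, y0, sample((x0 + 1):w, 1), sample((y0 + 1):h, 1))
      m1 <- sample(0:30, 1)
      m2 <- m1 + sample(1:30, 1)
      e0 <- expand_box(b, 0L, w, h)
      e1 <- expand_box(b, m1, w, h)
      e2 <- expand_box(b, m2, w, h)
      expect_equal(unlist(e0[, 1:4]), unlist(b[, 1:4]))
      # larger margin gives a superset box; both contain the input
      expect_true(e2$x0 <= e1$x0 && e2$y0 <= e1$y0 && e2$x1 >= e1$x1 && e2$y1 >= e1$y1)
      expect_true(e1$x0 <= b$x0 && e1$y1 >= b$y1)
      expect_true(e2$x0 >= 0 && e2$y0 >= 0 && e2$x1 <= w && e2$y1 <= h)
    }
  })
})

test_that("crop size, content and paste-back identity hold exactly", {
  withr::with_seed(8, {
    px <- matrix(sample(0:255, 300 * 300, replace = TRUE) + 0, 300, 300)
  })
  page <- page_raster(px, source_id = "doc9", page_index = 4L)
  b <- detection_boxes(80L, 80L, 220L, 220L, expanded = TRUE)
  cr <- crop_page(page, b)
  expect_equal(dim(cr$pixels), c(140, 140))
  # crop pixel (i, j) equals page pixel (y0 + i, x0 + j)
  expect_identical(cr$pixels, px[81:220, 81:220])
  pasted <- px
  pasted[81:220, 81:220] <- cr$pixels
  expect_identical(pasted, px)
  # lineage travels with the crop
  expect_equal(cr$lineage$source_id, "doc9")
  expect_equal(cr$lineage$page_index, 4L)
  expect_equal(cr$lineage$box$x0, 80L)

  const <- crop_page(page_raster(matrix(77, 50, 50)), detection_boxes(10L, 10L, 30L, 40L))
  expect_true(all(const$pixels == 77))
  expect_equal(dim(const$pixels), c(30, 20))
})

test_that("baseline detector keeps structure glyphs and rejects text and solid pages", {
  # hollow square glyph is kept; a long thin text-like bar is rejected by aspect
  page <- rect_outline_page(500, 700, list(c(100, 100, 300, 300)))
  page$pixels[(420 + 1):(420 + 12), (100 + 1):500] <- 0 # 400x12 text line
  boxes <- detect_structures(page)
  expect_equal(nrow(boxes), 1)
  expect_gte(box_iou(boxes[1, ], list(x0 = 100, y0 = 100, x1 = 300, y1 = 300)), 0.99)

  # all-black page: single blob rejected by the ink-density upper limit
  black <- page_raster(matrix(0, 200, 200))
  expect_equal(nrow(detect_structures(black)), 0)

  # blank page: no ink, no detections
  blank <- page_raster(matrix(255, 200, 200))
  expect_equal(nrow(detect_structures(blank)), 0)

  # two glyphs separated beyond the merge gap give two boxes
  two <- rect_outline_page(400, 700, list(c(50, 50, 200, 200), c(400, 120, 560, 280)))
  expect_equal(nrow(detect_structures(two)), 2)
})

test_that("baseline detector recovers planted fixture glyphs with IoU >= 0.5 and ignores text", {
  spec <- fixture_spec(seed = 31L)
  hits <- 0L
  planted <- 0L
  extra <- 0L
  for (i in 1:6) {
    pg <- render_fixture_page(spec, derive_seed(31L, i))
    boxes <- detect_structures(pg$page)
    planted <- planted + nrow(pg$truth$boxes)
    for (g in seq_len(nrow(pg$truth$boxes))) {
      ious <- purrr::map_dbl(
        seq_len(nrow(boxes)),
        function(b) box_iou(boxes[b, ], pg$truth$boxes[g, ])
      )
      if (length(ious) && max(ious) >= 0.5) hits <- hits + 1L
    }
    extra <- extra + max(0L, nrow(boxes) - nrow(pg$truth$boxes))
  }
  expect_gt(planted, 0)
  expect_equal(hits, planted)
  expect_equal(extra, 0L) # no boxes planted over pure-text regions
})

test_that("box dedup drops only near-duplicates and keeps confidence order", {
  boxes <- detection_boxes(
    x0 = c(10L, 12L, 200L), y0 = c(10L, 12L, 200L),
    x1 = c(110L, 112L, 300L), y1 = c(110L, 112L, 300L),
    confidence = c(0.9, 0.8, 0.7)
  )
  kept <- dedup_boxes(boxes, 0.5)
  expect_equal(nrow(kept), 2)
  expect_true(200L %in% kept$x0)
  expect_true(10L %in% kept$x0)
})

test_that("invalid boxes are rejected", {
  expect_error(detection_boxes(10L, 10L, 10L, 20L), "x0 < x1")
  expect_error(detection_boxes(-1L, 0L, 5L, 5L), "x0 < x1|0 <=")
  expect_error(detection_boxes(0L, 0L, 5L, 5L, confidence = 1.2), "confidence")
  page <- page_raster(matrix(255, 50, 50))
  expect_error(crop_page(page, detection_boxes(0L, 0L, 60L, 10L)), "width")
})
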