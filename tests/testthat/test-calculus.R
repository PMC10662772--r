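test_that("labeling hand-checked masks: isolated pixels and diagonal adjacency", {
  px <- matrix(0, 5, 5)
  px[1, 1] <- 128
  px[5, 5] <- 128
  comps <- label_components(mask_map(px), 8L)
  expect_equal(nrow(comps), 2)
  expect_equal(comps$pixel_count, c(1L, 1L))

  diag2 <- matrix(0, 3, 3)
  diag2[1, 1] <- 128
  diag2[2, 2] <- 128
  expect_equal(nrow(label_components(mask_map(diag2), 8L)), 1)
  expect_equal(nrow(label_components(mask_map(diag2), 4L)), 2)

  expect_equal(nrow(label_components(mask_map(matrix(0, 4, 4)))), 0)
})

test_that("labels are assigned in raster-scan order of first-encountered pixels", {
  px <- matrix(0, 6, 9)
  px[4:6, 1:2] <- 128 # first pixel at (y=3, x=0) 0-based
  px[1:2, 5:6] <- 128 # first pixel at (y=0, x=4): should get label 1
  comps <- label_components(mask_map(px), 8L)
  expect_equal(comps$label, 1:2)
  expect_equal(comps$y0, c(0L, 3L))
})

test_that("labeling matches the independent flood-fill oracle on random masks", {
  withr::with_seed(101, {
    for (i in 1:60) {
      h <- sample(4:32, 1)
      w <- sample(4:32, 1)
      m <- random_mask(h, w, p = runif(1, 0.1, 0.7))
      for (conn in c(4L, 8L)) {
        got <- attr(label_components(m, conn), "label_matrix")
        expect_identical(got, oracle_label(m$pixels == 128, conn))
      }
      # conservation: component counts sum to the foreground total
      comps <- label_components(m, 8L)
      expect_identical(sum(comps$pixel_count), sum(m$pixels == 128))
    }
  })
})

test_that("pixel_ratio computes exact quotients; reporting truncates to 3 decimals", {
  expect_equal(pixel_ratio(5725, 89872), 5725 / 89872)
  expect_equal(truncate_pr(pixel_ratio(5725, 89872)), 0.063)
  expect_equal(truncate_pr(pixel_ratio(89872, 89872)), 1.0)
  # long division: 47419 / 63060 = 0.75196..., truncated 0.751 (not 0.752)
  expect_equal(truncate_pr(pixel_ratio(47419, 63060)), 0.751)
  expect_error(pixel_ratio(1, 0), "positive largest_count")
  expect_error(pixel_ratio(10, 5), "1, largest_count")
})

test_that("classification is strict at the threshold and monotone in count", {
  mk <- function(counts) {
    tibble::tibble(
      label = seq_along(counts), pixel_count = as.integer(counts),
      x0 = 0L, y0 = 0L, x1 = 1L, y1 = 1L,
      pr = NA_real_, pr_reported = NA_real_, verdict = NA_character_
    )
  }
  out <- classify_components(mk(c(100, 50)), calculus_config(prt = 0.5))
  expect_equal(out$pr[2], 0.5)
  expect_equal(out$verdict, c("genuine", "noise")) # pr == PRT is noise

  # largest-count ties all get pr 1 and genuine
  tied <- classify_components(mk(c(70, 70, 10)))
  expect_equal(tied$pr[1:2], c(1, 1))
  expect_equal(tied$verdict, c("genuine", "genuine", "noise"))

  # monotone: if a smaller component is genuine, every larger one is too
  withr::with_seed(77, {
    for (i in 1:30) {
      counts <- sample(1:500, sample(2:6, 1))
      cl <- classify_components(mk(counts), calculus_config(prt = runif(1)))
      genuine_counts <- cl$pixel_count[cl$verdict == "genuine"]
      noise_counts <- cl$pixel_count[cl$verdict == "noise"]
      expect_gte(length(genuine_counts), 1) # the largest is always genuine
      if (length(noise_counts) > 0) {
        expect_true(min(genuine_counts) >= max(noise_counts))
      }
      expect_equal(max(cl$pr), 1)
      expect_true(all(cl$pr > 0 & cl$pr <= 1))
    }
  })
})

test_that("min_pixels floor overrides PR when enabled", {
  mc <- make_mask_case(c(40, 30))
  comps <- label_components(mc$mask)
  cl <- classify_components(comps, calculus_config(min_pixels = 35L))
  expect_equal(sort(cl$verdict), c("genuine", "noise"))
})

test_that("separation is sound: disjoint single-component masks covering the genuine foreground", {
  mc <- make_mask_case(c(800, 700, 90)) # two genuine, one noise at PRT 0.5
  comps <- classify_components(label_components(mc$mask))
  singles <- separate_masks(mc$mask, comps)
  expect_length(singles, 2)
  fgs <- purrr::map(singles, function(m) which(m$pixels == 128))
  expect_length(intersect(fgs[[1]], fgs[[2]]), 0)
  genuine_labels <- comps$label[comps$verdict == "genuine"]
  lab <- attr(comps, "label_matrix")
  expect_setequal(union(fgs[[1]], fgs[[2]]), which(lab %in% genuine_labels))
  expect_true(all(purrr::map_int(singles, function(m) {
    nrow(label_components(m))
  }) == 1))
  # re-running label+classify+separate on each output is the identity
  for (m in singles) {
    again <- separate_masks(m, classify_components(label_components(m)))
    expect_length(again, 1)
    expect_identical(again[[1]]$pixels, m$pixels)
  }
})

test_that("apply_mask keeps crop pixels under the mask and fills elsewhere", {
  crop <- as_crop(matrix(100, 20, 40))
  left <- matrix(0, 20, 40)
  left[, 1:20] <- 128
  ex <- apply_mask(crop, mask_map(left))
  expect_true(all(ex$image[, 1:20] == 100))
  expect_true(all(ex$image[, 21:40] == 255))

  # all-foreground mask reproduces the crop exactly
  withr::with_seed(5, {
    px <- matrix(sample(0:254, 300, replace = TRUE) + 0, 15, 20)
  })
  full <- mask_map(matrix(128, 15, 20))
  expect_identical(apply_mask(as_crop(px), full)$image, px)

  # multi-component masks are a contract violation
  two <- matrix(0, 10, 10)
  two[1, 1] <- 128
  two[9, 9] <- 128
  expect_error(apply_mask(as_crop(matrix(0, 10, 10)), mask_map(two)), "single-component")
})

test_that("extraction purity: non-background pixels lie only inside the component", {
  withr::with_seed(41, {
    for (i in 1:10) {
      crop <- as_crop(matrix(sample(0:200, 900, replace = TRUE), 30, 30))
      m <- random_mask(30, 30, 0.3)
      comps <- classify_components(label_components(m))
      if (nrow(comps) == 0) next
      for (s in separate_masks(m, comps)) {
        ex <- apply_mask(crop, s)
        outside <- ex$image[s$pixels != 128]
        expect_true(all(outside == 255))
      }
    }
  })
})

test_that("tight_crop re-frames to the component box plus margin, clipped", {
  px <- matrix(0, 50, 50)
  px[11:20, 11:30] <- 128 # component box (10,10)-(30,20), 0-based half-open
  cfg <- calculus_config(tight_crop = TRUE, tight_margin = 5L)
  ex <- apply_mask(as_crop(matrix(7, 50, 50)), mask_map(px), cfg)
  expect_equal(dim(ex$image), c(10 + 10, 20 + 10))
  cfg2 <- calculus_config(tight_crop = TRUE, tight_margin = 50L)
  ex2 <- apply_mask(as_crop(matrix(7, 50, 50)), mask_map(px), cfg2)
  expect_equal(dim(ex2$image), c(50, 50)) # clipped at the crop
})

test_that("an empty mask yields zero extractions with a warning, not an error", {
  crop <- as_crop(matrix(255, 10, 10))
  expect_warning(res <- calculate_crop(crop, mask_map(matrix(0, 10, 10))), "Empty mask")
  expect_length(res$extractions, 0)
  expect_equal(nrow(res$components), 0)
})
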