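test_that("plan_tiles counts and defaults follow the tiling contract", {
  tp <- plan_tiles(c(5000, 4000), core_size = 2048)
  expect_equal(nrow(tp), ceiling(5000 / 2048) * ceiling(4000 / 2048))
  one <- plan_tiles(c(2048, 2048), core_size = 2048, context_size = 4096)
  expect_equal(nrow(one), 1L)
  expect_equal(one$core_h, 2048L)
  def <- formals(plan_tiles)
  expect_equal(eval(def$core_size), 2048L)
  expect_equal(eval(def$context_size), 10240L)
  expect_error(plan_tiles(c(100, 100), core_size = 0), "positive")
})

test_that("cores partition the slide exactly (half-open, random shapes)", {
  set.seed(42)
  for (i in 1:12) {
    shape <- sample(50:900, 2)
    core <- sample(30:400, 1)
    tp <- plan_tiles(shape, core, max(core, 512))
    cover <- matrix(0L, shape[1], shape[2])
    for (j in seq_len(nrow(tp))) {
      tl <- tp[j, ]
      cover[(tl$core_row0 + 1):(tl$core_row0 + tl$core_h),
            (tl$core_col0 + 1):(tl$core_col0 + tl$core_w)] <-
        cover[(tl$core_row0 + 1):(tl$core_row0 + tl$core_h),
              (tl$core_col0 + 1):(tl$core_col0 + tl$core_w)] + 1L
    }
    expect_true(all(cover == 1L))
  }
})

test_that("extract_tile copies real data and zero-fills beyond the slide", {
  set.seed(1)
  img <- matrix(sample(0:255, 300 * 300, TRUE), 300, 300)
  tp <- plan_tiles(c(300, 300), core_size = 100, context_size = 160)
  ## interior tile: entire context is inside the slide
  mid <- tp[tp$core_row0 == 100 & tp$core_col0 == 100, ]
  ext <- extract_tile(img, mid)
  expect_equal(ext, img[(mid$ctx_row0 + 1):(mid$ctx_row0 + 160),
                        (mid$ctx_col0 + 1):(mid$ctx_col0 + 160)],
               ignore_attr = TRUE)
  ## corner tile: positions outside the slide are zero
  corner <- tp[tp$core_row0 == 0 & tp$core_col0 == 0, ]
  extc <- extract_tile(img, corner)
  expect_true(all(extc[1:(-corner$ctx_row0), ] == 0))
  ## conservation: the cores of all extracted tiles reproduce the slide sum
  total <- 0
  for (j in seq_len(nrow(tp))) {
    tl <- tp[j, ]
    e <- extract_tile(img, tl)
    r0 <- tl$core_row0 - tl$ctx_row0
    c0 <- tl$core_col0 - tl$ctx_col0
    total <- total + sum(e[(r0 + 1):(r0 + tl$core_h), (c0 + 1):(c0 + tl$core_w)])
  }
  expect_equal(total, sum(img))
})

test_that("stitching keeps each cell exactly once, including boundary cells", {
  shape <- c(400, 400)
  tp <- plan_tiles(shape, core_size = 200, context_size = 300)
  set.seed(7)
  pts <- cbind(runif(300, 0, shape[1] - 1e-9), runif(300, 0, shape[2] - 1e-9))
  ## plant cells exactly on the shared core boundary
  pts <- rbind(pts, c(200, 57), c(131, 200), c(200, 200), c(0, 0))
  per_tile <- lapply(seq_len(nrow(tp)), function(j) {
    tl <- tp[j, ]
    inside <- pts[, 1] >= tl$ctx_row0 & pts[, 1] < tl$ctx_row0 + tl$ctx_size &
      pts[, 2] >= tl$ctx_col0 & pts[, 2] < tl$ctx_col0 + tl$ctx_size
    data.frame(local_row_px = pts[inside, 1] - tl$ctx_row0,
               local_col_px = pts[inside, 2] - tl$ctx_col0,
               truth_id = which(inside))
  })
  out <- stitch_cells(per_tile, tp)
  expect_equal(nrow(out), nrow(pts))
  expect_equal(sort(out$truth_id), seq_len(nrow(pts)))
  expect_equal(out$cell_id, seq_len(nrow(out)))
})

test_that("stitch_labels mosaics cores and keeps object ids unique", {
  tp1 <- plan_tiles(c(128, 128), core_size = 128, context_size = 128)
  m <- matrix(0L, 128, 128); m[10:20, 10:20] <- 3L
  expect_equal(stitch_labels(list(m), tp1), relabel_ids <- {
    r <- m; r[r > 0] <- 1L; r
  })
  tp4 <- plan_tiles(c(200, 200), core_size = 100, context_size = 140)
  masks <- lapply(seq_len(nrow(tp4)), function(j) {
    mm <- matrix(0L, 140, 140); mm[60:70, 60:70] <- 1L; mm
  })
  mosaic <- stitch_labels(masks, tp4)
  ids <- sort(unique(mosaic[mosaic > 0]))
  expect_equal(ids, 1:4)
})

test_that("raster and table files round-trip", {
  d <- tempdir()
  px <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  f <- file.path(d, "ch.tif")
  write_channel_tiff(channel_image(px, 0.64, "x"), f)
  expect_equal(read_channel_tiff(f, 0.64)$pixels, px, ignore_attr = TRUE)
  lab <- matrix(sample(0:1200, 32 * 32, TRUE), 32, 32)
  f2 <- file.path(d, "lab.tif")
  write_label_tiff(lab, f2)
  expect_identical(read_label_tiff(f2), lab)
  rgb <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  f3 <- file.path(d, "rgb.tif")
  write_rgb_tiff(rgb, f3)
  expect_equal(read_rgb_tiff(f3), rgb, ignore_attr = TRUE)
  cells <- data.frame(extra = 1:2, cell_id = 1:2, centroid_x_um = c(1, 2),
                      centroid_y_um = c(3, 4), mean_radius_px = c(5, 6),
                      gland_id = c(0L, 1L), compartment = c("stromal", "epithelial"),
                      class = c("other", "epithelial"),
                      CD4_raw = c(10, 20), CD4_norm = c(10, 20) / 255,
                      CD4_positive = c(FALSE, TRUE))
  f4 <- file.path(d, "cells.csv")
  write_cell_table(cells, f4)
  back <- read_cell_table(f4)
  expect_equal(names(back)[1:7],
               c("cell_id", "centroid_x_um", "centroid_y_um", "mean_radius_px",
                 "gland_id", "compartment", "class"))
  expect_equal(back$CD4_raw, cells$CD4_raw)
})
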