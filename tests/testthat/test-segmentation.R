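test_that("otsu_level separates two spikes and flags degenerate histograms", {
  h <- integer(256); h[50 + 1] <- 100; h[200 + 1] <- 100
  lev <- otsu_level(h)
  expect_gte(as.numeric(lev), 50)
  expect_lt(as.numeric(lev), 200)
  ## strict-> foreground rule separates the spikes at the returned level
  expect_true(200 > as.numeric(lev) && !(50 > as.numeric(lev)))
  const <- otsu_level(matrix(7, 6, 6))
  expect_equal(as.numeric(const), 7)
  expect_true(attr(const, "degenerate"))
  expect_error(otsu_level(integer(256)), "nonempty")
})

test_that("otsu_level equals the brute-force variance maximizer exactly", {
  set.seed(99)
  for (i in 1:30) {
    n1 <- sample(50:400, 1); n2 <- sample(50:400, 1)
    x <- c(pmin(pmax(round(rnorm(n1, runif(1, 30, 90), runif(1, 5, 25))), 0), 255),
           pmin(pmax(round(rnorm(n2, runif(1, 120, 220), runif(1, 5, 30))), 0), 255))
    counts <- tabulate(x + 1L, 256L)
    expect_identical(as.numeric(otsu_level(counts)),
                     as.numeric(otsu_bruteforce(counts)))
  }
})

test_that("adaptive thresholding reduces to global on uniform backgrounds", {
  set.seed(12)
  vals <- round(c(rnorm(200 * 180, 40, 6), rnorm(200 * 20, 190, 8)))
  img <- matrix(pmin(pmax(sample(vals), 0), 255), 200, 200)
  glob <- as.numeric(otsu_level(intensity_histogram(img)))
  map <- adaptive_otsu(img, 64)
  expect_lte(max(abs(map - glob)), 8)
  const_map <- adaptive_otsu(matrix(9, 64, 64), 32)
  expect_true(attr(const_map, "degenerate"))
  expect_error(adaptive_otsu(img, 16), "at least 32")
})

test_that("adaptive thresholding recovers objects on a background ramp", {
  ## linear background ramp + constant-offset objects: the global Otsu level
  ## sits inside the ramp, so it misses objects at the dim end; the adaptive
  ## map recovers every planted object
  nr <- 300
  ramp <- matrix(rep(seq(10, 200, length.out = nr), nr), nr, nr)
  centres <- rbind(c(50, 50), c(50, 250), c(150, 150), c(250, 50), c(250, 250))
  img <- ramp
  for (i in seq_len(nrow(centres)))
    img[centres[i, 1] + (-8:8), centres[i, 2] + (-8:8)] <-
      img[centres[i, 1] + (-8:8), centres[i, 2] + (-8:8)] + 45
  img <- round(img)
  glob <- as.numeric(otsu_level(intensity_histogram(img)))
  glob_hits <- sum(img[cbind(centres[, 1], centres[, 2])] > glob)
  expect_lt(glob_hits, nrow(centres))     # global threshold provably fails
  map <- adaptive_otsu(img, 75)
  expect_equal(sum(img[cbind(centres[, 1], centres[, 2])] >
                     map[cbind(centres[, 1], centres[, 2])]), nrow(centres))
})

test_that("touching glands are split and blank channels give no glands", {
  m <- matrix(0, 400, 600)
  xy <- expand.grid(r = 1:400, c = 1:600)
  e1 <- ((xy$r - 200) / 90)^2 + ((xy$c - 200) / 110)^2 <= 1
  e2 <- ((xy$r - 200) / 90)^2 + ((xy$c - 365) / 110)^2 <= 1  # 1.5 axes apart
  m[e1 | e2] <- 200
  gl <- segment_glands(m, segmentation_params(gland_threshold_mode = "global",
                                              gland_close_radius = 0L))
  expect_equal(max(gl), 2L)
  expect_equal(max(segment_glands(matrix(0, 128, 128))), 0L)
})

test_that("gland segmentation recovers planted glands with good overlap", {
  fx <- test_slide("epithelial", seed = 4L)
  sl <- fx$slide
  gl <- segment_glands(get_channel(sl$fl, "PanEpi"),
                       segmentation_params(gland_threshold_mode = "adaptive"))
  truth <- sl$truth
  t_phys <- wsicyto:::planted_phys_transform(fx$config)
  found <- 0; ious <- c()
  for (i in seq_len(nrow(truth$glands))) {
    g <- truth$glands[i, ]
    ## sample scene-frame points around the gland, map through the planted
    ## transform into fluorescence pixels, and compare membership
    span <- 1.3 * g$a_um
    pts <- expand.grid(r = seq(g$row_um - span, g$row_um + span, by = 1.5),
                       c = seq(g$col_um - span, g$col_um + span, by = 1.5))
    dr <- pts$r - g$row_um; dc <- pts$c - g$col_um
    lr <- dr * cos(g$theta) + dc * sin(g$theta)
    lc <- -dr * sin(g$theta) + dc * cos(g$theta)
    inside <- (lr / g$a_um)^2 + (lc / g$b_um)^2 <= 1
    fl_px <- round(apply_affine(t_phys, as.matrix(pts)) / 0.64 - 0.5) + 1
    keep <- fl_px[, 1] >= 1 & fl_px[, 1] <= nrow(gl) &
      fl_px[, 2] >= 1 & fl_px[, 2] <= ncol(gl)
    inside <- inside[keep]
    lab <- gl[fl_px[keep, , drop = FALSE]]
    hit <- lab[inside]
    if (!any(hit > 0)) next
    best <- as.integer(names(which.max(table(hit[hit > 0]))))
    iou <- sum(inside & lab == best) / sum(inside | lab == best)
    found <- found + 1
    ious <- c(ious, iou)
  }
  expect_gte(found, nrow(truth$glands) - 2)
  expect_gte(mean(ious >= 0.7), 0.85)
})

test_that("nuclei are detected, declumped, and size-filtered", {
  one <- blob_image(cbind(100, 100), sigma = 10, peak = 200, shape = c(200, 200))
  lab <- segment_nuclei(one, segmentation_params(adaptive_window = 64))
  expect_equal(max(lab), 1L)
  ## two overlapping blobs 30 px apart are split into two objects
  two <- blob_image(rbind(c(90, 100), c(120, 100)), sigma = 10, peak = 200,
                    shape = c(220, 220))
  lab2 <- segment_nuclei(two, segmentation_params(adaptive_window = 64))
  expect_equal(max(lab2), 2L)
  ## a blob far below the minimum diameter is discarded
  small <- blob_image(cbind(100, 100), sigma = 2.5, peak = 200, shape = c(200, 200))
  lab3 <- segment_nuclei(small, segmentation_params(adaptive_window = 64))
  expect_equal(max(lab3), 0L)
})

test_that("marker masks cover the high mode and reject blank channels", {
  set.seed(21)
  img <- matrix(round(c(rnorm(5000, 30, 5), rnorm(1000, 200, 10))), 60, 100)
  img <- pmin(pmax(img, 0), 255)
  mask <- marker_mask(img)
  expect_gt(mean(mask[img > 150]), 0.99)
  expect_lt(mean(mask[img < 60]), 0.01)
  expect_false(any(marker_mask(matrix(7, 50, 50))))
  ## pure noise (no signal mode) yields an empty mask, not speckle
  noise <- pmax(round(matrix(rnorm(10000, 8, 2), 100, 100)), 0)
  expect_false(any(marker_mask(noise)))
})

test_that("label masks have contiguous ids and disjoint objects", {
  fx <- test_slide("immune")
  lab <- segment_nuclei(get_channel(fx$slide$fl, "nuclei"))
  ids <- sort(unique(as.vector(lab[lab > 0])))
  expect_equal(ids, seq_along(ids))
})
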