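test_that("identical config and seed give bit-identical slides", {
  cfg <- slide_sim_config(image_height_px = 1024L, image_width_px = 1024L,
                          cell_density = 500, gland_axes = c(60, 90),
                          rng_seed = 7L)
  a <- generate_slide(cfg)
  b <- generate_slide(cfg)
  expect_identical(a$fl$channels, b$fl$channels)
  expect_identical(a$bf, b$bf)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$glands, b$truth$glands)
})

test_that("zero cell density gives empty truth and background-only channels", {
  cfg <- slide_sim_config(image_height_px = 512L, image_width_px = 512L,
                          cell_density = 0, gland_axes = c(40, 60),
                          rng_seed = 2L)
  sl <- generate_slide(cfg)
  expect_equal(nrow(sl$truth$cells), 0L)
  ## background + noise only: nothing near a blob peak
  expect_lt(max(sl$fl$channels$nuclei), cfg$autofluorescence_level + 8 * cfg$noise_sd)
})

test_that("truth class draws are multinomial around the planted proportions", {
  cfg <- slide_sim_config(scheme = "immune", image_height_px = 5504L,
                          image_width_px = 5504L, cell_density = 800,
                          rng_seed = 11L)
  truth <- sample_truth(cfg)
  n <- nrow(truth$cells)
  expect_gt(n, 7000)
  grp <- ifelse(grepl("Treg|Th$|Te$|leukocyte", truth$cells$class), "leukocyte",
                ifelse(truth$cells$class == "epithelial", "epithelial", "stromal"))
  for (cls in names(cfg$class_proportions)) {
    p <- cfg$class_proportions[[cls]]
    key <- if (cls == "stromal") "stromal" else cls
    p_hat <- mean(grp == key)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("generate_slide and sample_truth agree for the same seed", {
  cfg <- slide_sim_config(image_height_px = 1024L, image_width_px = 1024L,
                          cell_density = 500, gland_axes = c(60, 90),
                          rng_seed = 5L)
  expect_identical(generate_slide(cfg)$truth$cells, sample_truth(cfg)$cells)
})

test_that("truth satisfies its geometric invariants", {
  for (scheme in c("immune", "epithelial")) {
    fx <- test_slide(scheme)
    tc <- fx$slide$truth$cells
    extent <- c(fx$config$image_height_px, fx$config$image_width_px) *
      fx$config$fl_resolution
    expect_true(all(tc$row_um > 0 & tc$row_um < extent[1]))
    expect_true(all(tc$col_um > 0 & tc$col_um < extent[2]))
    if (scheme == "epithelial") {
      g <- fx$slide$truth$glands
      mal_ids <- g$gland_id[g$malignant]
      expect_false(any(tc$class == "basal" & tc$gland_id %in% mal_ids))
    }
  }
})

test_that("render_brightfield follows the Beer-Lambert model", {
  sm <- stain_matrix(rbind(a = c(0.65, 0.70, 0.29), b = c(0.27, 0.57, 0.78),
                           c = c(0.7, 0.2, 0.69)))
  zero <- list(a = matrix(0, 4, 4), b = matrix(0, 4, 4), c = matrix(0, 4, 4))
  expect_equal(as.vector(render_brightfield(zero, sm)),
               rep(255, 48))
  one <- zero; one$a[] <- 1
  out <- render_brightfield(one, sm)
  expect_equal(out[1, 1, ], 255 * 10^(-unclass(sm)[1, ]),
               ignore_attr = TRUE, tolerance = 1e-12)
  neg <- zero; neg$b[1, 1] <- -0.1
  expect_error(render_brightfield(neg, sm), "negative")
})

test_that("rendering is monotone: more stain never brightens a channel", {
  sm <- synthetic_stain_matrix()
  set.seed(4)
  base <- lapply(1:3, function(i) matrix(runif(64, 0, 0.6), 8, 8))
  names(base) <- rownames(sm)
  img0 <- render_brightfield(base, sm)
  for (s in names(base)) {
    up <- base
    up[[s]] <- up[[s]] + 0.2
    expect_true(all(render_brightfield(up, sm) <= img0 + 1e-9))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(slide_sim_config(class_proportions = c(a = 0.5, b = 0.6)),
               "sum to 1")
  expect_error(slide_sim_config(image_height_px = 0), "image_height_px")
})

test_that("a slide bundle round-trips through disk", {
  fx <- test_slide("immune")
  d <- file.path(tempdir(), "bundle-test")
  write_synthetic_slide(fx$slide, d)
  nuc <- read_channel_tiff(file.path(d, "nuclei.tif"), 0.64)
  expect_equal(nuc$pixels, unname(fx$slide$fl$channels$nuclei),
               ignore_attr = TRUE)
  tf <- read_transform_json(file.path(d, "truth_transform.json"))
  expect_equal(tf$A, fx$slide$truth$transform$A, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
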