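make_label_disc <- function(shape, centre, radius) {
  m <- matrix(0L, shape[1], shape[2])
  xy <- expand.grid(r = 1:shape[1], c = 1:shape[2])
  m[(xy$r - centre[1])^2 + (xy$c - centre[2])^2 <= radius^2] <- 1L
  m
}

test_that("measure_cells reports means, radii, centroids and compartments", {
  lab <- make_label_disc(c(64, 64), c(32, 32), 10)
  ch <- matrix(100, 64, 64)
  cells <- measure_cells(lab, list(CD4 = ch), resolution = 0.64)
  expect_equal(cells$CD4_raw, 100)
  expect_equal(cells$CD4_norm, 100 / 255)
  expect_equal(cells$mean_radius_px, sqrt(cells$area_px / pi))
  expect_equal(cells$centroid_x_um, (cells$col_px + 0.5) * 0.64)
  ## area-100 object: mean radius = sqrt(100/pi)
  lab2 <- matrix(0L, 20, 20); lab2[1:10, 1:10] <- 1L
  c2 <- measure_cells(lab2, list(x = matrix(0, 20, 20)))
  expect_equal(c2$mean_radius_px, sqrt(100 / pi))
  ## empty mask gives an empty, well-formed table
  c3 <- measure_cells(matrix(0L, 16, 16), list(x = matrix(0, 16, 16)))
  expect_equal(nrow(c3), 0L)
  expect_true(all(c("cell_id", "x_raw", "x_norm") %in% names(c3)))
  ## gland containment decides the compartment
  glands <- matrix(0L, 64, 64); glands[20:45, 20:45] <- 1L
  c4 <- measure_cells(lab, list(x = ch), glands = glands)
  expect_equal(c4$compartment, "epithelial")
  expect_equal(c4$gland_id, 1L)
})

test_that("positivity thresholds use mean + k * population SD, strict", {
  v <- c(rep(0, 9), 1)
  th <- positivity_threshold(v, 1)
  expect_equal(th, 0.4)                  # mean 0.1, population SD 0.3
  expect_equal(sum(v > th), 1L)
  expect_equal(positivity_threshold(rep(0.3, 8), 1), 0.3)
  expect_equal(sum(rep(0.3, 8) > 0.3), 0L)   # all-equal: zero positives
  expect_error(positivity_threshold(numeric(0)), "no values")
  ## Ki67 default multiplier is 3
  expect_equal(panel_config("immune")$sd_multiplier[["Ki67"]], 3)
  ## positivity is invariant under the raw <-> normalized rescaling
  set.seed(2)
  raw <- runif(50, 0, 255)
  pos_raw <- raw > positivity_threshold(raw, 1)
  pos_norm <- (raw / 255) > positivity_threshold(raw / 255, 1)
  expect_identical(pos_raw, pos_norm)
})

test_that("immune classification maps marker patterns to the documented labels", {
  base <- expand.grid(cd45 = c(TRUE, FALSE), cd4 = c(TRUE, FALSE),
                      cd8 = c(TRUE, FALSE), foxp3 = c(TRUE, FALSE),
                      compartment = c("epithelial", "stromal"),
                      stringsAsFactors = FALSE)
  cells <- data.frame(compartment = base$compartment, cd45_pos = base$cd45,
                      CD4_positive = base$cd4, CD8_positive = base$cd8,
                      FoxP3_positive = base$foxp3)
  out <- classify_immune(cells)
  expected <- function(r) {
    pre <- if (r$compartment == "epithelial") "epi" else "stromal"
    if (!r$cd45) return(if (r$compartment == "epithelial") "epithelial" else "other")
    if (r$cd4 && r$foxp3 && !r$cd8) return(paste0(pre, "-Treg"))
    if (r$cd4 && !r$foxp3 && !r$cd8) return(paste0(pre, "-Th"))
    if (r$cd8 && !r$cd4 && !r$foxp3) return(paste0(pre, "-Te"))
    paste0(pre, "-leukocyte-other")
  }
  for (i in seq_len(nrow(out)))
    expect_equal(out$class[i], expected(base[i, ]))
  ## CD4+CD8+ double positives match none of the three T definitions
  dp <- out[out$cd45_pos & out$CD4_positive & out$CD8_positive, ]
  expect_true(all(grepl("leukocyte-other", dp$class)))
  ## every cell gets exactly one label from the closed set
  expect_true(all(out$class %in% wsicyto:::immune_class_levels))
  expect_error(classify_immune(cells[, -3]), "CD4_positive")
})

test_that("gland rule: malignancy is the complete absence of basal cells", {
  cells <- data.frame(
    gland_id     = c(1L, 1L, 1L, 2L, 2L, 0L),
    basal_overlap = c(0.50, 0.09, 0.00, 0.05, 0.02, 0.80))
  out <- classify_glands_and_epithelial(cells)
  expect_equal(out$glands$malignant, c(FALSE, TRUE))
  expect_equal(out$glands$n_basal_cells, c(1L, 0L))
  ## benign gland: basal if overlap >= 10%, else benign luminal (9% is below)
  expect_equal(out$cells$class[1:3], c("basal", "benign-luminal", "benign-luminal"))
  ## cancer gland: every nucleus is a cancer cell
  expect_equal(out$cells$class[4:5], c("cancer", "cancer"))
  ## outside glands: stromal, whatever the overlap
  expect_equal(out$cells$class[6], "stromal")
  ## invariant: malignant => zero basal cells
  expect_true(all(out$glands$n_basal_cells[out$glands$malignant] == 0L))
  expect_true(all(out$cells$class %in% wsicyto:::epithelial_class_levels))
})

test_that("summarize_panel reproduces hand-computed proportions", {
  cells <- data.frame(
    class = c(rep("epithelial", 4), rep("other", 2),
              "epi-Th", "epi-Th", "stromal-Te", "stromal-Te"),
    compartment = c(rep("epithelial", 4), rep("stromal", 2),
                    "epithelial", "epithelial", "stromal", "stromal"),
    Ki67_positive = rep(FALSE, 10))
  s <- summarize_panel(cells, "immune")
  expect_equal(s$leukocytes$pct_of_cells, 40)
  expect_equal(s$leukocytes$pct_epithelial, 50)
  th_epi <- s$t_classes[s$t_classes$t_class == "Th" &
                          s$t_classes$compartment == "epithelial", ]
  expect_equal(th_epi$pct_of_leukocytes, 100)   # both epithelial leukocytes are Th
  te_str <- s$t_classes[s$t_classes$t_class == "Te" &
                          s$t_classes$compartment == "stromal", ]
  expect_equal(te_str$pct_of_leukocytes, 100)
  ## Th share of all leukocytes is 50%
  expect_equal(sum(s$class_distribution$n[s$class_distribution$class
                                          %in% c("epi-Th", "stromal-Th")]) /
                 s$leukocytes$n * 100, 50)
  ## empty input: zero-filled summary
  s0 <- summarize_panel(cells[0, ], "immune")
  expect_equal(s0$n_cells, 0L)
  expect_true(all(s0$class_distribution$pct == 0))
})

test_that("epithelial summaries stratify AR by AMACR status", {
  cells <- data.frame(
    class = c("cancer", "cancer", "benign-luminal", "stromal"),
    AR_norm = c(0.2, 0.1, 0.1, 0.02),
    AMACR_positive = c(TRUE, FALSE, FALSE, FALSE),
    CK18_norm = c(0.2, 0.2, 0.12, 0.01))
  s <- summarize_panel(cells, "epithelial")
  g <- s$ar_by_amacr
  expect_equal(g$mean_ar_norm[g$class == "cancer" & g$amacr], 0.2)
  expect_equal(g$mean_ar_norm[g$class == "cancer" & !g$amacr], 0.1)
  expect_equal(s$marker_means$CK18_norm[s$marker_means$class == "cancer"], 0.2)
})

test_that("mask overlap fractions drive CD45 calls", {
  lab <- matrix(0L, 40, 40)
  lab[5:14, 5:14] <- 1L        # 100 px object
  lab[25:34, 25:34] <- 2L
  mask <- matrix(FALSE, 40, 40)
  mask[5:14, 5:9] <- TRUE      # 50% of object 1, 0% of object 2
  ov <- mask_overlap(lab, mask)
  expect_equal(ov, c(0.5, 0))
})
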