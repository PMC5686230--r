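test_that("affine transform algebra round-trips", {
  tf <- affine_transform(matrix(c(1.02, 0.08, -0.08, 1.02), 2), c(12.5, -3.1))
  pts <- matrix(runif(20, 0, 100), 10, 2)
  back <- apply_affine(invert_affine(tf), apply_affine(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  comp <- compose_affine(invert_affine(tf), tf)
  expect_lt(max(abs(comp$A - diag(2))), 1e-9)
  expect_lt(max(abs(comp$t)), 1e-9)
  ## rescaling to a grid and back is the identity
  s <- compose_affine(scale_transform(1.76, 0.64), scale_transform(0.64, 1.76))
  expect_lt(max(abs(s$A - diag(2))), 1e-12)
  expect_lt(max(abs(s$t)), 1e-12)
  expect_error(affine_transform(matrix(0, 2, 2)), "singular")
})

test_that("the blob detector finds planted blobs and nothing on flat images", {
  flat <- matrix(37, 128, 128)
  expect_equal(nrow(detect_and_describe(flat)$keypoints), 0L)
  set.seed(2)
  pos <- cbind(runif(10, 40, 215), runif(10, 40, 215))
  ## enforce separation
  pos <- pos[c(TRUE, sapply(2:10, function(i)
    all(sqrt(rowSums((pos[1:(i - 1), , drop = FALSE] -
                        matrix(pos[i, ], i - 1, 2, byrow = TRUE))^2)) > 25))), ]
  img <- blob_image(pos, sigma = 3)
  kp <- detect_and_describe(img)
  expect_gte(nrow(kp$keypoints), nrow(pos))
  for (i in seq_len(nrow(pos))) {
    d <- sqrt((kp$keypoints$row - pos[i, 1])^2 + (kp$keypoints$col - pos[i, 2])^2)
    expect_lt(min(d), 2)
  }
  ## determinism
  kp2 <- detect_and_describe(img)
  expect_identical(kp$keypoints, kp2$keypoints)
  expect_identical(kp$descriptors, kp2$descriptors)
  expect_error(detect_and_describe(matrix(0, 8, 8)), "smaller")
})

test_that("descriptor matching passes self-matches and rejects impostors", {
  ## blobs with distinct sizes/contrasts so descriptors are discriminative
  img <- blob_image(cbind(c(70, 120, 180, 70, 150), c(70, 60, 170, 180, 110)),
                    sigma = c(2.5, 3.2, 4, 2.8, 3.6),
                    peak = c(120, 160, 200, 240, 140))
  kp <- detect_and_describe(img)
  m <- match_descriptors(kp, kp)
  expect_equal(m[, 1], m[, 2])
  expect_equal(nrow(m), nrow(kp$keypoints))
  ## an impostor with an orthogonal descriptor stays unmatched
  imp <- matrix(0, 1, 64)
  imp[1, 64] <- 1                       # |dc| sums are nonnegative features
  imp[1, 1] <- -1
  b <- list(descriptors = rbind(kp$descriptors, imp))
  m2 <- match_descriptors(kp, b)
  expect_false((nrow(kp$keypoints) + 1L) %in% m2[, 2])
  expect_equal(nrow(match_descriptors(list(descriptors = matrix(0, 0, 64)), kp)), 0L)
})

test_that("robust affine estimation recovers planted transforms", {
  set.seed(9)
  pa <- cbind(runif(80, 0, 500), runif(80, 0, 500))
  matches <- cbind(1:80, 1:80)
  ## identity
  tf <- estimate_affine(matches, pa, pa)
  expect_lt(max(abs(tf$A - diag(2))), 1e-6)
  expect_lt(max(abs(tf$t)), 1e-6)
  ## translation with 30% gross outliers
  pb <- sweep(pa, 2, c(12, -7), "+")
  out_idx <- 1:24
  pb[out_idx, ] <- pb[out_idx, ] + matrix(runif(48, 30, 200), 24, 2)
  tf2 <- estimate_affine(matches, pa, pb)
  expect_lt(sqrt(sum((tf2$t - c(12, -7))^2)), 0.5)
  expect_equal(attr(tf2, "fit")$n_inliers, 56L)
  ## 5 degree rotation + scale 1.02
  th <- 5 * pi / 180
  A <- 1.02 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pb3 <- pa %*% t(A) + matrix(c(3, 4), 80, 2, byrow = TRUE)
  tf3 <- estimate_affine(matches, pa, pb3)
  expect_lt(max(abs(tf3$A - A)) / max(abs(A)), 1e-2)
  ## failure is signalled distinctly
  expect_error(estimate_affine(matches[1:2, , drop = FALSE], pa, pb3),
               class = "wsicyto_registration_error")
})

test_that("consensus refit equals the closed-form least squares on clean input", {
  set.seed(13)
  pa <- cbind(runif(40, 0, 300), runif(40, 0, 300))
  A <- matrix(c(1.01, 0.03, -0.02, 0.99), 2)
  pb <- pa %*% t(A) + matrix(c(5, -2), 40, 2, byrow = TRUE) +
    matrix(rnorm(80, 0, 0.3), 40, 2)
  tf <- estimate_affine(cbind(1:40, 1:40), pa, pb)
  ## normal-equations oracle
  X <- cbind(pa, 1)
  beta <- solve(t(X) %*% X, t(X) %*% pb)
  expect_lt(max(abs(tf$A - t(beta[1:2, ]))), 1e-9)
  expect_lt(max(abs(tf$t - beta[3, ])), 1e-9)
})

test_that("planted similarity transforms are recovered within tolerance", {
  pair <- simulate_registration_pair(n_blobs = 150, shape = c(512, 512),
                                     rotation_deg = 8, scale = 1.02,
                                     translation_px = c(8.3, -5.7),
                                     noise_sd = 4, seed = 21)
  km <- detect_and_describe(pair$moving)
  kr <- detect_and_describe(pair$reference)
  m <- match_descriptors(km, kr)
  tf <- estimate_affine(m, as.matrix(km$keypoints[, 1:2]),
                        as.matrix(kr$keypoints[, 1:2]))
  expect_lt(sqrt(sum((tf$t - pair$transform$t)^2)), 0.5)
  rot <- atan2(tf$A[2, 1], tf$A[1, 1]) * 180 / pi
  expect_lt(abs(rot - 8), 0.2)
})

test_that("register_modalities aligns a synthetic modality pair on the 0.64 grid", {
  fx <- test_slide("immune")
  sl <- fx$slide; cfg <- fx$config
  conc <- deconvolve(sl$bf, cfg$stain_matrix, downscale = 2)
  haem <- channel_image(pmin(255 * conc$maps[[1]], 255),
                        cfg$bf_resolution * 2, "haematoxylin")
  reg <- register_modalities(haem, get_channel(sl$fl, "nuclei"))
  expect_equal(reg$transform$target_resolution, 0.64)
  ## compare against the planted transform on control points
  t_true <- compose_affine(scale_transform(cfg$bf_resolution, 0.64),
                           sl$truth$transform)
  set.seed(1)
  cp <- cbind(runif(200, 100, 1400), runif(200, 100, 1400))
  err <- sqrt(rowSums((apply_affine(reg$transform, cp) -
                         apply_affine(t_true, cp))^2))
  expect_lt(sqrt(mean(err^2)), 1)
  expect_gt(reg$diagnostics$n_inliers, 50)
  ## identical modality pair reduces to the identity
  nuc <- get_channel(sl$fl, "nuclei")
  reg2 <- register_modalities(nuc, nuc, ref_work_res = 2.56,
                              mov_work_res = 2.56, out_res = 0.64)
  expect_lt(max(abs(reg2$transform_working$A - diag(2))), 1e-3)
  expect_lt(max(abs(reg2$transform_working$t)), 0.1)
})

test_that("anti-aliased downscaling preserves the mean of smooth images", {
  set.seed(3)
  base <- matrix(runif(16, 60, 200), 4, 4)
  img <- channel_image(wsicyto:::gauss_blur(base[rep(1:4, each = 64), rep(1:4, each = 64)], 8),
                       0.64, "smooth")
  for (res in c(1.28, 1.76, 2.56)) {
    down <- resample_channel(img, res)
    expect_lt(abs(mean(down$pixels) - mean(img$pixels)) / mean(img$pixels), 0.02)
    expect_equal(down$resolution, res)
  }
})
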