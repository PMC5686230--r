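test_that("optical density conversion follows -log10(I/255)", {
  white <- array(255, c(2, 2, 3))
  expect_equal(as.vector(rgb_to_od(white)), rep(0, 12))
  I <- array(25.5, c(1, 1, 3))
  expect_equal(as.vector(rgb_to_od(I)), rep(1, 3), tolerance = 1e-12)
  ## monotone: darker pixels have higher OD
  a <- array(100, c(1, 1, 3)); b <- array(90, c(1, 1, 3))
  expect_true(all(rgb_to_od(b) > rgb_to_od(a)))
  ## clamp keeps OD finite at zero intensity
  expect_true(all(is.finite(rgb_to_od(array(0, c(1, 1, 3))))))
})

test_that("two-stain matrices complete with an orthogonal third vector", {
  m <- complete_stain_matrix(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unclass(m)[3, ], c(R = 0, G = 0, B = 1))
  m2 <- complete_stain_matrix(rbind(c(0.65, 0.70, 0.29), c(0.27, 0.57, 0.78)))
  expect_gt(abs(det(unclass(m2))), 1e-3)
  expect_equal(rowSums(unclass(m2)^2), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(complete_stain_matrix(rbind(c(1, 0, 0), c(2, 0, 0))), "parallel")
  ## a 2-stain mixture deconvolves with ~zero third-channel concentration
  set.seed(5)
  maps <- list(s1 = matrix(runif(64, 0, 0.6), 8, 8),
               s2 = matrix(runif(64, 0, 0.6), 8, 8),
               residual = matrix(0, 8, 8))
  names(maps) <- rownames(m2)
  rgb <- render_brightfield(maps, m2)
  rec <- deconvolve(round(rgb), m2, downscale = 1)
  expect_lt(max(rec$maps[[3]]), 0.02)
})

test_that("render then deconvolve recovers concentrations within quantization", {
  sm <- synthetic_stain_matrix()
  set.seed(8)
  maps <- lapply(1:3, function(i) matrix(runif(256, 0, 0.7), 16, 16))
  names(maps) <- rownames(sm)
  rgb <- round(render_brightfield(maps, sm))
  rec <- deconvolve(rgb, sm, downscale = 1)
  ## per-pixel error bound propagated through |M^-1| from a half-gray-level
  Minv_abs <- abs(solve(unclass(sm)))
  od_err <- 0.5 / (pmax(rgb, 1) * log(10))
  bound <- array(0, dim(rgb))
  for (s in 1:3) {
    err_s <- od_err[, , 1] * Minv_abs[1, s] + od_err[, , 2] * Minv_abs[2, s] +
      od_err[, , 3] * Minv_abs[3, s]
    expect_true(all(abs(rec$maps[[s]] - maps[[s]]) <= err_s + 1e-9))
  }
})

test_that("round trip through rendering is stable within one gray level", {
  sm <- synthetic_stain_matrix()
  set.seed(10)
  maps <- lapply(1:3, function(i) matrix(runif(100, 0, 0.7), 10, 10))
  names(maps) <- rownames(sm)
  rgb <- round(render_brightfield(maps, sm))
  rec <- deconvolve(rgb, sm, downscale = 1)
  rgb2 <- render_brightfield(rec$maps, sm)
  expect_lte(max(abs(rgb2 - rgb)), 1)
})

test_that("deconvolution handles white input, defaults and linearity", {
  sm <- default_stain_matrix()
  white <- array(255, c(8, 8, 3))
  rec <- deconvolve(white, sm, downscale = 1)
  expect_equal(max(vapply(rec$maps, max, 0)), 0)
  expect_equal(eval(formals(deconvolve)$downscale), 4L)
  ## doubling concentrations doubles the recovered ones (pre-clipping)
  maps <- list(matrix(0.2, 4, 4), matrix(0.15, 4, 4), matrix(0.1, 4, 4))
  names(maps) <- rownames(sm)
  r1 <- deconvolve(render_brightfield(maps, sm), sm, downscale = 1)
  maps2 <- lapply(maps, function(m) 2 * m)
  r2 <- deconvolve(render_brightfield(maps2, sm), sm, downscale = 1)
  for (s in 1:3)
    expect_equal(r2$maps[[s]], 2 * r1$maps[[s]], tolerance = 0.02)
})

test_that("area-average downscale feeds the deconvolution", {
  sm <- synthetic_stain_matrix()
  maps <- list(matrix(0.4, 8, 8), matrix(0.2, 8, 8), matrix(0.1, 8, 8))
  names(maps) <- rownames(sm)
  rgb <- render_brightfield(maps, sm)
  rec <- deconvolve(rgb, sm, downscale = 4)
  expect_equal(dim(rec$maps[[1]]), c(2L, 2L))
  expect_equal(rec$maps[[1]], matrix(0.4, 2, 2), tolerance = 0.01)
  expect_equal(rec$downscale, 4L)
})
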