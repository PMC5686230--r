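test_that("fisher_exact_2x2 matches hand-enumerated tables", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("fisher p agrees with stats::fisher.test and is swap-symmetric", {
  set.seed(31)
  for (i in 1:40) {
    tb <- matrix(sample(1:25, 4, TRUE), 2)
    p <- fisher_exact_2x2(tb)$p_value
    expect_equal(p, stats::fisher.test(tb)$p.value, tolerance = 1e-9)
    swapped <- tb[2:1, 2:1]
    expect_equal(p, fisher_exact_2x2(swapped)$p_value, tolerance = 1e-12)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("KS statistic is the ECDF supremum with sane p-values", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_two_sample(1:3, 4:6)
  expect_equal(disjoint$statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
  ## brute-force oracle over all sample points, random pairs
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(5:60, 1)); y <- rnorm(sample(5:60, 1), 0.3)
    D <- ks_two_sample(x, y)$statistic
    pts <- c(x, y)
    D_bf <- max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p),
                           numeric(1))))
    expect_equal(D, D_bf, tolerance = 1e-12)
    ## same D as stats::ks.test, and similar asymptotic p
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(D, unname(kt$statistic), tolerance = 1e-12)
    expect_equal(ks_two_sample(x, y)$p_value, kt$p.value, tolerance = 1e-3)
  }
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rgamma(40, 2); y <- rgamma(55, 2.5)
  D0 <- ks_two_sample(x, y)$statistic
  expect_equal(ks_two_sample(log(x), log(y))$statistic, D0)
  expect_equal(ks_two_sample(x^3, y^3)$statistic, D0)
})

test_that("pearson_r equals the product-moment formula with a t-test p", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10)
  r <- pearson_r(a, b)
  direct <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(r$statistic, direct, tolerance = 1e-12)
  ct <- stats::cor.test(a, b)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("signal-to-background follows its definition and pixel minimum", {
  bg <- rep(10, 1000)
  expect_equal(as.numeric(signal_to_background(rep(110, 50), bg)), 10)
  expect_equal(as.numeric(signal_to_background(rep(10, 50), bg)), 0)
  expect_error(signal_to_background(rep(110, 50), rep(10, 999)), "at least 1000")
  ## noise-thresholded variant drops signal pixels at or below the
  ## background Otsu level before averaging
  set.seed(3)
  bg2 <- pmax(0, round(rnorm(2000, 10, 2)))
  sig <- c(rep(5, 100), rep(120, 100))
  plain <- as.numeric(signal_to_background(sig, bg2))
  thresh <- as.numeric(signal_to_background(sig, bg2, noise_threshold = TRUE))
  expect_gt(thresh, plain)
})

test_that("heat retention is the post/pre object mean-intensity ratio", {
  set.seed(9)
  pre <- matrix(5, 200, 200)
  for (ctr in list(c(50, 50), c(140, 60), c(100, 150)))
    pre[ctr[1] + (-9:9), ctr[2] + (-9:9)] <- 180       # 361 px objects
  pre[22:27, 150:155] <- 180     # small object: still <= 100 px after dilation
  ret <- heat_retention(pre, pre)
  expect_equal(as.numeric(ret), 100, tolerance = 1e-9)
  half <- heat_retention(pre, pre * 0.5)
  expect_equal(as.numeric(half), 50, tolerance = 1e-6)
  expect_equal(attr(ret, "n_objects"), 3L)             # the small object is out
  expect_error(heat_retention(matrix(5, 50, 50), matrix(5, 50, 50)), "objects")
})
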