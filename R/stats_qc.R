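## Statistical tests and imaging QC metrics used by the tissue-cytometry
## analyses: Fisher's exact test (two-tailed, probability-mass method) for
## cell-count comparisons, the two-sample Kolmogorov-Smirnov test for marker
## expression distributions, Pearson correlation for continuous marker
## relationships, and the signal-to-background / heat-retention metrics used
## to qualify the imaging assay.

#' QC parameters
#'
#' @param min_background_pixels minimum number of blank pixels required for a
#'   background estimate (default 1000).
#' @param min_object_area minimum object size (pixels) entering the
#'   heat-retention measurement (objects must be strictly larger; default
#'   100).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_background_pixels = 1000L, min_object_area = 100L) {
  stopifnot(min_background_pixels > 0, min_object_area > 0)
  structure(list(min_background_pixels = as.integer(min_background_pixels),
                 min_object_area = as.integer(min_object_area)),
            class = "qc_params")
}

stat_result <- function(test_name, statistic, p_value, n) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.6g, p = %.4g (n = %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Fisher's exact test for a 2 x 2 table (two-tailed)
#'
#' Exact two-tailed p-value by the probability-mass method: with the margins
#' fixed, the p-value is the sum of hypergeometric probabilities of all
#' tables no more probable than the observed one (a relative tolerance of
#' 1e-7 guards ties against floating-point noise).
#'
#' @param table 2 x 2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return A `stat_result` with the chi-squared statistic (no continuity
#'   correction) as `statistic` and the exact two-tailed p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- matrix(as.numeric(table), 2L, 2L)
  if (any(tb < 0) || any(tb != round(tb))) stop("counts must be nonnegative integers")
  r <- rowSums(tb); cs <- colSums(tb); N <- sum(tb)
  if (any(r == 0) || any(cs == 0)) stop("zero margin")
  x <- tb[1, 1]
  lo <- max(0, cs[1] - r[2]); hi <- min(r[1], cs[1])
  support <- lo:hi
  dens <- stats::dhyper(support, cs[1], cs[2], r[1])
  p_obs <- dens[support == x]
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  expected <- outer(r, cs) / N
  chi2 <- sum((tb - expected)^2 / expected)
  stat_result("fisher_exact_2x2", chi2, p, n = N)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution at effective sample
#' size `n m / (n + m)` (appropriate for the large samples of whole-slide
#' cytometry).
#'
#' @param x,y numeric samples (nonempty).
#' @return A `stat_result` with `statistic = D`.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample")
  n <- length(x); m <- length(y)
  pts <- sort(unique(c(x, y)))
  ## ECDFs evaluated at all sample points
  Fx <- findInterval(pts, sort(x)) / n
  Fy <- findInterval(pts, sort(y)) / m
  D <- max(abs(Fx - Fy))
  ne <- n * m / (n + m)
  t_stat <- sqrt(ne) * D
  if (t_stat < 0.2) {
    p <- 1                      # series limit; survival probability ~ 1 here
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t_stat^2))
    p <- min(1, max(0, p))
  }
  stat_result("ks_two_sample", D, p, n = c(n, m))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value uses the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, both with nonzero variance.
#' @return A `stat_result` with `statistic = r`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  stat_result("pearson_r", r, p, n = n)
}

#' Signal-to-background ratio
#'
#' `B` is the mean of the background pixels, `S` the background-corrected
#' signal `mean(signal) - B`; the ratio is `S / B`. At least
#' `params$min_background_pixels` blank pixels are required. With
#' `noise_threshold = TRUE`, signal pixels at or below the Otsu level of the
#' background pixel histogram are excluded before averaging (an optional
#' autofluorescence-noise variant; off by default).
#'
#' @param signal_pixels,background_pixels numeric vectors of 8-bit
#'   intensities.
#' @param params [qc_params()].
#' @param noise_threshold logical, see above.
#' @return The S/B ratio (numeric), with attributes `S` and `B`.
#' @export
signal_to_background <- function(signal_pixels, background_pixels,
                                 params = qc_params(),
                                 noise_threshold = FALSE) {
  if (length(background_pixels) < params$min_background_pixels)
    stop(sprintf("need at least %d background pixels (got %d)",
                 params$min_background_pixels, length(background_pixels)))
  B <- mean(background_pixels)
  if (B == 0) stop("zero background; S/B undefined")
  sig <- signal_pixels
  if (noise_threshold) {
    lev <- otsu_level(tabulate(as.integer(quantize8(background_pixels)) + 1L,
                               nbins = 256L))
    sig <- sig[sig > as.numeric(lev)]
    if (!length(sig)) stop("no signal pixels above the background noise level")
  }
  S <- mean(sig) - B
  structure(S / B, S = S, B = B)
}

#' Fluorochrome heat-retention measurement
#'
#' Segments objects on the pre-heating image (Otsu binarization, dilation,
#' watershed declumping), keeps objects strictly larger than
#' `params$min_object_area` pixels, and reports
#' `100 * mean(object mean intensity in post) / mean(object mean intensity
#' in pre)` over the same objects.
#'
#' @param pre_image,post_image co-acquired [channel_image]s or matrices
#'   (0--255).
#' @param params [qc_params()].
#' @return Percent retained (numeric), with attribute `n_objects`.
#' @export
heat_retention <- function(pre_image, post_image, params = qc_params()) {
  pre <- if (inherits(pre_image, "channel_image")) pre_image$pixels
    else as_pixel_matrix(pre_image)
  post <- if (inherits(post_image, "channel_image")) post_image$pixels
    else as_pixel_matrix(post_image)
  if (!all(dim(pre) == dim(post))) stop("image pair shapes differ")
  lev <- otsu_level(intensity_histogram(pre))
  if (isTRUE(attr(lev, "degenerate"))) stop("no qualifying objects")
  binary <- (pre > as.numeric(lev)) * 1
  binary <- EBImage::imageData(EBImage::dilate(binary, EBImage::makeBrush(3L, "disc")))
  dm <- EBImage::imageData(EBImage::distmap(binary))
  labels <- as_label_matrix(EBImage::imageData(EBImage::watershed(dm, tolerance = 1)))
  area <- tabulate(labels[labels > 0L])
  labels <- drop_objects(labels, which(area <= params$min_object_area))
  idx <- which(labels > 0L)
  if (!length(idx)) stop("no qualifying objects")
  lab <- labels[idx]
  n <- max(lab)
  a <- tabulate(lab, nbins = n)
  mean_pre <- as.vector(rowsum(pre[idx], lab)) / a
  mean_post <- as.vector(rowsum(post[idx], lab)) / a
  structure(100 * mean(mean_post) / mean(mean_pre), n_objects = n)
}
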