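## Shared fixtures, generated in code and memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

## a small but complete synthetic slide (both modalities + truth)
test_slide <- function(scheme = "immune", seed = 3L, size = 1536L,
                       density = 800) {
  key <- paste(scheme, seed, size, density)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- slide_sim_config(scheme = scheme, image_height_px = size,
                            image_width_px = size, cell_density = density,
                            rng_seed = seed)
    .fixture_cache[[key]] <- list(config = cfg, slide = generate_slide(cfg))
  }
  .fixture_cache[[key]]
}

## tile-friendly run configuration for small test slides
small_run_config <- function(core = 1024L, context = 1536L)
  run_config(core_size = core, context_size = context, deconv_downscale = 2L)

## pipeline run on the cached small slide, memoized
test_run <- function(scheme = "immune", seed = 3L) {
  key <- paste("run", scheme, seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- test_slide(scheme, seed)
    .fixture_cache[[key]] <- run_panel(
      fx$slide$fl, fx$slide$bf, fx$config$bf_resolution,
      fx$config$stain_matrix, panel_config(scheme), small_run_config())
  }
  .fixture_cache[[key]]
}

## image with n Gaussian blobs at known positions (for detector tests)
blob_image <- function(positions, sigma = 3, peak = 200, shape = c(256, 256),
                       background = 5, noise_sd = 0, seed = 1) {
  img <- matrix(background, shape[1], shape[2])
  sigma <- rep(sigma, length.out = nrow(positions))
  peak <- rep(peak, length.out = nrow(positions))
  for (i in seq_len(nrow(positions))) {
    r <- positions[i, 1]; c <- positions[i, 2]
    rr <- max(1, round(r - 4 * sigma[i])):min(shape[1], round(r + 4 * sigma[i]))
    cc <- max(1, round(c - 4 * sigma[i])):min(shape[2], round(c + 4 * sigma[i]))
    img[rr, cc] <- img[rr, cc] +
      peak[i] * exp(-outer((rr - 1 - r)^2, (cc - 1 - c)^2, "+") /
                      (2 * sigma[i]^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(prod(shape), 0, noise_sd), shape[1], shape[2])
  }
  pmin(pmax(round(img), 0), 255)
}

## brute-force Otsu oracle: per-level between-class variance by direct sums
otsu_bruteforce <- function(counts) {
  v <- 0:255
  best <- -Inf; best_t <- 0
  total_w <- sum(counts)
  total_s <- sum(counts * v)
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)])
    w1 <- total_w - w0
    if (w0 == 0 || w1 == 0) next
    s0 <- sum(counts[1:(t + 1)] * v[1:(t + 1)])
    m0 <- s0 / w0
    m1 <- (total_s - s0) / w1
    sigma_b <- w0 * w1 * (m0 - m1)^2
    if (sigma_b > best) { best <- sigma_b; best_t <- t }
  }
  best_t
}

## full hypergeometric enumeration oracle for the two-tailed Fisher p-value
fisher_enumeration <- function(tb) {
  r <- rowSums(tb); cs <- colSums(tb)
  lo <- max(0, cs[1] - r[2]); hi <- min(r[1], cs[1])
  p_tab <- function(a) {
    b <- r[1] - a; c <- cs[1] - a; d <- r[2] - c
    exp(lgamma(r[1] + 1) + lgamma(r[2] + 1) + lgamma(cs[1] + 1) +
          lgamma(cs[2] + 1) - lgamma(sum(r) + 1) - lgamma(a + 1) -
          lgamma(b + 1) - lgamma(c + 1) - lgamma(d + 1))
  }
  probs <- vapply(lo:hi, p_tab, numeric(1))
  p_obs <- probs[which(lo:hi == tb[1, 1])]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
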