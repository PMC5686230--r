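## Gland and nucleus segmentation.
##
## Two pipelines: epithelial glands are thresholded (global or adaptive Otsu)
## on the pan-epithelium channel, morphologically closed, hole-filled (lumina
## count as gland interior) and split by watershed seeded at distance-map
## maxima; nuclei are thresholded by adaptive Otsu and declumped by
## seeded region growing from smoothed intensity peaks, then filtered to the
## 20-80 px equivalent-diameter range.

#' Segmentation parameters
#'
#' @param nucleus_diameter_range accepted equivalent-circle diameters of
#'   nuclei, pixels (default `c(20, 80)`).
#' @param adaptive_window block size of adaptive Otsu thresholding, pixels
#'   (default 200).
#' @param gland_min_area minimum gland area, px^2 (default 500 at 0.64
#'   um/px; removes speckle).
#' @param smoothing_sigma Gaussian sigma (px) applied before nuclear peak
#'   detection (default 2).
#' @param gland_threshold_mode `"global"` or `"adaptive"` Otsu for the gland
#'   channel.
#' @param gland_close_radius radius (px) of the morphological closing that
#'   bridges the epithelial cell ring before hole filling (default 14).
#' @param gland_watershed_tol minimum distance-map depth (px) separating two
#'   gland seeds (default 25; smaller values over-split wiggly outlines).
#' @param min_threshold_contrast minimum separation (gray levels) between the
#'   two Otsu classes for a threshold to count as signal; histograms split
#'   less widely than this (background-only regions, where Otsu would carve
#'   up noise) are treated as signal-free (default 16).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(nucleus_diameter_range = c(20, 80),
                                adaptive_window = 200L,
                                gland_min_area = 500,
                                smoothing_sigma = 2,
                                gland_threshold_mode = c("global", "adaptive"),
                                gland_close_radius = 14L,
                                gland_watershed_tol = 25,
                                min_threshold_contrast = 16) {
  stopifnot(length(nucleus_diameter_range) == 2L,
            nucleus_diameter_range[1] < nucleus_diameter_range[2],
            adaptive_window > 0, gland_min_area >= 0, smoothing_sigma > 0)
  structure(list(nucleus_diameter_range = as.numeric(nucleus_diameter_range),
                 adaptive_window = as.integer(adaptive_window),
                 gland_min_area = as.numeric(gland_min_area),
                 smoothing_sigma = as.numeric(smoothing_sigma),
                 gland_threshold_mode = match.arg(gland_threshold_mode),
                 gland_close_radius = as.integer(gland_close_radius),
                 gland_watershed_tol = as.numeric(gland_watershed_tol),
                 min_threshold_contrast = as.numeric(min_threshold_contrast)),
            class = "segmentation_params")
}

#' Otsu threshold level of an 8-bit histogram
#'
#' Returns the level `t` in 0..255 maximizing the between-class variance of
#' the split into classes `<= t` and `> t` (foreground is strictly above the
#' level). Ties are broken toward the lower level. A single-valued
#' (degenerate) histogram returns that value with attribute
#' `degenerate = TRUE`.
#'
#' @param histogram integer vector of 256 counts for levels 0..255, or a
#'   numeric raster on the 0--255 scale (its histogram is taken).
#' @return Numeric level in `[0, 255]`, attribute `degenerate`.
#' @export
otsu_level <- function(histogram) {
  if (is.matrix(histogram)) histogram <- intensity_histogram(histogram)
  counts <- as.numeric(histogram)
  if (length(counts) != 256L) stop("histogram must have 256 bins (levels 0..255)")
  if (any(counts < 0) || sum(counts) == 0) stop("histogram must be nonempty")
  nz <- which(counts > 0)
  if (length(nz) == 1L)
    return(structure(nz - 1, degenerate = TRUE))
  v <- 0:255
  w0 <- cumsum(counts)
  w1 <- w0[256] - w0
  s0 <- cumsum(counts * v)
  m0 <- s0 / w0
  m1 <- (s0[256] - s0) / w1
  sigma_b <- w0 * w1 * (m0 - m1)^2
  sigma_b[!is.finite(sigma_b)] <- -Inf
  sigma_b[256] <- -Inf                      # empty foreground split
  best <- which.max(sigma_b)
  structure(v[best], degenerate = FALSE, contrast = m1[best] - m0[best])
}

#' Per-pixel adaptive Otsu threshold map
#'
#' The Otsu level is computed per block of roughly `window x window` pixels
#' and bilinearly interpolated between block centres (clamped beyond the
#' outermost centres). Blocks with a degenerate (single-valued) histogram
#' fall back to the global Otsu level, as does the whole map when `window`
#' exceeds the image (attribute `fallback = TRUE`).
#'
#' @param image [channel_image] or numeric matrix (0--255).
#' @param window nominal block size in pixels (>= 32).
#' @param min_contrast minimum Otsu class separation (gray levels): blocks
#'   splitting less widely fall back to the global level, and an image whose
#'   global split is below it is treated as signal-free (threshold above the
#'   whole range; attribute `low_contrast = TRUE`).
#' @return Numeric matrix of per-pixel threshold levels; attribute
#'   `degenerate = TRUE` when the whole image is single-valued.
#' @export
adaptive_otsu <- function(image, window = 200L, min_contrast = 0) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_pixel_matrix(image)
  window <- as.integer(window)
  if (window < 32L) stop("adaptive window must be at least 32 px")
  glob <- otsu_level(intensity_histogram(px))
  nr <- nrow(px); nc <- ncol(px)
  if (isTRUE(attr(glob, "degenerate")))
    return(structure(matrix(as.numeric(glob), nr, nc), degenerate = TRUE))
  if (attr(glob, "contrast") < min_contrast)
    return(structure(matrix(255, nr, nc), low_contrast = TRUE))
  if (window > min(nr, nc)) {
    return(structure(matrix(as.numeric(glob), nr, nc), fallback = TRUE))
  }
  nbr <- max(1L, round(nr / window)); nbc <- max(1L, round(nc / window))
  rb <- floor(seq(0L, nr, length.out = nbr + 1L))
  cb <- floor(seq(0L, nc, length.out = nbc + 1L))
  levels <- matrix(NA_real_, nbr, nbc)
  q <- quantize8(px)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    blk <- q[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
    lev <- otsu_level(tabulate(as.integer(blk) + 1L, nbins = 256L))
    levels[i, j] <- if (isTRUE(attr(lev, "degenerate")) ||
                          isTRUE(attr(lev, "contrast") < min_contrast))
      as.numeric(glob) else as.numeric(lev)
  }
  ## bilinear interpolation from block centres (0-based pixel coordinates)
  rc <- (rb[-1] + rb[-length(rb)]) / 2 - 0.5
  cc <- (cb[-1] + cb[-length(cb)]) / 2 - 0.5
  interp_axis <- function(centres, n, vals_mat, along_rows) {
    ## vals_mat interpolated along one axis onto 0..n-1
    x <- 0:(n - 1)
    if (length(centres) == 1L) {
      m <- if (along_rows) matrix(vals_mat[1, ], n, ncol(vals_mat), byrow = TRUE)
        else matrix(vals_mat[, 1], nrow(vals_mat), n)
      return(m)
    }
    if (along_rows) {
      apply(vals_mat, 2L, function(vv)
        approx(centres, vv, xout = x, rule = 2)$y)
    } else {
      t(apply(vals_mat, 1L, function(vv)
        approx(centres, vv, xout = x, rule = 2)$y))
    }
  }
  rows_interp <- interp_axis(rc, nr, levels, TRUE)       # nr x nbc
  interp_axis(cc, nc, rows_interp, FALSE)                # nr x nc
}

#' Binary marker mask by global Otsu thresholding
#'
#' Pixels strictly above the global Otsu level are set `TRUE`. Degenerate
#' (single-valued) channels, and channels whose Otsu classes separate by
#' less than `min_contrast` gray levels (background-only channels, where a
#' threshold would only carve up noise), yield an all-`FALSE` mask.
#'
#' @param channel [channel_image] or numeric matrix (0--255).
#' @param min_contrast minimum Otsu class separation, gray levels.
#' @return Logical matrix.
#' @export
marker_mask <- function(channel, min_contrast = 16) {
  px <- if (inherits(channel, "channel_image")) channel$pixels else as_pixel_matrix(channel)
  lev <- otsu_level(intensity_histogram(px))
  if (isTRUE(attr(lev, "degenerate")) || attr(lev, "contrast") < min_contrast)
    return(matrix(FALSE, nrow(px), ncol(px)))
  px > as.numeric(lev)
}

#' Segment epithelial glands
#'
#' Thresholds the pan-epithelium channel (global or adaptive Otsu per
#' `params$gland_threshold_mode`), bridges the epithelial cell ring by
#' morphological closing, fills holes so lumina count as gland interior,
#' splits touching glands by watershed seeded at distance-transform maxima,
#' and removes objects below `params$gland_min_area`.
#'
#' @param pan_epi [channel_image] or matrix: fluorescent pan-epithelium
#'   channel, or the de-convolved green-chromogen map rescaled to 0--255.
#' @param params [segmentation_params()].
#' @return Integer label matrix (ids 1..N contiguous; 0 = background).
#' @export
segment_glands <- function(pan_epi, params = segmentation_params()) {
  px <- if (inherits(pan_epi, "channel_image")) pan_epi$pixels else as_pixel_matrix(pan_epi)
  thr <- switch(params$gland_threshold_mode,
                global = {
                  lev <- otsu_level(intensity_histogram(px))
                  if (isTRUE(attr(lev, "degenerate")) ||
                        attr(lev, "contrast") < params$min_threshold_contrast)
                    return(matrix(0L, nrow(px), ncol(px)))
                  matrix(as.numeric(lev), 1L, 1L)
                },
                adaptive = adaptive_otsu(px, params$adaptive_window,
                                         params$min_threshold_contrast))
  if (isTRUE(attr(thr, "degenerate")))
    return(matrix(0L, nrow(px), ncol(px)))
  binary <- if (length(thr) == 1L) px > thr[1] else px > thr
  if (!any(binary)) return(matrix(0L, nrow(px), ncol(px)))
  storage.mode(binary) <- "double"
  if (params$gland_close_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$gland_close_radius + 1L, "disc")
    binary <- EBImage::imageData(EBImage::closing(binary, brush))
  }
  binary <- EBImage::imageData(EBImage::fillHull(binary))
  labels <- split_touching_glands(binary, params$gland_watershed_tol)
  area <- tabulate(labels[labels > 0L])
  drop_objects(labels, which(area < params$gland_min_area))
}

## distance-transform watershed declumping of a filled gland mask. The
## split decision is made on a 4x subsampled grid (gland geometry is
## hundreds of pixels, so the coarse distance map carries the same maxima);
## only connected components that the coarse watershed actually divides are
## re-run at full resolution within their bounding box.
split_touching_glands <- function(binary, tolerance) {
  comp <- as_label_matrix(EBImage::imageData(EBImage::bwlabel(binary)))
  n_comp <- max(comp, 0L)
  if (n_comp == 0L) return(comp)
  sub_r <- seq(1L, nrow(binary), by = 4L)
  sub_c <- seq(1L, ncol(binary), by = 4L)
  small <- binary[sub_r, sub_c]
  dm_s <- EBImage::imageData(EBImage::distmap(small))
  ws_s <- as_label_matrix(EBImage::imageData(
    EBImage::watershed(dm_s, tolerance = tolerance / 4, ext = 1L)))
  comp_s <- comp[sub_r, sub_c]
  sel <- ws_s > 0L & comp_s > 0L
  ## number of coarse watershed objects per component
  pairs <- unique(comp_s[sel] + n_comp * as.numeric(ws_s[sel]))
  per_comp <- tabulate((pairs - 1L) %% n_comp + 1L, nbins = n_comp)
  needs_split <- which(per_comp > 1L)
  if (!length(needs_split)) return(comp)
  out <- comp
  out[out %in% needs_split] <- 0L
  next_id <- n_comp
  nr <- nrow(binary)
  for (ci in needs_split) {
    idx <- which(comp == ci)
    rr <- range((idx - 1L) %% nr) + 1L
    cc <- range((idx - 1L) %/% nr) + 1L
    crop <- (comp[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == ci) * 1
    dm <- EBImage::imageData(EBImage::distmap(crop))
    ws <- as_label_matrix(EBImage::imageData(
      EBImage::watershed(dm, tolerance = tolerance, ext = 1L)))
    pos <- ws > 0L
    out[rr[1]:rr[2], cc[1]:cc[2]][pos] <- ws[pos] + next_id
    next_id <- next_id + max(ws)
  }
  relabel_mask(out)
}

## greedy peak picking with a minimum separation, strongest peak first;
## returns (row, col) 1-based integer coordinates
find_peaks <- function(img, min_sep, candidates) {
  if (!length(candidates)) return(matrix(integer(), 0L, 2L))
  nr <- nrow(img)
  v <- img[candidates]
  o <- order(-v, candidates)
  cand <- candidates[o]
  rr <- (cand - 1L) %% nr + 1L
  cc <- (cand - 1L) %/% nr + 1L
  cell <- as.integer(ceiling(min_sep))
  br <- rr %/% cell; bc <- cc %/% cell
  key <- paste(br, bc)
  buckets <- new.env(parent = emptyenv())
  keep <- logical(length(cand))
  min2 <- min_sep^2
  for (i in seq_along(cand)) {
    ok <- TRUE
    for (dr in -1:1) {
      for (dc in -1:1) {
        k <- paste(br[i] + dr, bc[i] + dc)
        prev <- buckets[[k]]
        if (!is.null(prev) &&
            any((rr[prev] - rr[i])^2 + (cc[prev] - cc[i])^2 < min2)) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      keep[i] <- TRUE
      buckets[[key[i]]] <- c(buckets[[key[i]]], i)
    }
  }
  cbind(rr[keep], cc[keep])
}

#' Segment cell nuclei
#'
#' Adaptive Otsu thresholding of the nuclear channel, declumping by seeded
#' region growing from smoothed intensity peaks (minimum peak separation =
#' the minimum accepted nucleus diameter), and removal of objects whose
#' equivalent-circle diameter `2 sqrt(A/pi)` falls outside
#' `params$nucleus_diameter_range`.
#'
#' @param nuclear [channel_image] or numeric matrix (0--255).
#' @param params [segmentation_params()].
#' @return Integer label matrix (ids 1..N contiguous; 0 = background).
#' @export
segment_nuclei <- function(nuclear, params = segmentation_params()) {
  px <- if (inherits(nuclear, "channel_image")) nuclear$pixels else as_pixel_matrix(nuclear)
  thr <- adaptive_otsu(px, params$adaptive_window,
                       params$min_threshold_contrast)
  if (isTRUE(attr(thr, "degenerate")))
    return(matrix(0L, nrow(px), ncol(px)))
  binary <- px > thr
  if (!any(binary)) return(matrix(0L, nrow(px), ncol(px)))
  storage.mode(binary) <- "double"
  binary <- EBImage::imageData(EBImage::fillHull(binary))
  smoothed <- gauss_blur(px, params$smoothing_sigma)
  ## local maxima of the smoothed intensity inside the foreground
  nr <- nrow(px); nc <- ncol(px)
  interior <- matrix(FALSE, nr, nc)
  interior[2:(nr - 1), 2:(nc - 1)] <- TRUE
  cand <- which(binary > 0 & interior)
  if (length(cand)) {
    s <- smoothed
    is_max <- rep(TRUE, length(cand))
    for (off in c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L))
      is_max <- is_max & s[cand] >= s[cand + off]
    cand <- cand[is_max]
  }
  peaks <- find_peaks(smoothed, params$nucleus_diameter_range[1], cand)
  if (nrow(peaks) == 0L) return(matrix(0L, nrow(px), ncol(px)))
  seeds <- matrix(0L, nr, nc)
  seeds[peaks] <- seq_len(nrow(peaks))
  labels <- EBImage::imageData(EBImage::propagate(smoothed, seeds, mask = binary))
  labels <- as_label_matrix(labels)
  area <- tabulate(labels[labels > 0L])
  diam <- 2 * sqrt(area / pi)
  drop_objects(labels, which(diam < params$nucleus_diameter_range[1] |
                               diam > params$nucleus_diameter_range[2]))
}
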