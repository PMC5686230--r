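## Colour de-convolution of chromogenic whole-slide images.
##
## Chromogen absorbances mix linearly in optical-density space (Beer-Lambert):
## OD_k = -log10(I_k / 255) = sum_s c_s * M[s, k], so per-pixel stain
## concentrations are recovered by inverting the 3 x 3 stain matrix M whose
## rows are the unit-norm OD colour vectors of the stains.

#' Stain matrix of unit optical-density colour vectors
#'
#' @param vectors 3 x 3 numeric matrix, one stain per row, columns (R, G, B).
#'   Rows are L2-normalized; the matrix must be non-singular.
#' @param names stain names (defaults to rownames or stain1..3).
#' @return An object of class `stain_matrix` (a 3 x 3 matrix).
#' @export
stain_matrix <- function(vectors, names = NULL) {
  m <- as.matrix(vectors)
  stopifnot(nrow(m) == 3L, ncol(m) == 3L, all(is.finite(m)))
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("stain vectors must be nonzero")
  m <- m / nrm
  if (abs(det(m)) < 1e-8) stop("stain matrix is singular")
  rownames(m) <- if (!is.null(names)) names
    else if (!is.null(rownames(vectors))) rownames(vectors)
    else paste0("stain", 1:3)
  colnames(m) <- c("R", "G", "B")
  class(m) <- c("stain_matrix", "matrix", "array")
  m
}

#' Default development stain matrix (haematoxylin / DAB / residual)
#'
#' Published haematoxylin and DAB optical-density vectors completed with a
#' third orthogonal residual vector. Real chromogen vectors (e.g. VinaGreen,
#' Liquid Permanent Red) are sample-dependent and must be supplied by the
#' user; this matrix is a development fixture.
#'
#' @return A [stain_matrix].
#' @export
default_stain_matrix <- function() {
  complete_stain_matrix(rbind(
    haematoxylin = c(0.650, 0.704, 0.286),
    dab          = c(0.268, 0.570, 0.776)))
}

#' Synthetic stand-in stain matrix for the three-chromogen panels
#'
#' Haematoxylin plus plausible synthetic colour vectors for a green chromogen
#' (absorbing red/blue) and a red chromogen (absorbing green/blue). These are
#' constructed stand-ins for the unpublished VinaGreen / Liquid Permanent Red
#' vectors, used by the synthetic-slide generator.
#'
#' @return A [stain_matrix] with rows haematoxylin, green, red.
#' @export
synthetic_stain_matrix <- function() {
  stain_matrix(rbind(
    haematoxylin = c(0.650, 0.704, 0.286),
    green        = c(0.620, 0.180, 0.764),
    red          = c(0.180, 0.880, 0.440)))
}

#' Convert an 8-bit RGB raster to optical density
#'
#' `OD_k = -log10(max(I_k, 1) / 255)` per channel; the clamp at intensity 1
#' keeps the OD finite for fully absorbed pixels.
#'
#' @param rgb numeric array `H x W x 3` on the 0--255 scale.
#' @return Numeric array `H x W x 3` of optical densities.
#' @export
rgb_to_od <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  -log10(pmax(rgb, 1) / 255)
}

#' Complete a two-stain matrix with an orthogonal third vector
#'
#' When only two chromogen vectors are specified, the third row is the
#' normalized cross product of the two, capturing any residual absorbance.
#'
#' @param two_vectors 2 x 3 matrix of linearly independent stain vectors.
#' @return A [stain_matrix].
#' @export
complete_stain_matrix <- function(two_vectors) {
  m <- as.matrix(two_vectors)
  stopifnot(nrow(m) == 2L, ncol(m) == 3L)
  m <- m / sqrt(rowSums(m^2))
  v1 <- m[1, ]; v2 <- m[2, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  n <- sqrt(sum(cr^2))
  if (n < 1e-8) stop("stain vectors are parallel; cannot complete the matrix")
  nm <- c(rownames(m), "residual")
  if (is.null(rownames(m))) nm <- c("stain1", "stain2", "residual")
  ## the raw (orthogonal) cross product: a two-stain mixture then deconvolves
  ## with zero third-channel concentration
  stain_matrix(rbind(m, cr / n), names = nm)
}

#' Separate an RGB brightfield raster into stain concentration maps
#'
#' Downscales the input by area averaging, converts to optical density, and
#' solves the Beer-Lambert mixing model per pixel: `c = OD %*% solve(M)`.
#' Negative concentrations (noise outside the stain simplex) are clipped to
#' zero; the clipped fraction is reported.
#'
#' @param rgb numeric array `H x W x 3` on the 0--255 scale.
#' @param matrix a [stain_matrix].
#' @param downscale integer area-averaging factor applied before conversion
#'   (default 4).
#' @return An object of class `concentration_maps`: list with `maps` (named
#'   list of rasters, one per stain), `downscale`, and `clip_fraction`.
#' @export
deconvolve <- function(rgb, matrix, downscale = 4L) {
  stopifnot(inherits(matrix, "stain_matrix"))
  downscale <- as.integer(downscale)
  stopifnot(downscale >= 1L)
  if (downscale > 1L) {
    rgb <- vapply(1:3, function(k) block_mean(rgb[, , k], downscale),
                  matrix(0, nrow(rgb) %/% downscale, ncol(rgb) %/% downscale))
  }
  d <- dim(rgb)
  od <- matrix(rgb_to_od(rgb), d[1] * d[2], 3L)
  conc <- od %*% solve(unclass(matrix))
  clip_fraction <- mean(conc < -1e-12)
  conc[conc < 0] <- 0
  maps <- lapply(1:3, function(s) matrix(conc[, s], d[1], d[2]))
  names(maps) <- rownames(matrix)
  structure(list(maps = maps, downscale = downscale,
                 clip_fraction = clip_fraction),
            class = "concentration_maps")
}

#' @export
print.concentration_maps <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf(
    "<concentration_maps> %d x %d px (1:%d downscale), stains: %s; %.3g%% clipped\n",
    d[1], d[2], x$downscale, paste(names(x$maps), collapse = ", "),
    100 * x$clip_fraction))
  invisible(x)
}

## area-average downscale by integer factor (trailing remainder rows/cols
## are dropped; origins are unchanged)
block_mean <- function(px, k) {
  k <- as.integer(k)
  if (k == 1L) return(px)
  nr <- nrow(px) %/% k; nc <- ncol(px) %/% k
  px <- px[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  ## average k x k blocks: fold rows, then columns
  m <- matrix(colMeans(matrix(px, nrow = k)), nr, nc * k)
  t(matrix(colMeans(matrix(t(m), nrow = k)), nc, nr))
}
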