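#' @import stats
#' @import utils
NULL

#' Single-channel 8-bit image with physical resolution
#'
#' The basic raster container of the package: a numeric matrix of intensities
#' on the 0--255 scale (stored as doubles, `pixels[row, col]`) together with
#' its physical resolution in micrometres per pixel and a channel name.
#'
#' Pixel coordinates are 0-based throughout the package and refer to pixel
#' centres: pixel index `i` (0-based) covers the physical interval
#' `[i * res, (i + 1) * res)` micrometres, its centre sitting at
#' `(i + 0.5) * res`.
#'
#' @param pixels numeric matrix, values in `[0, 255]`.
#' @param resolution physical resolution, micrometres per pixel (`> 0`).
#' @param channel_name character scalar naming the channel.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, resolution, channel_name = "channel") {
  pixels <- as_pixel_matrix(pixels)
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel_image: pixel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, resolution = as.numeric(resolution),
         channel_name = as.character(channel_name)),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> '%s': %d x %d px @ %.3g um/px, range [%g, %g]\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels), x$resolution,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Co-registered multi-channel slide
#'
#' A set of named single-channel rasters sharing one pixel grid and one
#' physical resolution, the working representation of a registered
#' multiplexed slide.
#'
#' @param channels named list of numeric matrices (equal dimensions) or of
#'   [channel_image] objects.
#' @param resolution shared resolution in micrometres per pixel.
#' @return An object of class `multiplex_slide`.
#' @export
multiplex_slide <- function(channels, resolution) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  channels <- lapply(channels, function(ch) {
    if (inherits(ch, "channel_image")) ch$pixels else as_pixel_matrix(ch)
  })
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("multiplex_slide: all channels must share one pixel grid")
  stopifnot(resolution > 0)
  structure(list(channels = channels, resolution = as.numeric(resolution)),
            class = "multiplex_slide")
}

#' @export
print.multiplex_slide <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multiplex_slide> %d x %d px @ %.3g um/px, %d channel(s): %s\n",
              d[1], d[2], x$resolution, length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.multiplex_slide <- function(x) dim(x$channels[[1]])

#' Extract one channel of a multiplex slide as a channel_image
#'
#' @param slide a [multiplex_slide].
#' @param name channel name.
#' @return A [channel_image].
#' @export
get_channel <- function(slide, name) {
  stopifnot(inherits(slide, "multiplex_slide"))
  if (!name %in% names(slide$channels))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(slide$channels), collapse = ", ")))
  channel_image(slide$channels[[name]], slide$resolution, name)
}

## ---- internal raster helpers ------------------------------------------------

as_pixel_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) {
    if (is.array(x) && length(dim(x)) == 2L) x <- as.matrix(x)
    else stop("expected a 2D raster")
  }
  ## integer and raw (1 byte/px whole-slide) storage is kept; anything else
  ## becomes double
  if (!is.double(x) && !is.integer(x) && !is.raw(x))
    storage.mode(x) <- "double"
  x
}

## 8-bit integer matrix <-> raw-byte matrix (quarter the memory)
int_to_raw8 <- function(m) {
  r <- as.raw(m)
  dim(r) <- dim(m)
  r
}

## clip to [0,255] and round to the 8-bit grid
quantize8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

## relabel an integer label raster so object ids are 1..N contiguous
relabel_mask <- function(labels) {
  labels <- as_label_matrix(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  labels
}

as_label_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stop("expected a 2D label raster")
  storage.mode(x) <- "integer"
  x
}

## drop labelled objects by id (vector of ids), then relabel contiguously
drop_objects <- function(labels, ids) {
  labels <- as_label_matrix(labels)
  if (length(ids)) labels[labels %in% as.integer(ids)] <- 0L
  relabel_mask(labels)
}

## histogram of an 8-bit raster: counts for levels 0..255
intensity_histogram <- function(pixels) {
  pixels <- as_pixel_matrix(pixels)
  tabulate(as.integer(quantize8(pixels)) + 1L, nbins = 256L)
}

## run code with a private RNG stream, restoring the caller's state
with_rng_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## pixel-centre coordinate conversions (0-based pixel indices)
px_to_um <- function(px, resolution) (px + 0.5) * resolution
um_to_px <- function(um, resolution) um / resolution - 0.5

## separable Gaussian blur with edge replication (spatial convolution; much
## faster than FFT filtering for the small sigmas used here)
gauss_blur <- function(x, sigma) {
  R <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(-R:R)^2 / (2 * sigma^2))
  w <- w / sum(w)
  nr <- nrow(x); nc <- ncol(x)
  pass <- function(m, n_along, byrow) {
    out <- 0
    for (k in -R:R) {
      idx <- pmin(pmax(seq_len(n_along) + k, 1L), n_along)
      out <- out + w[k + R + 1L] * (if (byrow) m[idx, , drop = FALSE]
                                    else m[, idx, drop = FALSE])
    }
    out
  }
  pass(pass(x, nr, TRUE), nc, FALSE)
}
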