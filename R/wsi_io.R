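## Tile--pad--stitch machinery and plain-file I/O.
##
## Whole-slide rasters are processed in square core tiles that partition the
## slide exactly (half-open pixel intervals, 0-based origins), each embedded in
## a larger centred context window so that objects crossing a core boundary are
## seen whole by at least one tile. Per-tile results are stitched back by
## keeping only objects whose centroid falls inside the owning tile's core.

#' Plan a tile grid over a slide
#'
#' Splits a slide of `slide_shape` pixels into core tiles of
#' `core_size x core_size` pixels (edge cores are clipped so the cores
#' partition the slide exactly, half-open), each with a centred context window
#' of `context_size x context_size` pixels. Context windows may extend beyond
#' the slide; [extract_tile()] zero-fills those positions.
#'
#' @param slide_shape integer `(rows, cols)` of the slide in pixels.
#' @param core_size side of the core tile in pixels (default 2048).
#' @param context_size side of the padded context window in pixels
#'   (default 10240).
#' @return A data.frame of class `tile_plan`, one row per tile, with 0-based
#'   origins: `tile_id`, `core_row0`, `core_col0`, `core_h`, `core_w`,
#'   `ctx_row0`, `ctx_col0`, `ctx_size`.
#' @export
plan_tiles <- function(slide_shape, core_size = 2048L, context_size = 10240L) {
  stopifnot(length(slide_shape) == 2L, all(slide_shape >= 1))
  core_size <- as.integer(core_size)
  context_size <- as.integer(context_size)
  if (core_size <= 0L) stop("core_size must be positive")
  if (context_size < core_size) stop("context_size must be >= core_size")
  rows <- as.integer(slide_shape[1]); cols <- as.integer(slide_shape[2])
  r0 <- seq.int(0L, rows - 1L, by = core_size)
  c0 <- seq.int(0L, cols - 1L, by = core_size)
  grid <- expand.grid(core_row0 = r0, core_col0 = c0, KEEP.OUT.ATTRS = FALSE)
  grid$core_h <- pmin(core_size, rows - grid$core_row0)
  grid$core_w <- pmin(core_size, cols - grid$core_col0)
  grid$ctx_row0 <- grid$core_row0 + (grid$core_h - context_size) %/% 2L
  grid$ctx_col0 <- grid$core_col0 + (grid$core_w - context_size) %/% 2L
  grid$ctx_size <- context_size
  out <- cbind(data.frame(tile_id = seq_len(nrow(grid))), grid)
  attr(out, "slide_shape") <- c(rows, cols)
  attr(out, "core_size") <- core_size
  attr(out, "context_size") <- context_size
  class(out) <- c("tile_plan", "data.frame")
  out
}

#' Extract the padded context window of one tile
#'
#' Copies the pixels of `tile`'s context window out of the slide; positions of
#' the context window that fall outside the slide are zero-filled. Core pixels
#' are always real slide data.
#'
#' @param image a [channel_image] or a numeric matrix.
#' @param tile one row of a [plan_tiles()] tile plan.
#' @return A `ctx_size x ctx_size` numeric matrix.
#' @export
extract_tile <- function(image, tile) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_pixel_matrix(image)
  n <- tile$ctx_size
  out <- if (is.double(px)) matrix(0, n, n) else matrix(0L, n, n)
  ## overlap of context window [ctx0, ctx0+n) with slide [0, dim)
  r_lo <- max(0L, tile$ctx_row0); r_hi <- min(nrow(px), tile$ctx_row0 + n)
  c_lo <- max(0L, tile$ctx_col0); c_hi <- min(ncol(px), tile$ctx_col0 + n)
  if (r_hi <= r_lo || c_hi <= c_lo) {
    if (tile$core_h > 0 && tile$core_w > 0)
      stop("tile inconsistent with image shape")
    return(out)
  }
  sub <- px[(r_lo + 1L):r_hi, (c_lo + 1L):c_hi]
  if (is.raw(sub)) sub <- matrix(as.integer(sub), nrow(sub), ncol(sub))
  out[(r_lo - tile$ctx_row0 + 1L):(r_hi - tile$ctx_row0),
      (c_lo - tile$ctx_col0 + 1L):(c_hi - tile$ctx_col0)] <- sub
  out
}

#' Stitch per-tile cell records into a whole-slide table
#'
#' Keeps a record if and only if its centroid, converted to global
#' coordinates, lies inside the owning tile's half-open core region, so that
#' every physical cell -- including one sitting exactly on a shared core
#' boundary -- appears exactly once.
#'
#' @param per_tile_cells list of data.frames, one per tile (same order as
#'   `tiles`), each with 0-based context-local centroid columns
#'   `local_row_px`, `local_col_px`.
#' @param tiles a [plan_tiles()] tile plan.
#' @return One data.frame with global `row_px`, `col_px` columns (0-based
#'   pixel-centre coordinates) in place of the local ones, `cell_id`
#'   renumbered 1..N.
#' @export
stitch_cells <- function(per_tile_cells, tiles) {
  stopifnot(inherits(tiles, "tile_plan"))
  if (length(per_tile_cells) != nrow(tiles))
    stop("per_tile_cells must have one element per tile")
  kept <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    cells <- per_tile_cells[[i]]
    if (is.null(cells) || nrow(cells) == 0L) next
    if (!all(c("local_row_px", "local_col_px") %in% names(cells)))
      stop("per-tile records must carry local_row_px/local_col_px")
    tl <- tiles[i, ]
    row_px <- tl$ctx_row0 + cells$local_row_px
    col_px <- tl$ctx_col0 + cells$local_col_px
    in_core <- row_px >= tl$core_row0 & row_px < tl$core_row0 + tl$core_h &
      col_px >= tl$core_col0 & col_px < tl$core_col0 + tl$core_w
    if (!any(in_core)) next
    cells <- cells[in_core, , drop = FALSE]
    cells$row_px <- row_px[in_core]
    cells$col_px <- col_px[in_core]
    cells$tile_id <- tl$tile_id
    cells$local_row_px <- NULL
    cells$local_col_px <- NULL
    kept[[i]] <- cells
  }
  kept <- kept[!vapply(kept, is.null, logical(1))]
  if (!length(kept)) {
    return(data.frame(cell_id = integer(), row_px = numeric(),
                      col_px = numeric(), tile_id = integer()))
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out$cell_id <- seq_len(nrow(out))
  out
}

#' Stitch per-tile label masks into a whole-slide mosaic
#'
#' Copies each tile's core region out of its context-sized label mask into the
#' slide mosaic and relabels objects so ids are unique (and contiguous) across
#' the mosaic.
#'
#' @param per_tile_label_masks list of integer label matrices of context size,
#'   one per tile.
#' @param tiles a [plan_tiles()] tile plan.
#' @return Whole-slide integer label matrix.
#' @export
stitch_labels <- function(per_tile_label_masks, tiles) {
  stopifnot(inherits(tiles, "tile_plan"))
  if (length(per_tile_label_masks) != nrow(tiles))
    stop("per_tile_label_masks must have one element per tile")
  shape <- attr(tiles, "slide_shape")
  mosaic <- matrix(0L, shape[1], shape[2])
  next_id <- 0L
  for (i in seq_len(nrow(tiles))) {
    tl <- tiles[i, ]
    m <- as_label_matrix(per_tile_label_masks[[i]])
    if (nrow(m) != tl$ctx_size || ncol(m) != tl$ctx_size)
      stop("label mask shape does not match the tile's context size")
    r_off <- tl$core_row0 - tl$ctx_row0
    c_off <- tl$core_col0 - tl$ctx_col0
    core <- m[(r_off + 1L):(r_off + tl$core_h),
              (c_off + 1L):(c_off + tl$core_w), drop = FALSE]
    core <- relabel_mask(core)
    n_obj <- max(core, 0L)
    core[core > 0L] <- core[core > 0L] + next_id
    next_id <- next_id + n_obj
    mosaic[(tl$core_row0 + 1L):(tl$core_row0 + tl$core_h),
           (tl$core_col0 + 1L):(tl$core_col0 + tl$core_w)] <- core
  }
  mosaic
}

## ---- file formats -----------------------------------------------------------

#' Read and write single-plane 8-bit TIFF channels
#'
#' @param path file path.
#' @param resolution micrometres per pixel to attach on read.
#' @param channel_name channel name to attach on read.
#' @return `read_channel_tiff` returns a [channel_image];
#'   `write_channel_tiff` returns `path` invisibly.
#' @export
read_channel_tiff <- function(path, resolution, channel_name = NULL) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (is.null(channel_name))
    channel_name <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  channel_image(round(px * 255), resolution, channel_name)
}

#' @param image a [channel_image] (or numeric matrix on the 0--255 scale).
#' @rdname read_channel_tiff
#' @export
write_channel_tiff <- function(image, path) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_pixel_matrix(image)
  if (!is.integer(px)) px <- quantize8(px)
  tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write an RGB raster (0--255 array, H x W x 3) as 8-bit TIFF
#' @param rgb numeric array `H x W x 3` on the 0--255 scale.
#' @param path file path.
#' @export
write_rgb_tiff <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  arr <- rgb
  arr[] <- quantize8(arr)
  tiff::writeTIFF(arr / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_rgb_tiff
#' @export
read_rgb_tiff <- function(path) {
  arr <- tiff::readTIFF(path)
  stopifnot(length(dim(arr)) == 3L)
  out <- array(0L, c(dim(arr)[1:2], 3L))
  for (k in 1:3)                      # channel-wise keeps temporaries small
    out[, , k] <- as.integer(round(arr[, , k] * 255))
  out
}

#' Read and write 16-bit label-mask TIFFs
#'
#' Object masks are stored as 16-bit grayscale TIFF, pixel value = object id
#' (0 = background, up to 65535 objects per mask).
#'
#' @param labels integer label matrix.
#' @param path file path.
#' @export
write_label_tiff <- function(labels, path) {
  labels <- as_label_matrix(labels)
  if (max(labels) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  as_label_matrix(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

## fixed, documented column order of the cell table
cell_table_columns <- function(markers) {
  c("cell_id", "centroid_x_um", "centroid_y_um", "mean_radius_px", "gland_id",
    "compartment", "class",
    as.vector(rbind(paste0(markers, "_raw"), paste0(markers, "_norm"),
                    paste0(markers, "_positive"))))
}

#' Write a cell table as CSV with the package's fixed column order
#'
#' Leading columns `cell_id, centroid_x_um, centroid_y_um, mean_radius_px,
#' gland_id, compartment, class` are followed by `<marker>_raw`,
#' `<marker>_norm`, `<marker>_positive` triples; any remaining columns keep
#' their order at the end.
#'
#' @param cells cell-record data.frame.
#' @param path file path.
#' @export
write_cell_table <- function(cells, path) {
  markers <- unique(sub("_raw$", "", grep("_raw$", names(cells), value = TRUE)))
  lead <- intersect(cell_table_columns(markers), names(cells))
  rest <- setdiff(names(cells), lead)
  utils::write.csv(cells[, c(lead, rest), drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML run configuration
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
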