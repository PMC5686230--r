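## End-to-end orchestration: colour de-convolution -> registration -> tiling
## -> segmentation -> per-cell quantification -> stitching -> global
## positivity calling and classification -> summary tables, with a run
## manifest recording every effective parameter, seed, timing and object
## count so each filtering step is auditable.

#' Pipeline run configuration
#'
#' @param out_res output (registered) grid resolution, um/px (default 0.64).
#' @param ref_work_res,mov_work_res registration working resolutions, um/px
#'   (defaults 1.76 haematoxylin / 2.56 nuclear).
#' @param core_size,context_size tile core and padded context sizes, px.
#' @param deconv_downscale area-averaging factor of the colour
#'   de-convolution (default 4).
#' @param segmentation a [segmentation_params()]; its `gland_threshold_mode`
#'   is overridden per scheme (immune: global, epithelial: adaptive) unless
#'   `gland_mode` is set.
#' @param gland_mode `NULL` (scheme default) or `"global"` / `"adaptive"`.
#' @param ransac_seed seed of the robust registration estimator.
#' @param match_radius_um validation matching radius, micrometres.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_res = 0.64, ref_work_res = 1.76,
                       mov_work_res = 2.56, core_size = 2048L,
                       context_size = 10240L, deconv_downscale = 4L,
                       segmentation = segmentation_params(),
                       gland_mode = NULL, ransac_seed = 0L,
                       match_radius_um = 8) {
  structure(list(out_res = out_res, ref_work_res = ref_work_res,
                 mov_work_res = mov_work_res,
                 core_size = as.integer(core_size),
                 context_size = as.integer(context_size),
                 deconv_downscale = as.integer(deconv_downscale),
                 segmentation = segmentation, gland_mode = gland_mode,
                 ransac_seed = as.integer(ransac_seed),
                 match_radius_um = match_radius_um),
            class = "run_config")
}

## centroids and areas of labelled objects
label_centroids <- function(labels) {
  labels <- as_label_matrix(labels)
  idx <- which(labels > 0L)
  if (!length(idx))
    return(data.frame(id = integer(), row_px = numeric(), col_px = numeric(),
                      area_px = integer()))
  lab <- labels[idx]
  n <- max(lab)
  area <- tabulate(lab, nbins = n)
  nr <- nrow(labels)
  data.frame(id = seq_len(n),
             row_px = as.vector(rowsum((idx - 1L) %% nr, lab)) / area,
             col_px = as.vector(rowsum((idx - 1L) %/% nr, lab)) / area,
             area_px = area)
}

#' Run the full whole-slide analysis for one panel
#'
#' Stages, in fixed order: (1) colour de-convolution of the brightfield
#' image; (2) registration of the fluorescence nuclear channel onto the
#' brightfield haematoxylin reference; (3) resampling of all channels onto
#' the common output grid; (4) tiled gland/nucleus segmentation, marker
#' masking and per-cell measurement (gland malignancy is decided per tile
#' from the full padded context, so glands crossing core boundaries are seen
#' whole); (5) stitching by the half-open core rule; (6) global SD-based
#' positivity calling and cell classification; (7) summary tables.
#' Deterministic given the configuration.
#'
#' @param fl a [multiplex_slide] of fluorescence channels (must contain
#'   `nuclei` plus the panel's fluorescence markers), or a named character
#'   vector of single-channel TIFF paths (names = channel names), in which
#'   case `fl_resolution` must be given and channels are read one at a time
#'   (memory-bounded whole-slide operation).
#' @param bf RGB brightfield array (0--255) or the path of an RGB TIFF.
#' @param bf_resolution brightfield resolution, um/px.
#' @param fl_resolution fluorescence resolution, um/px (only needed when
#'   `fl` is a vector of paths).
#' @param stain_matrix [stain_matrix] of the brightfield chromogens
#'   (haematoxylin first).
#' @param panel a [panel_config()].
#' @param config a [run_config()].
#' @param chromogen_markers named map of chromogen stain (matrix row name,
#'   e.g. `green`, `red`) to marker name; default immune
#'   `c(green = "PanEpi", red = "Ki67")`, epithelial
#'   `c(green = "AR", red = "AMACR")`.
#' @param output_dir optional directory: writes `cells.csv`, `glands.csv`,
#'   summary CSVs, `transform.json` and `manifest.json`.
#' @return An object of class `wsi_run`: list with `cells`, `glands`,
#'   `summary`, `transform`, `registration`, `tiles`, `manifest`.
#' @export
run_panel <- function(fl, bf, bf_resolution, stain_matrix, panel,
                      config = run_config(), chromogen_markers = NULL,
                      fl_resolution = NULL, output_dir = NULL) {
  stopifnot(inherits(panel, "panel_config"))
  from_files <- is.character(fl)
  if (from_files) {
    if (is.null(fl_resolution))
      stop("fl_resolution is required when fl channels are given as paths")
    fl_names <- names(fl)
    fl_res <- fl_resolution
    load_channel <- function(m) {
      px <- quantize8(tiff::readTIFF(fl[[m]]) * 255)
      storage.mode(px) <- "integer"
      px
    }
  } else {
    stopifnot(inherits(fl, "multiplex_slide"))
    fl_names <- names(fl$channels)
    fl_res <- fl$resolution
    load_channel <- function(m) fl$channels[[m]]
  }
  if (is.character(bf)) bf <- read_rgb_tiff(bf)
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function() proc.time()[["elapsed"]]
  if (is.null(chromogen_markers))
    chromogen_markers <- if (panel$scheme == "immune")
      c(green = "PanEpi", red = "Ki67") else c(green = "AR", red = "AMACR")
  fl_markers <- setdiff(panel$required, c(chromogen_markers))
  missing <- setdiff(fl_markers, fl_names)
  if (length(missing))
    stop(sprintf("missing fluorescence channel(s): %s",
                 paste(missing, collapse = ", ")))
  if (!all(names(chromogen_markers) %in% rownames(stain_matrix)))
    stop("chromogen_markers must name rows of the stain matrix")

  ## stage 1: colour de-convolution ------------------------------------------
  t0 <- tick()
  conc <- deconvolve(bf, stain_matrix, downscale = config$deconv_downscale)
  conc_res <- bf_resolution * config$deconv_downscale
  haem <- channel_image(pmin(255 * conc$maps[[1]], 255), conc_res,
                        rownames(stain_matrix)[1])
  timings["deconvolution_s"] <- tick() - t0

  ## stage 2: registration ----------------------------------------------------
  t0 <- tick()
  reg <- register_modalities(haem, channel_image(load_channel("nuclei"),
                                                 fl_res, "nuclei"),
                             ref_work_res = config$ref_work_res,
                             mov_work_res = config$mov_work_res,
                             out_res = config$out_res,
                             resample_reference = FALSE,
                             seed = config$ransac_seed)
  out_dim <- reg$out_dim
  timings["registration_s"] <- tick() - t0

  ## stage 3: common grid -----------------------------------------------------
  t0 <- tick()
  ## registered channels live as raw bytes (1 byte/px) until tiles need them
  slide_channels <- list()
  slide_channels[["nuclei"]] <- int_to_raw8(noise_quantize_int(reg$moving$pixels, 0))
  reg$moving <- NULL
  reg$reference <- NULL
  gc(FALSE)
  for (m in setdiff(fl_markers, "nuclei")) {
    src <- load_channel(m)
    slide_channels[[m]] <- int_to_raw8(warp_affine(src, reg$transform, out_dim,
                                                   out_mode = "int8"))
    rm(src); gc(FALSE)
  }
  for (s in names(chromogen_markers)) {
    ch <- pmin(255 * conc$maps[[s]], 255)
    ## bilinear upsampling onto the output grid (zero-filled beyond)
    slide_channels[[chromogen_markers[[s]]]] <-
      int_to_raw8(warp_affine(ch, scale_transform(conc_res, config$out_res),
                              out_dim, out_mode = "int8"))
    rm(ch)
  }
  registered <- multiplex_slide(slide_channels, config$out_res)
  rm(slide_channels); gc(FALSE)
  timings["resampling_s"] <- tick() - t0

  ## stage 4+5: tiled segmentation, measurement, stitching --------------------
  t0 <- tick()
  seg <- config$segmentation
  seg$gland_threshold_mode <- if (!is.null(config$gland_mode)) config$gland_mode
    else if (panel$scheme == "immune") "global" else "adaptive"
  mask_marker <- if (panel$scheme == "immune") "CD45" else "CK5p63"
  overlap_col <- if (panel$scheme == "immune") "cd45_overlap" else "basal_overlap"
  tiles <- plan_tiles(out_dim, config$core_size, config$context_size)
  per_tile_cells <- vector("list", nrow(tiles))
  per_tile_glands <- vector("list", nrow(tiles))
  counts <- list(nuclei_segmented = 0L, glands_segmented = 0L)
  for (i in seq_len(nrow(tiles))) {
    tl <- tiles[i, ]
    ## channels are extracted one at a time to bound the working set
    ext <- extract_tile(registered$channels$nuclei, tl)
    nu_lab <- segment_nuclei(ext, seg)
    cells <- measure_cells(nu_lab, list(nuclei = ext),
                           resolution = config$out_res)
    idx <- which(nu_lab > 0L)
    lab_px <- nu_lab[idx]
    n_obj <- max(nu_lab, 0L)
    area <- if (n_obj) tabulate(lab_px, nbins = n_obj) else integer()
    rm(ext)
    ext <- extract_tile(registered$channels$PanEpi, tl)
    gl_lab <- segment_glands(ext, seg)
    cells$PanEpi_raw <- if (n_obj)
      as.vector(rowsum(as.numeric(ext[idx]), lab_px)) / area else numeric()
    cells$PanEpi_norm <- cells$PanEpi_raw / 255
    rm(ext); gc(FALSE)
    cells <- assign_compartment(cells, gl_lab)
    for (m in setdiff(panel$required, c("nuclei", "PanEpi"))) {
      ext <- extract_tile(registered$channels[[m]], tl)
      if (m == mask_marker) {
        mask <- marker_mask(ext)
        cells[[overlap_col]] <- mask_overlap(nu_lab, mask)
        rm(mask)
      }
      cells[[paste0(m, "_raw")]] <- if (n_obj)
        as.vector(rowsum(as.numeric(ext[idx]), lab_px)) / area else numeric()
      cells[[paste0(m, "_norm")]] <- cells[[paste0(m, "_raw")]] / 255
      rm(ext)
    }
    counts$nuclei_segmented <- counts$nuclei_segmented + n_obj
    counts$glands_segmented <- counts$glands_segmented + max(gl_lab, 0L)
    gl_info <- label_centroids(gl_lab)
    rm(nu_lab, gl_lab, idx, lab_px); gc(FALSE)
    if (panel$scheme == "epithelial") {
      cl <- classify_glands_and_epithelial(cells, panel,
                                           gland_areas = gl_info$area_px)
      cells <- cl$cells
      gl_info <- merge(gl_info, cl$glands, by.x = "id", by.y = "gland_id",
                       all.x = TRUE)
      gl_info$n_cells[is.na(gl_info$n_cells)] <- 0L
      gl_info$n_basal_cells[is.na(gl_info$n_basal_cells)] <- 0L
      gl_info$malignant[is.na(gl_info$malignant)] <- TRUE
    } else {
      gl_info$malignant <- NA
    }
    names(cells)[names(cells) == "row_px"] <- "local_row_px"
    names(cells)[names(cells) == "col_px"] <- "local_col_px"
    per_tile_cells[[i]] <- cells
    names(gl_info)[names(gl_info) == "row_px"] <- "local_row_px"
    names(gl_info)[names(gl_info) == "col_px"] <- "local_col_px"
    per_tile_glands[[i]] <- gl_info
  }
  cells <- stitch_cells(per_tile_cells, tiles)
  glands <- stitch_cells(per_tile_glands, tiles)
  if (nrow(glands)) {
    glands$gland_id <- glands$cell_id
    glands$cell_id <- NULL
    glands$centroid_x_um <- px_to_um(glands$col_px, config$out_res)
    glands$centroid_y_um <- px_to_um(glands$row_px, config$out_res)
  }
  if (nrow(cells)) {
    cells$centroid_x_um <- px_to_um(cells$col_px, config$out_res)
    cells$centroid_y_um <- px_to_um(cells$row_px, config$out_res)
  }
  timings["tiles_s"] <- tick() - t0

  ## stage 6: global positivity and classification ----------------------------
  t0 <- tick()
  if (nrow(cells)) {
    cells <- call_positivity(cells, panel,
                             markers = setdiff(panel$required, "nuclei"))
    if (panel$scheme == "immune") cells <- classify_immune(cells, panel)
  }
  summary <- summarize_panel(cells, panel$scheme)
  timings["classification_s"] <- tick() - t0

  manifest <- list(
    package = "wsicyto",
    version = as.character(utils::packageVersion("wsicyto")),
    scheme = panel$scheme,
    parameters = list(
      out_res = config$out_res, ref_work_res = config$ref_work_res,
      mov_work_res = config$mov_work_res, core_size = config$core_size,
      context_size = config$context_size,
      deconv_downscale = config$deconv_downscale,
      gland_threshold_mode = seg$gland_threshold_mode,
      nucleus_diameter_range = seg$nucleus_diameter_range,
      adaptive_window = seg$adaptive_window,
      gland_min_area = seg$gland_min_area,
      smoothing_sigma = seg$smoothing_sigma,
      gland_close_radius = seg$gland_close_radius,
      gland_watershed_tol = seg$gland_watershed_tol,
      sd_multiplier = as.list(panel$sd_multiplier),
      basal_overlap_min = panel$basal_overlap_min,
      ransac_seed = config$ransac_seed),
    registration = reg$diagnostics,
    deconvolution_clip_fraction = conc$clip_fraction,
    counts = c(counts, list(n_tiles = nrow(tiles),
                            cells_stitched = nrow(cells),
                            glands_stitched = nrow(glands))),
    positivity_thresholds = as.list(attr(cells, "positivity_thresholds")),
    timings_s = as.list(c(timings, total_s = tick() - t_all)))

  run <- structure(list(cells = cells, glands = glands, summary = summary,
                        transform = reg$transform,
                        registration = reg$diagnostics,
                        tiles = tiles, manifest = manifest,
                        out_dim = out_dim, config = config, panel = panel),
                   class = "wsi_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.wsi_run <- function(x, ...) {
  cat(sprintf("<wsi_run> %s scheme: %d cells, %d glands, %d tiles (grid %d x %d)\n",
              x$panel$scheme, nrow(x$cells), nrow(x$glands), nrow(x$tiles),
              x$out_dim[1], x$out_dim[2]))
  print(x$summary)
  invisible(x)
}

#' Write the outputs of a pipeline run
#'
#' @param run a `wsi_run`.
#' @param dir output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(run$cells, file.path(dir, "cells.csv"))
  utils::write.csv(run$glands, file.path(dir, "glands.csv"), row.names = FALSE)
  utils::write.csv(run$summary$class_distribution,
                   file.path(dir, "summary_classes.csv"), row.names = FALSE)
  if (!is.null(run$summary$t_classes))
    utils::write.csv(run$summary$t_classes,
                     file.path(dir, "summary_t_classes.csv"), row.names = FALSE)
  if (!is.null(run$summary$marker_means))
    utils::write.csv(run$summary$marker_means,
                     file.path(dir, "summary_marker_means.csv"),
                     row.names = FALSE)
  write_transform_json(run$transform, file.path(dir, "transform.json"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Validate detected cells against synthetic ground truth
#'
#' Greedy one-to-one nearest-centroid matching within `match_radius_um`
#' (candidate pairs sorted by distance; ties broken by ids, so the matching
#' is invariant to input order). Unmatched truth cells are misses, unmatched
#' detections false positives.
#'
#' @param cells detected cell table with `centroid_x_um`, `centroid_y_um`
#'   and (optionally) `class`.
#' @param truth a `ground_truth_slide` (or its `cells` data.frame with
#'   `row_um`, `col_um`, `class`).
#' @param match_radius_um matching radius, micrometres.
#' @return List with `recall`, `precision`, `n_matched`, `class_agreement`
#'   (fraction of matched pairs with equal class), `confusion` (truth x
#'   detected class table), `proportion_error` (max absolute difference
#'   of class percentages, detected vs truth), and `matches` (data.frame of
#'   matched `truth_idx` / `detected_idx` row indices).
#' @export
validate_against_truth <- function(cells, truth, match_radius_um = 8) {
  tc <- if (inherits(truth, "ground_truth_slide")) truth$cells else truth
  n_t <- nrow(tc); n_d <- nrow(cells)
  if (n_t == 0L || n_d == 0L) {
    return(list(recall = 0, precision = 0, n_matched = 0L,
                class_agreement = NA_real_, confusion = table(NULL),
                proportion_error = NA_real_,
                matches = data.frame(truth_idx = integer(),
                                     detected_idx = integer())))
  }
  ty <- tc$row_um; tx <- tc$col_um
  dy <- cells$centroid_y_um; dx <- cells$centroid_x_um
  r <- match_radius_um
  ## bucket truth cells on a grid of cell size r
  bkey <- function(y, x) paste(floor(y / r), floor(x / r))
  buckets <- split(seq_len(n_t), bkey(ty, tx))
  cand_d <- integer(); cand_t <- integer(); cand_dist <- numeric()
  for (i in seq_len(n_d)) {
    by <- floor(dy[i] / r); bx <- floor(dx[i] / r)
    for (oy in -1:1) for (ox in -1:1) {
      js <- buckets[[paste(by + oy, bx + ox)]]
      if (is.null(js)) next
      dist <- sqrt((ty[js] - dy[i])^2 + (tx[js] - dx[i])^2)
      sel <- dist <= r
      if (any(sel)) {
        cand_d <- c(cand_d, rep(i, sum(sel)))
        cand_t <- c(cand_t, js[sel])
        cand_dist <- c(cand_dist, dist[sel])
      }
    }
  }
  o <- order(cand_dist, cand_t, cand_d)
  used_t <- logical(n_t); used_d <- logical(n_d)
  match_t <- integer(); match_d <- integer()
  for (k in o) {
    if (used_t[cand_t[k]] || used_d[cand_d[k]]) next
    used_t[cand_t[k]] <- TRUE; used_d[cand_d[k]] <- TRUE
    match_t <- c(match_t, cand_t[k]); match_d <- c(match_d, cand_d[k])
  }
  nm <- length(match_t)
  agree <- NA_real_; confusion <- table(NULL); prop_err <- NA_real_
  if (!is.null(cells$class) && !is.null(tc$class)) {
    lv <- sort(unique(c(tc$class, cells$class)))
    if (nm > 0) {
      confusion <- table(truth = factor(tc$class[match_t], lv),
                         detected = factor(cells$class[match_d], lv))
      agree <- mean(tc$class[match_t] == cells$class[match_d])
    }
    pt <- 100 * table(factor(tc$class, lv)) / n_t
    pd <- 100 * table(factor(cells$class, lv)) / n_d
    prop_err <- max(abs(pt - pd))
  }
  list(recall = nm / n_t, precision = nm / n_d, n_matched = nm,
       class_agreement = agree, confusion = confusion,
       proportion_error = prop_err,
       matches = data.frame(truth_idx = match_t, detected_idx = match_d))
}

#' Validate detected glands against synthetic ground truth
#'
#' Matches detected gland centroids to planted gland centres (greedy
#' one-to-one within `match_radius_um`) and scores the malignancy call.
#'
#' @param glands stitched gland table of a `wsi_run` (epithelial scheme).
#' @param truth a `ground_truth_slide`.
#' @param match_radius_um matching radius (default 60 um).
#' @return List with `recall`, `precision`, `n_matched`,
#'   `malignancy_accuracy`, and `matches` (data.frame with the truth
#'   `gland_id`, the detected gland's `gland_id`, and the two malignancy
#'   calls).
#' @export
validate_glands_against_truth <- function(glands, truth,
                                          match_radius_um = 60) {
  tg <- truth$glands
  det <- data.frame(centroid_y_um = glands$centroid_y_um,
                    centroid_x_um = glands$centroid_x_um,
                    class = as.character(glands$malignant))
  tru <- data.frame(row_um = tg$row_um, col_um = tg$col_um,
                    class = as.character(tg$malignant))
  v <- validate_against_truth(det, tru, match_radius_um)
  matches <- data.frame(
    truth_gland_id = tg$gland_id[v$matches$truth_idx],
    detected_gland_id = glands$gland_id[v$matches$detected_idx],
    truth_malignant = tg$malignant[v$matches$truth_idx],
    detected_malignant = glands$malignant[v$matches$detected_idx])
  list(recall = v$recall, precision = v$precision, n_matched = v$n_matched,
       malignancy_accuracy = v$class_agreement, matches = matches)
}

## class colour palette of the overlay visualization
class_palette <- function(scheme) {
  if (scheme == "immune") {
    c("epi-Treg" = "#e41a1c", "epi-Th" = "#ff7f00", "epi-Te" = "#ffff33",
      "epi-leukocyte-other" = "#f781bf", "stromal-Treg" = "#a65628",
      "stromal-Th" = "#984ea3", "stromal-Te" = "#66c2a5",
      "stromal-leukocyte-other" = "#fb9a99", "epithelial" = "#4daf4a",
      "other" = "#377eb8")
  } else {
    c(cancer = "#e41a1c", "benign-luminal" = "#4daf4a", basal = "#377eb8",
      stromal = "#999999")
  }
}

#' Write a class-overlay visualization of a classified cell table
#'
#' Paints one coloured disc per cell (colour = class) on a black canvas at a
#' downscaled slide resolution and writes it as an RGB TIFF.
#'
#' @param cells classified cell table with `row_px`, `col_px`, `class`.
#' @param slide_shape full-resolution slide shape `(rows, cols)` px.
#' @param path output TIFF path.
#' @param scheme `"immune"` or `"epithelial"`.
#' @param downscale rendering downscale factor (default 8).
#' @param radius disc radius at the downscaled grid, px.
#' @export
write_class_overlay <- function(cells, slide_shape, path, scheme,
                                downscale = 8L, radius = 3L) {
  pal <- class_palette(scheme)
  d <- pmax(1L, as.integer(slide_shape) %/% as.integer(downscale))
  img <- array(0, c(d[1], d[2], 3L))
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  for (i in seq_len(nrow(cells))) {
    col <- pal[[cells$class[i]]]
    if (is.null(col)) next
    rgbv <- as.vector(grDevices::col2rgb(col)) / 255
    r0 <- round(cells$row_px[i] / downscale) + 1L
    c0 <- round(cells$col_px[i] / downscale) + 1L
    rr <- r0 + off$dr; cc <- c0 + off$dc
    keep <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
    for (k in 1:3) img[cbind(rr[keep], cc[keep], k)] <- rgbv[k]
  }
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  invisible(path)
}
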