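## Per-cell marker quantification and rule-based classification.
##
## Marker intensity is the mean 8-bit intensity over the nucleus object's
## pixels, normalized to 0-1 by dividing by 255 (a global scale, so absolute
## expression levels remain comparable across classes). A cell is positive
## for a marker when its normalized intensity is strictly above
## mean + k * SD over all cells (population SD; k = 1, except Ki67 at k = 3).
## Compartment (epithelial vs. stromal) follows centroid containment in the
## hole-filled gland mask. Mask-derived calls (CD45, CK5+p63 basal status)
## use nucleus area overlap with the marker mask (minimum 10%).

immune_class_levels <- c("epi-Treg", "epi-Th", "epi-Te", "epi-leukocyte-other",
                         "stromal-Treg", "stromal-Th", "stromal-Te",
                         "stromal-leukocyte-other", "epithelial", "other")
epithelial_class_levels <- c("cancer", "benign-luminal", "basal", "stromal")

#' Panel configuration
#'
#' @param scheme `"immune"` or `"epithelial"` classification scheme.
#' @param channels named character vector mapping required marker names to
#'   channel names of the registered slide (defaults to identity).
#' @param sd_multiplier named numeric vector of positivity SD multipliers;
#'   unlisted markers use 1. Ki67 defaults to 3 (rare positives).
#' @param basal_overlap_min minimum nucleus-area overlap fraction with a
#'   marker mask for mask-derived calls (CD45 / CK5+p63), default 0.10.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(scheme = c("immune", "epithelial"),
                         channels = NULL,
                         sd_multiplier = NULL,
                         basal_overlap_min = 0.10) {
  scheme <- match.arg(scheme)
  required <- switch(scheme,
                     immune = c("nuclei", "CD45", "CD4", "CD8", "FoxP3",
                                "Ki67", "PanEpi"),
                     epithelial = c("nuclei", "PanEpi", "CK5p63", "AMACR",
                                    "AR", "CK8", "CK18"))
  if (is.null(channels)) channels <- stats::setNames(required, required)
  missing <- setdiff(required, names(channels))
  if (length(missing))
    stop(sprintf("panel '%s' requires marker channels: %s", scheme,
                 paste(missing, collapse = ", ")))
  k <- stats::setNames(rep(1, length(required)), required)
  k["Ki67"] <- 3
  if (!is.null(sd_multiplier)) k[names(sd_multiplier)] <- sd_multiplier
  structure(list(scheme = scheme, channels = channels,
                 required = required, sd_multiplier = k,
                 basal_overlap_min = basal_overlap_min),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> %s scheme; markers: %s\n", x$scheme,
              paste(x$required, collapse = ", ")))
  invisible(x)
}

#' Measure per-cell marker intensities and geometry
#'
#' For every labelled nucleus: mean 8-bit intensity per channel over the
#' object's pixels (raw) and its 0-1 normalization (raw/255), the
#' equivalent-circle mean radius `sqrt(area/pi)`, the centroid (0-based pixel
#' and micrometre coordinates), and the id of the containing gland (0 =
#' stroma), from which the compartment follows.
#'
#' @param nuclei integer nucleus label mask.
#' @param channels a [multiplex_slide] (or named list of matrices).
#' @param glands optional integer gland label mask (hole-filled), same grid.
#' @param resolution micrometres per pixel (taken from `channels` if a
#'   [multiplex_slide]).
#' @return data.frame with one row per cell: `cell_id`, `row_px`, `col_px`,
#'   `centroid_x_um`, `centroid_y_um`, `area_px`, `mean_radius_px`,
#'   `gland_id`, `compartment`, and `<marker>_raw` / `<marker>_norm` pairs.
#' @export
measure_cells <- function(nuclei, channels, glands = NULL, resolution = NULL) {
  if (inherits(channels, "multiplex_slide")) {
    if (is.null(resolution)) resolution <- channels$resolution
    channels <- channels$channels
  }
  if (is.null(resolution)) resolution <- 1
  nuclei <- as_label_matrix(nuclei)
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != nrow(nuclei)) || any(dims[2, ] != ncol(nuclei)))
    stop("channel grids do not match the nucleus mask")
  if (!is.null(glands) && !all(dim(glands) == dim(nuclei)))
    stop("gland mask grid does not match the nucleus mask")
  idx <- which(nuclei > 0L)
  n <- if (length(idx)) max(nuclei[idx]) else 0L
  marker_cols <- as.vector(rbind(paste0(names(channels), "_raw"),
                                 paste0(names(channels), "_norm")))
  if (n == 0L) {
    out <- data.frame(cell_id = integer(), row_px = numeric(),
                      col_px = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), area_px = integer(),
                      mean_radius_px = numeric(), gland_id = integer(),
                      compartment = character())
    for (mc in marker_cols) out[[mc]] <- numeric()
    return(out)
  }
  lab <- nuclei[idx]
  nr <- nrow(nuclei)
  area <- tabulate(lab, nbins = n)
  row0 <- (idx - 1L) %% nr
  col0 <- (idx - 1L) %/% nr
  crow <- as.vector(rowsum(row0, lab, reorder = TRUE)) / area
  ccol <- as.vector(rowsum(col0, lab, reorder = TRUE)) / area
  gid <- integer(n)
  if (!is.null(glands)) {
    glands <- as_label_matrix(glands)
    gid <- glands[cbind(round(crow) + 1L, round(ccol) + 1L)]
  }
  out <- data.frame(cell_id = seq_len(n), row_px = crow, col_px = ccol,
                    centroid_x_um = px_to_um(ccol, resolution),
                    centroid_y_um = px_to_um(crow, resolution),
                    area_px = area,
                    mean_radius_px = sqrt(area / pi),
                    gland_id = gid,
                    compartment = ifelse(gid > 0L, "epithelial", "stromal"),
                    stringsAsFactors = FALSE)
  for (m in names(channels)) {
    raw <- as.vector(rowsum(channels[[m]][idx], lab, reorder = TRUE)) / area
    out[[paste0(m, "_raw")]] <- raw
    out[[paste0(m, "_norm")]] <- raw / 255
  }
  out
}

#' Nucleus-area overlap fraction with a binary mask
#'
#' @param nuclei integer nucleus label mask.
#' @param mask logical (or 0/1) matrix on the same grid.
#' @return Numeric vector, one overlap fraction in `[0, 1]` per object id.
#' @export
mask_overlap <- function(nuclei, mask) {
  nuclei <- as_label_matrix(nuclei)
  if (!all(dim(mask) == dim(nuclei))) stop("mask grid mismatch")
  idx <- which(nuclei > 0L)
  if (!length(idx)) return(numeric())
  lab <- nuclei[idx]
  n <- max(lab)
  as.vector(rowsum(as.numeric(mask[idx]), lab, reorder = TRUE)) /
    tabulate(lab, nbins = n)
}

#' Marker positivity threshold
#'
#' `mean + k * SD` over the supplied values (population SD, i.e. divisor N);
#' a cell is positive when its value is strictly greater than the threshold.
#'
#' @param values numeric vector of (normalized) intensities, nonempty.
#' @param k SD multiplier (1 for most markers; 3 for Ki67).
#' @return The threshold.
#' @export
positivity_threshold <- function(values, k = 1) {
  if (!length(values)) stop("no values; cannot set a positivity threshold")
  m <- mean(values)
  m + k * sqrt(mean((values - m)^2))
}

#' Add SD-based positivity calls to a cell table
#'
#' Computes `positivity_threshold` per marker over all cells' normalized
#' intensities and adds strict-greater `<marker>_positive` columns.
#'
#' @param cells cell table from [measure_cells()].
#' @param panel a [panel_config()]; thresholds use its `sd_multiplier`.
#' @param markers markers to call (default: all with a `_norm` column).
#' @return `cells` with `<marker>_positive` columns; thresholds in attribute
#'   `positivity_thresholds`.
#' @export
call_positivity <- function(cells, panel, markers = NULL) {
  if (is.null(markers))
    markers <- sub("_norm$", "", grep("_norm$", names(cells), value = TRUE))
  th <- numeric(0)
  for (m in markers) {
    k <- if (m %in% names(panel$sd_multiplier)) panel$sd_multiplier[[m]] else 1
    t_m <- positivity_threshold(cells[[paste0(m, "_norm")]], k)
    cells[[paste0(m, "_positive")]] <- cells[[paste0(m, "_norm")]] > t_m
    th[m] <- t_m
  }
  attr(cells, "positivity_thresholds") <- th
  cells
}

#' Compartment of a cell from the gland mask
#'
#' Epithelial when the centroid pixel lies inside a (hole-filled) gland
#' object, stromal otherwise.
#'
#' @param cells cell table with `row_px`, `col_px` (0-based).
#' @param glands integer gland label mask.
#' @return `cells` with refreshed `gland_id` and `compartment` columns.
#' @export
assign_compartment <- function(cells, glands) {
  glands <- as_label_matrix(glands)
  gid <- glands[cbind(round(cells$row_px) + 1L, round(cells$col_px) + 1L)]
  cells$gland_id <- gid
  cells$compartment <- ifelse(gid > 0L, "epithelial", "stromal")
  cells
}

#' Immune-scheme cell classification
#'
#' CD45-positive cells (nucleus overlap with the CD45 mask at least
#' `basal_overlap_min`) become epithelial or stromal leukocytes by
#' compartment, sub-typed T regulatory (CD4+FoxP3+CD8-), T helper
#' (CD4+FoxP3-CD8-) or T effector (CD8+CD4-FoxP3-); CD45-positive cells
#' matching none of the three are `leukocyte-other`. CD45-negative cells
#' inside glands are `epithelial`, outside `other`.
#'
#' @param cells cell table with `compartment`, `cd45_overlap` (or a logical
#'   `cd45_pos`), and `CD4_positive`, `CD8_positive`, `FoxP3_positive`
#'   columns.
#' @param panel a [panel_config()] (immune scheme).
#' @return `cells` with a `class` column over the closed immune label set.
#' @export
classify_immune <- function(cells, panel = panel_config("immune")) {
  stopifnot(panel$scheme == "immune")
  for (col in c("CD4_positive", "CD8_positive", "FoxP3_positive"))
    if (is.null(cells[[col]])) stop(sprintf("missing required column %s", col))
  cd45 <- if (!is.null(cells$cd45_pos)) cells$cd45_pos
    else if (!is.null(cells$cd45_overlap))
      cells$cd45_overlap >= panel$basal_overlap_min
    else stop("missing cd45_pos / cd45_overlap column")
  inside <- cells$compartment == "epithelial"
  pre <- ifelse(inside, "epi", "stromal")
  cd4 <- cells$CD4_positive; cd8 <- cells$CD8_positive
  foxp3 <- cells$FoxP3_positive
  subtype <- rep("leukocyte-other", nrow(cells))
  subtype[cd4 & foxp3 & !cd8] <- "Treg"
  subtype[cd4 & !foxp3 & !cd8] <- "Th"
  subtype[cd8 & !cd4 & !foxp3] <- "Te"
  cls <- ifelse(cd45, paste0(pre, "-", subtype),
                ifelse(inside, "epithelial", "other"))
  cells$cd45_pos <- cd45
  cells$class <- cls
  cells
}

#' Epithelial-scheme gland and cell classification
#'
#' A cell is basal when its nucleus overlaps the CK5+p63 mask by at least
#' `basal_overlap_min` of its area; a gland is malignant iff it contains no
#' basal cell. Nuclei in malignant glands are cancer cells, nuclei in benign
#' glands are basal or benign luminal, nuclei outside glands are stromal.
#'
#' @param cells cell table with `gland_id` (0 = stroma) and `basal_overlap`
#'   (nucleus-area overlap fraction with the CK5+p63 mask, from
#'   [mask_overlap()]).
#' @param panel a [panel_config()] (epithelial scheme).
#' @param gland_areas optional named/indexed vector of gland areas (px^2) to
#'   carry into the gland records.
#' @return List with `cells` (added `basal_pos`, `class`) and `glands`
#'   (data.frame `gland_id`, `n_cells`, `n_basal_cells`, `malignant`,
#'   optionally `area_px`).
#' @export
classify_glands_and_epithelial <- function(cells,
                                           panel = panel_config("epithelial"),
                                           gland_areas = NULL) {
  stopifnot(panel$scheme == "epithelial")
  if (is.null(cells$basal_overlap)) stop("missing basal_overlap column")
  basal <- cells$basal_overlap >= panel$basal_overlap_min
  gids <- sort(unique(cells$gland_id[cells$gland_id > 0]))
  if (!is.null(gland_areas)) gids <- union(gids, seq_along(gland_areas))
  gids <- sort(gids)
  n_cells_g <- vapply(gids, function(g) sum(cells$gland_id == g), integer(1))
  n_basal_g <- vapply(gids, function(g) sum(basal[cells$gland_id == g]),
                      integer(1))
  glands <- data.frame(gland_id = gids, n_cells = n_cells_g,
                       n_basal_cells = n_basal_g,
                       malignant = n_basal_g == 0L)
  if (!is.null(gland_areas)) glands$area_px <- gland_areas[gids]
  malignant_of <- stats::setNames(glands$malignant, glands$gland_id)
  inside <- cells$gland_id > 0
  mal <- rep(FALSE, nrow(cells))
  mal[inside] <- malignant_of[as.character(cells$gland_id[inside])]
  cls <- rep("stromal", nrow(cells))
  cls[inside & mal] <- "cancer"
  cls[inside & !mal & basal] <- "basal"
  cls[inside & !mal & !basal] <- "benign-luminal"
  cells$basal_pos <- basal
  cells$class <- cls
  list(cells = cells, glands = glands)
}

#' Tissue-cytometry summary tables
#'
#' Immune scheme: class distribution over the closed label set, the
#' leukocyte compartment split, T-class proportions among leukocytes per
#' compartment, and Ki67-positive fractions per T class per compartment.
#' Epithelial scheme: class distribution, per-class mean normalized marker
#' expression, and AR expression stratified by AMACR status within cancer
#' and benign luminal cells.
#'
#' @param cells classified cell table.
#' @param scheme `"immune"` or `"epithelial"`.
#' @return A list of data.frames of class `panel_summary` (zero-filled for an
#'   empty input).
#' @export
summarize_panel <- function(cells, scheme = c("immune", "epithelial")) {
  scheme <- match.arg(scheme)
  lv <- if (scheme == "immune") immune_class_levels else epithelial_class_levels
  n <- nrow(cells)
  tab <- table(factor(cells$class, levels = lv))
  dist <- data.frame(class = lv, n = as.integer(tab),
                     pct = if (n > 0) 100 * as.integer(tab) / n else 0)
  out <- list(class_distribution = dist, n_cells = n)
  if (scheme == "immune") {
    is_leuk <- grepl("Treg|Th$|Te$|leukocyte", cells$class)
    nl <- sum(is_leuk)
    out$leukocytes <- data.frame(
      n = nl,
      pct_of_cells = if (n > 0) 100 * nl / n else 0,
      pct_epithelial = if (nl > 0)
        100 * sum(is_leuk & cells$compartment == "epithelial") / nl else 0,
      pct_stromal = if (nl > 0)
        100 * sum(is_leuk & cells$compartment == "stromal") / nl else 0)
    rows <- expand.grid(t_class = c("Treg", "Th", "Te"),
                        compartment = c("epithelial", "stromal"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$pct_of_leukocytes <- 0
    rows$pct_ki67_positive <- 0
    for (i in seq_len(nrow(rows))) {
      in_comp <- is_leuk & cells$compartment == rows$compartment[i]
      in_cls <- in_comp & grepl(paste0("-", rows$t_class[i], "$"), cells$class)
      nlc <- sum(in_comp)
      rows$pct_of_leukocytes[i] <- if (nlc > 0) 100 * sum(in_cls) / nlc else 0
      if (!is.null(cells$Ki67_positive) && sum(in_cls) > 0)
        rows$pct_ki67_positive[i] <- 100 * mean(cells$Ki67_positive[in_cls])
    }
    out$t_classes <- rows
  } else {
    norm_cols <- grep("_norm$", names(cells), value = TRUE)
    mm <- lapply(lv, function(cl) {
      sel <- cells$class == cl
      v <- vapply(norm_cols, function(cc)
        if (any(sel)) mean(cells[[cc]][sel]) else 0, numeric(1))
      as.data.frame(as.list(v))
    })
    out$marker_means <- cbind(data.frame(class = lv), do.call(rbind, mm))
    if (!is.null(cells$AMACR_positive) && "AR_norm" %in% names(cells)) {
      grp <- expand.grid(class = c("cancer", "benign-luminal"),
                         amacr = c(TRUE, FALSE),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grp$n <- 0L; grp$mean_ar_norm <- 0
      for (i in seq_len(nrow(grp))) {
        sel <- cells$class == grp$class[i] & cells$AMACR_positive == grp$amacr[i]
        grp$n[i] <- sum(sel)
        if (any(sel)) grp$mean_ar_norm[i] <- mean(cells$AR_norm[sel])
      }
      out$ar_by_amacr <- grp
    }
  }
  class(out) <- c("panel_summary", "list")
  out
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("<panel_summary> %d cells\n", x$n_cells))
  print(x$class_distribution, row.names = FALSE)
  if (!is.null(x$t_classes)) {
    cat("T classes among leukocytes, by compartment:\n")
    print(x$t_classes, row.names = FALSE)
  }
  if (!is.null(x$ar_by_amacr)) {
    cat("AR by AMACR status:\n")
    print(x$ar_by_amacr, row.names = FALSE)
  }
  invisible(x)
}
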