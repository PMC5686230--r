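## Synthetic whole-slide generator.
##
## Emits a paired fluorescence + brightfield slide with full ground truth:
## glandular tissue (elliptical glands with an epithelial cell ring/annulus,
## an empty or leukocyte-bearing lumen, and -- for benign glands -- a basal
## cell ring), stromal and immune cells on jittered hexagonal site lattices,
## per-class marker intensities, autofluorescence background, Beer-Lambert
## chromogen rendering of the brightfield image at a different resolution,
## and a planted similarity transform between the two modalities.
##
## Every cell is an isotropic Gaussian blob (sigma = radius / 2) on the
## nuclear channel; marker channels reuse the footprint scaled by the cell's
## class-specific marker mean. The brightfield image is rendered from
## per-stain concentration maps (haematoxylin from all nuclei, the two
## chromogens from their marker-positive cells).

#' Configuration of the synthetic slide generator
#'
#' Defaults define the package's reference study conditions: a prostate-like
#' tissue with the immune-panel class mix 38% leukocytes / 40% epithelial /
#' 22% stromal cells (T subsets and their compartment imbalance included) or
#' the epithelial-panel mix 54% stromal / 15% basal / 11% benign luminal /
#' 20% cancer cells, at 800 cells/mm^2, fluorescence sampled at 0.64 um/px
#' and brightfield at 0.88 um/px under a small planted similarity transform.
#'
#' @param scheme `"immune"` or `"epithelial"` panel.
#' @param image_height_px,image_width_px fluorescence image size in pixels.
#' @param fl_resolution,bf_resolution modality resolutions, um/px.
#' @param n_glands gland count, or `NULL` to size automatically from the
#'   epithelial cell demand.
#' @param gland_axes range of gland semi-major axes, px (semi-minor drawn as
#'   75--100% of the major).
#' @param fraction_cancer_glands fraction of glands lacking basal cells
#'   (used when `n_glands` is given explicitly; epithelial scheme).
#' @param cell_density cells per mm^2 of placeable tissue.
#' @param class_proportions named proportions over the scheme's truth
#'   classes, summing to 1 (defaults above).
#' @param t_subset_props per-compartment proportions of Treg/Th/Te (and
#'   remainder "other") among leukocytes (immune scheme).
#' @param leukocyte_epi_fraction fraction of leukocytes inside glands.
#' @param ki67_rates named Ki67-positive rates per truth class (immune).
#' @param amacr_rates named AMACR-positive rates per truth class (epithelial).
#' @param marker_profiles data.frame `(class, marker, mean, sd)` of blob peak
#'   intensities on the 0--255 scale; `NULL` for the scheme default
#'   ([default_marker_profiles()]).
#' @param cell_radius_range planted cell radius range, px.
#' @param marker_footprint named multipliers of the blob sigma per marker
#'   (cytoplasmic markers are wider than the nucleus; default Pan-Epi 1.8).
#' @param autofluorescence_level background level of fluorescence channels.
#' @param noise_sd additive Gaussian noise, gray levels (both modalities).
#' @param planted_transform list `rotation_deg`, `scale`, `translation_um`
#'   (length 2): the similarity mapping scene (brightfield) physical
#'   coordinates to fluorescence physical coordinates, about the scene
#'   centre.
#' @param stain_matrix [stain_matrix] used to render the brightfield image.
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `slide_sim_config`.
#' @export
slide_sim_config <- function(scheme = c("immune", "epithelial"),
                             image_height_px = 2048L,
                             image_width_px = 2048L,
                             fl_resolution = 0.64,
                             bf_resolution = 0.88,
                             n_glands = NULL,
                             gland_axes = c(80, 130),
                             fraction_cancer_glands = 0.5,
                             cell_density = 800,
                             class_proportions = NULL,
                             t_subset_props = NULL,
                             leukocyte_epi_fraction = 0.24,
                             ki67_rates = NULL,
                             amacr_rates = NULL,
                             marker_profiles = NULL,
                             cell_radius_range = c(20, 24),
                             marker_footprint = c(PanEpi = 1.8),
                             autofluorescence_level = 8,
                             noise_sd = 2,
                             planted_transform = list(rotation_deg = 3,
                                                      scale = 1.01,
                                                      translation_um = c(25, -18)),
                             stain_matrix = synthetic_stain_matrix(),
                             rng_seed = 1L) {
  scheme <- match.arg(scheme)
  if (is.null(class_proportions)) {
    class_proportions <- switch(scheme,
      immune = c(leukocyte = 0.38, epithelial = 0.40, stromal = 0.22),
      epithelial = c(stromal = 0.54, basal = 0.15,
                     benign_luminal = 0.11, cancer = 0.20))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class_proportions must be nonnegative")
  if (is.null(t_subset_props)) {
    t_subset_props <- list(
      epithelial = c(Treg = 0.018, Th = 0.11, Te = 0.090),
      stromal    = c(Treg = 0.057, Th = 0.22, Te = 0.088))
  }
  if (is.null(ki67_rates)) {
    ki67_rates <- c("epi-Treg" = 0.040, "epi-Th" = 0.011, "epi-Te" = 0.010,
                    "stromal-Treg" = 0.014, "stromal-Th" = 0.005,
                    "stromal-Te" = 0.010, "epi-leukocyte-other" = 0.005,
                    "stromal-leukocyte-other" = 0.005,
                    "epithelial" = 0.020, "other" = 0.005)
  }
  if (is.null(amacr_rates)) {
    amacr_rates <- c(cancer = 0.31, benign_luminal = 0.053,
                     basal = 0, stromal = 0)
  }
  if (is.null(marker_profiles)) marker_profiles <- default_marker_profiles(scheme)
  stopifnot(image_height_px >= 1, image_width_px >= 1,
            fl_resolution > 0, bf_resolution > 0,
            cell_density >= 0, length(cell_radius_range) == 2L,
            autofluorescence_level >= 0, autofluorescence_level <= 255,
            noise_sd >= 0,
            all(marker_profiles$mean >= 0), all(marker_profiles$mean <= 255))
  if (image_height_px * image_width_px == 0) stop("zero-size image")
  structure(list(scheme = scheme,
                 image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 fl_resolution = fl_resolution,
                 bf_resolution = bf_resolution,
                 n_glands = n_glands,
                 gland_axes = gland_axes,
                 fraction_cancer_glands = fraction_cancer_glands,
                 cell_density = cell_density,
                 class_proportions = class_proportions,
                 t_subset_props = t_subset_props,
                 leukocyte_epi_fraction = leukocyte_epi_fraction,
                 ki67_rates = ki67_rates,
                 amacr_rates = amacr_rates,
                 marker_profiles = marker_profiles,
                 cell_radius_range = cell_radius_range,
                 marker_footprint = marker_footprint,
                 autofluorescence_level = autofluorescence_level,
                 noise_sd = noise_sd,
                 planted_transform = planted_transform,
                 stain_matrix = stain_matrix,
                 rng_seed = as.integer(rng_seed)),
            class = "slide_sim_config")
}

#' Default per-class marker blob intensities
#'
#' Peak intensities (0--255) of the Gaussian marker blobs per truth class.
#' Epithelial-panel levels follow the relative expression differences the
#' platform is meant to resolve (e.g. CK18 elevated in cancer vs. benign
#' luminal cells, AR elevated in AMACR-negative cancer cells).
#'
#' @param scheme `"immune"` or `"epithelial"`.
#' @return data.frame with columns `class`, `marker`, `mean`, `sd`.
#' @export
default_marker_profiles <- function(scheme) {
  pos <- function(cls, m, mean, sd = 15) data.frame(class = cls, marker = m,
                                                    mean = mean, sd = sd)
  if (scheme == "immune") {
    classes <- c("epi-Treg", "epi-Th", "epi-Te", "epi-leukocyte-other",
                 "stromal-Treg", "stromal-Th", "stromal-Te",
                 "stromal-leukocyte-other", "epithelial", "other")
    leuk <- grep("Treg|Th|Te|leukocyte", classes, value = TRUE)
    cd4 <- grep("Treg|Th$", classes, value = TRUE)
    prof <- expand.grid(class = classes,
                        marker = c("nuclei", "CD45", "CD4", "CD8", "FoxP3",
                                   "PanEpi", "Ki67"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    prof$mean <- 10; prof$sd <- 4
    set <- function(p, cls, m, mean, sd) {
      i <- p$class %in% cls & p$marker == m
      p$mean[i] <- mean; p$sd[i] <- sd; p
    }
    prof <- set(prof, classes, "nuclei", 200, 20)
    prof <- set(prof, leuk, "CD45", 180, 15)
    prof <- set(prof, cd4, "CD4", 170, 15)
    prof <- set(prof, grep("Te$", classes, value = TRUE), "CD8", 170, 15)
    prof <- set(prof, grep("Treg", classes, value = TRUE), "FoxP3", 160, 15)
    prof <- set(prof, "epithelial", "PanEpi", 140, 12)
    prof <- rbind(prof, data.frame(class = "_ki67_positive", marker = "Ki67",
                                   mean = 150, sd = 12))
    prof
  } else {
    classes <- c("cancer", "benign-luminal", "basal", "stromal")
    prof <- expand.grid(class = classes,
                        marker = c("nuclei", "CK18", "CK8", "CK5p63",
                                   "PanEpi", "AR", "AMACR"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    prof$mean <- 8; prof$sd <- 3
    set <- function(p, cls, m, mean, sd) {
      i <- p$class %in% cls & p$marker == m
      p$mean[i] <- mean; p$sd[i] <- sd; p
    }
    epi <- c("cancer", "benign-luminal", "basal")
    prof <- set(prof, classes, "nuclei", 200, 20)
    prof <- set(prof, epi, "PanEpi", 170, 15)
    prof <- set(prof, "basal", "CK5p63", 180, 15)
    prof <- set(prof, "cancer", "CK18", 51, 8)
    prof <- set(prof, "benign-luminal", "CK18", 30, 6)
    prof <- set(prof, "basal", "CK18", 12, 4)
    prof <- set(prof, "cancer", "CK8", 21, 5)
    prof <- set(prof, "benign-luminal", "CK8", 18, 5)
    prof <- set(prof, "basal", "CK8", 10, 4)
    prof <- set(prof, "cancer", "AR", 41, 7)          # AMACR- cancer level
    prof <- set(prof, "benign-luminal", "AR", 26, 6)
    prof <- set(prof, "basal", "AR", 16, 5)
    prof <- rbind(prof,
                  data.frame(class = "_amacr_positive", marker = "AMACR",
                             mean = 120, sd = 12),
                  data.frame(class = "_amacr_positive", marker = "AR",
                             mean = 29, sd = 6))
    prof
  }
}

## ---- geometry helpers -------------------------------------------------------

## jittered hexagonal lattice over [0, w] x [0, h]; returns (row, col) matrix
hex_lattice <- function(h, w, spacing, jitter = 0.15) {
  dy <- spacing * sqrt(3) / 2
  rows <- seq(0, h, by = dy)
  pts <- lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    cols <- seq(off, w, by = spacing)
    cbind(rows[i], cols)
  })
  pts <- do.call(rbind, pts)
  if (!nrow(pts)) return(pts)
  pts + matrix(runif(2L * nrow(pts), -jitter * spacing, jitter * spacing),
               ncol = 2L)
}

## the planted similarity as a physical-coordinate affine (scene um -> fl um)
planted_phys_transform <- function(config) {
  pt <- config$planted_transform
  th <- pt$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(config$image_height_px, config$image_width_px) *
    config$fl_resolution / 2
  A <- pt$scale * R
  affine_transform(A, ctr + pt$translation_um - as.vector(A %*% ctr))
}

## physical um <-> pixel-grid affines
phys_to_px_transform <- function(res)
  affine_transform(diag(2) / res, c(-0.5, -0.5))
px_to_phys_transform <- function(res)
  affine_transform(diag(2) * res, c(res / 2, res / 2))

## planted moving->reference transform: fluorescence px -> brightfield px
planted_px_transform <- function(config) {
  t_phys <- planted_phys_transform(config)            # scene um -> fl um
  compose_affine(phys_to_px_transform(config$bf_resolution),
                 compose_affine(invert_affine(t_phys),
                                px_to_phys_transform(config$fl_resolution)))
}

## ---- truth sampling ---------------------------------------------------------

#' Sample the ground truth of a synthetic slide (no rendering)
#'
#' Draws gland geometry, cell positions, classes, flags, and per-marker true
#' intensities, without rendering any raster. [generate_slide()] uses the
#' same draws (same seed, same order), so its truth is identical.
#'
#' @param config a [slide_sim_config()].
#' @return An object of class `ground_truth_slide`: list with `cells`
#'   (data.frame), `glands` (data.frame), `transform` (planted
#'   [affine_transform], fluorescence px to brightfield px), `stain_matrix`,
#'   and `config`.
#' @export
sample_truth <- function(config) {
  stopifnot(inherits(config, "slide_sim_config"))
  with_rng_seed(config$rng_seed, sample_truth_impl(config))
}

sample_truth_impl <- function(config) {
  u <- config$fl_resolution
  extent <- c(config$image_height_px, config$image_width_px) * u   # um
  t_phys <- planted_phys_transform(config)
  corners <- rbind(c(0, 0), c(extent[1], 0), c(0, extent[2]), extent)
  disp <- max(sqrt(rowSums((apply_affine(t_phys, corners) - corners)^2)))
  r_mean <- mean(config$cell_radius_range)
  margin <- disp + (max(config$cell_radius_range) + 10) * u
  inner <- extent - 2 * margin
  if (any(inner <= 0)) stop("slide too small for the planted transform margin")
  area_mm2 <- prod(inner) / 1e6
  n_cells <- round(config$cell_density * area_mm2)

  classes <- if (n_cells > 0)
    sample(names(config$class_proportions), n_cells, replace = TRUE,
           prob = config$class_proportions) else character()

  spacing <- 1.75 * r_mean * u         # gland site lattice spacing (um)
  spacing_stroma <- 2.2 * r_mean * u
  ax_mean <- mean(config$gland_axes) * u
  bx_mean <- 0.875 * ax_mean
  ## immune glands keep the lumen clear for infiltrating leukocytes, so the
  ## epithelial annulus starts at 0.50; the epithelial panel has empty
  ## lumina and can line cells from 0.40 outwards. Benign glands stop at
  ## 0.70 to leave clearance for the basal ring at 0.94.
  lo_ann <- if (config$scheme == "immune") 0.50 else 0.40
  cap_of <- function(lo, hi) max(1, floor(pi * ax_mean * bx_mean *
                                            (hi^2 - lo^2) * 1.1547 / spacing^2))
  per_mean <- pi * (3 * (ax_mean + bx_mean) -
                      sqrt((3 * ax_mean + bx_mean) * (ax_mean + 3 * bx_mean)))
  ann_cap <- cap_of(lo_ann, 0.88)
  ## benign: a closed luminal ring sitting a fixed physical distance below
  ## the basal ring (always morphologically bridged, never close enough to
  ## merge nuclei) plus an inner lattice kept clear of the ring
  ring_gap <- 32 * 0.64        # luminal-to-basal ring distance, um
  lat_gap <- 25 * 0.64         # lattice-to-ring clearance, um
  s1_mean <- max(0.30, min(0.70, 0.94 - ring_gap / bx_mean))
  lat_hi_mean <- max(lo_ann, s1_mean - lat_gap / bx_mean)
  ann_cap_benign <- max(1, floor(per_mean * s1_mean / (0.85 * spacing)) +
                          cap_of(lo_ann, lat_hi_mean))
  basal_cap <- max(1, floor(2 * pi * (ax_mean + bx_mean) / 2 * 0.94 /
                              (0.85 * spacing)))
  fill <- 0.92   # target site occupancy: glands are filled one after another,
                 # so head-room vacancies concentrate in the last gland(s)
                 # instead of punching holes in every epithelial ring

  ## gland demand by scheme
  if (config$scheme == "immune") {
    is_leuk <- classes == "leukocyte"
    leuk_epi <- is_leuk & runif(length(classes)) < config$leukocyte_epi_fraction
    n_epi_cells <- sum(classes == "epithelial")
    n_ben <- 0L
    n_can <- 0L
    n_gl <- if (!is.null(config$n_glands)) as.integer(config$n_glands)
      else ceiling(n_epi_cells / (fill * ann_cap))
  } else {
    n_basal <- sum(classes == "basal")
    n_benlum <- sum(classes == "benign_luminal")
    n_cancer <- sum(classes == "cancer")
    if (!is.null(config$n_glands)) {
      n_gl <- as.integer(config$n_glands)
      n_can <- round(n_gl * config$fraction_cancer_glands)
      n_ben <- n_gl - n_can
    } else {
      n_ben <- max(ceiling(n_basal / (fill * basal_cap)),
                   ceiling(n_benlum / (fill * ann_cap_benign)))
      n_can <- ceiling(n_cancer / (fill * ann_cap))
      n_gl <- n_ben + n_can
    }
  }

  ## place gland ellipses on a jittered hexagonal grid whose spacing
  ## guarantees non-overlap (jitter amplitude shrinks with gland size)
  glands <- NULL
  if (n_gl > 0) {
    a <- runif(n_gl, config$gland_axes[1], config$gland_axes[2]) * u
    b <- a * runif(n_gl, 0.75, 1)
    theta <- runif(n_gl, 0, pi)
    a_max <- config$gland_axes[2] * u
    sg <- 2.1 * a_max
    gm <- margin + a_max
    span <- extent - 2 * gm
    if (any(span <= 0))
      stop("slide too small to hold a gland; enlarge the image or shrink gland_axes")
    nodes <- hex_lattice(span[1], span[2], sg, jitter = 0)
    nodes <- sweep(nodes, 2L, c(gm, gm), "+")
    if (nrow(nodes) < n_gl)
      stop(sprintf("tissue area holds at most %d glands, %d requested; lower cell_density or n_glands",
                   nrow(nodes), n_gl))
    nodes <- nodes[sample.int(nrow(nodes), n_gl), , drop = FALSE]
    jit_amp <- pmax(0, sg / 2 - a - 8)
    centres <- nodes + matrix(runif(2L * n_gl, -1, 1), ncol = 2L) * jit_amp
    malignant <- if (config$scheme == "epithelial")
      rep(c(FALSE, TRUE), c(n_ben, n_can))[sample.int(n_gl)] else rep(NA, n_gl)
    glands <- data.frame(gland_id = seq_len(n_gl),
                         row_um = centres[, 1], col_um = centres[, 2],
                         a_um = a, b_um = b, theta = theta,
                         malignant = malignant)
  }

  ## site pools
  ell_local <- function(g, pts) {
    ## local elliptical radius of (row, col) um points for gland row g
    d <- sweep(pts, 2L, c(g$row_um, g$col_um))
    lr <- d[, 1] * cos(g$theta) + d[, 2] * sin(g$theta)
    lc <- -d[, 1] * sin(g$theta) + d[, 2] * cos(g$theta)
    sqrt((lr / g$a_um)^2 + (lc / g$b_um)^2)
  }
  gland_sites <- function(g, lo, hi) {
    box <- c(2 * g$a_um, 2 * g$a_um)
    pts <- hex_lattice(box[1], box[2], spacing)
    if (!nrow(pts)) return(NULL)
    pts <- sweep(pts, 2L, c(g$row_um - g$a_um, g$col_um - g$a_um), "+")
    r <- ell_local(g, pts)
    pts <- pts[r >= lo & r < hi, , drop = FALSE]
    if (!nrow(pts)) return(NULL)
    cbind(pts, g$gland_id)[sample.int(nrow(pts)), , drop = FALSE]
  }
  ring_sites <- function(g, sc, arc_spacing) {
    per <- pi * (3 * (g$a_um + g$b_um) -
                   sqrt((3 * g$a_um + g$b_um) * (g$a_um + 3 * g$b_um)))
    n1 <- max(3L, round(per * sc / arc_spacing))
    phi <- seq(0, 2 * pi, length.out = n1 + 1L)[-1] +
      runif(n1, -0.5, 0.5) * 2 * pi / (4 * n1)
    lr <- g$a_um * sc * cos(phi); lc <- g$b_um * sc * sin(phi)
    out <- cbind(g$row_um + lr * cos(g$theta) - lc * sin(g$theta),
                 g$col_um + lr * sin(g$theta) + lc * cos(g$theta),
                 g$gland_id)
    out[sample.int(nrow(out)), , drop = FALSE]
  }

  pool_ann <- list(); pool_lumen <- list(); pool_basal <- list()
  if (n_gl > 0) {
    for (i in seq_len(n_gl)) {
      g <- glands[i, ]
      if (config$scheme == "epithelial" && isTRUE(!g$malignant)) {
        ## benign: closed luminal ring (consumed first, so every benign
        ## gland outline below the basal ring is connected) plus the deeper
        ## annulus lattice
        s1 <- max(0.30, min(0.70, 0.94 - ring_gap / g$b_um))
        lat_hi <- max(lo_ann, s1 - lat_gap / g$b_um)
        lat <- if (lat_hi > lo_ann + 0.03) gland_sites(g, lo_ann, lat_hi)
        pool_ann[[i]] <- rbind(ring_sites(g, s1, 0.85 * spacing), lat)
        pool_basal[[i]] <- ring_sites(g, 0.94, 0.85 * spacing)
      } else {
        pool_ann[[i]] <- gland_sites(g, lo_ann, 0.88)
      }
      pool_lumen[[i]] <- gland_sites(g, 0, 0.30)
    }
  }
  ## sequential pools: sites shuffled within each gland, glands visited in
  ## random order, so consuming the pool front-to-back fills whole glands.
  ## interleaved pools cycle gland by gland (rank 1 of every gland, then
  ## rank 2, ...), so head-room vacancies spread evenly -- used for basal
  ## rings, where every benign gland must keep basal cells.
  bind_pool <- function(lst, interleave = FALSE) {
    ## sites are already shuffled within each gland (rings first for benign
    ## glands); only the gland visiting order is randomized here
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (!length(lst)) return(matrix(numeric(), 0L, 3L))
    lst <- lst[sample.int(length(lst))]
    m <- do.call(rbind, lst)
    if (interleave) {
      rank <- unlist(lapply(lst, function(x) seq_len(nrow(x))))
      m <- m[order(rank), , drop = FALSE]
    }
    m
  }
  pool_ann <- bind_pool(pool_ann)
  pool_lumen <- bind_pool(pool_lumen, interleave = TRUE)
  pool_basal <- bind_pool(pool_basal, interleave = TRUE)

  ## stroma sites: lattice minus glands (with clearance)
  stroma <- hex_lattice(inner[1], inner[2], spacing_stroma)
  if (nrow(stroma)) {
    stroma <- sweep(stroma, 2L, c(margin, margin), "+")
    keep <- rep(TRUE, nrow(stroma))
    if (n_gl > 0) {
      for (i in seq_len(n_gl))
        keep <- keep & ell_local(glands[i, ], stroma) > 1.25
    }
    inb <- stroma[, 1] > margin & stroma[, 1] < extent[1] - margin &
      stroma[, 2] > margin & stroma[, 2] < extent[2] - margin
    stroma <- stroma[keep & inb, , drop = FALSE]
    stroma <- stroma[sample.int(nrow(stroma)), , drop = FALSE]
  }

  take <- function(pool, n, what) {
    if (n > nrow(pool))
      stop(sprintf("site pool exhausted for %s (%d needed, %d available)",
                   what, n, nrow(pool)))
    pool[seq_len(n), , drop = FALSE]
  }

  ## assign positions per class
  n <- length(classes)
  pos <- matrix(NA_real_, n, 2L)
  gland_id <- integer(n)
  compartment <- character(n)
  if (config$scheme == "immune") {
    subtype <- rep(NA_character_, n)
    idx_epi <- which(classes == "epithelial")
    s <- take(pool_ann, length(idx_epi), "epithelial cells")
    if (length(idx_epi)) {
      pos[idx_epi, ] <- s[, 1:2]; gland_id[idx_epi] <- s[, 3]
      pool_ann <- pool_ann[-seq_len(length(idx_epi)), , drop = FALSE]
    }
    idx_le <- which(leuk_epi)
    pool_in <- rbind(pool_lumen, pool_ann)
    s <- take(pool_in, length(idx_le), "epithelial leukocytes")
    pos[idx_le, ] <- s[, 1:2]; gland_id[idx_le] <- s[, 3]
    idx_str <- which(!leuk_epi & classes != "epithelial")
    s <- take(stroma, length(idx_str), "stromal cells")
    pos[idx_str, ] <- s[, 1:2]
    compartment <- ifelse(gland_id > 0, "epithelial", "stromal")
    ## T subsets within leukocytes, per compartment
    for (comp in c("epithelial", "stromal")) {
      idx <- which(is_leuk & compartment == comp)
      pr <- config$t_subset_props[[comp]]
      pr <- c(pr, other = 1 - sum(pr))
      if (length(idx))
        subtype[idx] <- sample(names(pr), length(idx), TRUE, pr)
    }
    pre <- ifelse(compartment == "epithelial", "epi", "stromal")
    class_label <- ifelse(is_leuk,
                          paste0(pre, "-", ifelse(subtype == "other",
                                                  "leukocyte-other", subtype)),
                          ifelse(classes == "epithelial", "epithelial", "other"))
  } else {
    for (cls in c("basal", "benign_luminal", "cancer", "stromal")) {
      idx <- which(classes == cls)
      if (!length(idx)) next
      pool <- switch(cls,
                     basal = pool_basal,
                     benign_luminal = pool_ann[glands$malignant[pool_ann[, 3]] == FALSE, ,
                                               drop = FALSE],
                     cancer = pool_ann[glands$malignant[pool_ann[, 3]] == TRUE, ,
                                       drop = FALSE],
                     stromal = cbind(stroma, 0))
      s <- take(pool, length(idx), cls)
      pos[idx, ] <- s[, 1:2]; gland_id[idx] <- s[, 3]
    }
    compartment <- ifelse(gland_id > 0, "epithelial", "stromal")
    class_label <- sub("benign_luminal", "benign-luminal", classes)
  }

  radius <- if (n > 0)
    runif(n, config$cell_radius_range[1], config$cell_radius_range[2]) else numeric()
  ki67 <- amacr <- rep(FALSE, n)
  if (n > 0 && config$scheme == "immune") {
    rate <- config$ki67_rates[class_label]
    rate[is.na(rate)] <- 0
    ki67 <- runif(n) < rate
  }
  if (n > 0 && config$scheme == "epithelial") {
    rate <- config$amacr_rates[classes]
    rate[is.na(rate)] <- 0
    amacr <- runif(n) < rate
  }

  ## per-marker true blob peaks
  markers <- setdiff(unique(config$marker_profiles$marker), NA)
  markers <- markers[!startsWith(markers, "_")]
  prof <- config$marker_profiles
  marker_means <- matrix(0, n, length(markers),
                         dimnames = list(NULL, markers))
  if (n > 0) {
    for (m in markers) {
      pm <- prof[prof$marker == m & !startsWith(prof$class, "_"), ]
      mu <- pm$mean[match(class_label, pm$class)]
      sd_ <- pm$sd[match(class_label, pm$class)]
      mu[is.na(mu)] <- 8; sd_[is.na(sd_)] <- 3
      ## flag overrides (Ki67+/AMACR+ cells)
      ov <- prof[prof$marker == m & startsWith(prof$class, "_"), ]
      if (nrow(ov)) {
        flag <- if (ov$class[1] == "_ki67_positive") ki67 else amacr
        mu[flag] <- ov$mean[1]; sd_[flag] <- ov$sd[1]
      }
      marker_means[, m] <- pmin(255, pmax(0, rnorm(n, mu, sd_)))
    }
  }

  cells <- data.frame(cell_id = seq_len(n),
                      row_um = pos[, 1], col_um = pos[, 2],
                      radius_px = radius,
                      class = class_label,
                      compartment = compartment,
                      gland_id = gland_id,
                      ki67_pos = ki67, amacr_pos = amacr,
                      stringsAsFactors = FALSE)
  if (n > 0) cells <- cbind(cells, as.data.frame(marker_means))
  if (is.null(glands))
    glands <- data.frame(gland_id = integer(), row_um = numeric(),
                         col_um = numeric(), a_um = numeric(),
                         b_um = numeric(), theta = numeric(),
                         malignant = logical())
  structure(list(cells = cells, glands = glands,
                 transform = planted_px_transform(config),
                 stain_matrix = config$stain_matrix,
                 concentration_maps = NULL,
                 config = config),
            class = "ground_truth_slide")
}

#' @export
print.ground_truth_slide <- function(x, ...) {
  cat(sprintf("<ground_truth_slide> %s scheme: %d cells, %d glands\n",
              x$config$scheme, nrow(x$cells), nrow(x$glands)))
  if (nrow(x$cells)) print(round(100 * table(x$cells$class) / nrow(x$cells), 1))
  invisible(x)
}

## ---- rendering --------------------------------------------------------------

## add Gaussian blobs in place; sub-pixel centres are honoured to 1/4 px by
## caching fractional-offset patches per (sigma, offset) pair
paint_blobs <- function(canvas, rows_px, cols_px, sigmas, peaks,
                        cache = new.env(parent = emptyenv())) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  base_r <- floor(rows_px); base_c <- floor(cols_px)
  fr <- round((rows_px - base_r) * 4) / 4
  fc <- round((cols_px - base_c) * 4) / 4
  base_r <- as.integer(base_r) + 1L       # to 1-based
  base_c <- as.integer(base_c) + 1L
  sig_k <- round(sigmas * 10) / 10
  for (i in seq_along(rows_px)) {
    if (peaks[i] <= 0) next
    key <- paste(sig_k[i], fr[i], fc[i])
    patch <- cache[[key]]
    if (is.null(patch)) {
      R <- ceiling(2.5 * sig_k[i])
      d <- (-R):(R + 1L)
      patch <- exp(-outer((d - fr[i])^2, (d - fc[i])^2, "+") /
                     (2 * sig_k[i]^2))
      cache[[key]] <- patch
    }
    R <- nrow(patch) %/% 2L - 1L
    r0 <- base_r[i] - R; r1 <- base_r[i] + R + 1L
    c0 <- base_c[i] - R; c1 <- base_c[i] + R + 1L
    pr0 <- 1L + max(0L, 1L - r0); pr1 <- nrow(patch) - max(0L, r1 - nr)
    pc0 <- 1L + max(0L, 1L - c0); pc1 <- ncol(patch) - max(0L, c1 - nc)
    if (pr1 < pr0 || pc1 < pc0) next
    rr <- max(1L, r0):min(nr, r1); cc <- max(1L, c0):min(nc, c1)
    canvas[rr, cc] <- canvas[rr, cc] +
      peaks[i] * patch[pr0:pr1, pc0:pc1]
  }
  canvas
}

#' Render an RGB brightfield image from stain concentration maps
#'
#' Forward Beer-Lambert model: per pixel and RGB channel `k`,
#' `I_k = 255 * 10^(-sum_s c_s M[s, k])`, clipped to `[0, 255]` (not
#' quantized; the caller decides).
#'
#' @param concentration_maps named list of nonnegative rasters, one per stain
#'   (names matching `stain_matrix` rows), or a `concentration_maps` object.
#' @param stain_matrix a [stain_matrix].
#' @return Numeric array `H x W x 3` on the 0--255 scale.
#' @export
render_brightfield <- function(concentration_maps, stain_matrix) {
  maps <- if (inherits(concentration_maps, "concentration_maps"))
    concentration_maps$maps else concentration_maps
  stopifnot(inherits(stain_matrix, "stain_matrix"),
            is.list(maps), length(maps) >= 1L)
  M <- unclass(stain_matrix)[names(maps), , drop = FALSE]
  d <- dim(maps[[1]])
  out <- array(0, c(d, 3L))
  od_total <- matrix(0, d[1], d[2])
  for (k in 1:3) {
    od <- matrix(0, d[1], d[2])
    for (s in seq_along(maps)) {
      cm <- maps[[s]]
      if (any(cm < 0)) stop("negative concentration")
      od <- od + cm * M[s, k]
    }
    out[, , k] <- pmin(255, 255 * 10^(-od))
  }
  out
}

#' Generate a paired synthetic fluorescence + brightfield slide
#'
#' Samples the ground truth ([sample_truth()]) and renders the fluorescence
#' channels (nuclei + panel markers, Gaussian blobs over autofluorescence
#' background), the stain concentration maps, and the Beer-Lambert
#' brightfield image at `bf_resolution` under the planted transform. 8-bit
#' quantization and additive Gaussian noise are applied after rendering.
#' Identical config and seed give bit-identical outputs.
#'
#' @param config a [slide_sim_config()].
#' @param keep_concentrations keep the noise-free stain concentration maps in
#'   the returned truth (memory-heavy for large slides; default `FALSE`).
#' @param output_dir when given, every fluorescence channel is written to
#'   `<output_dir>/<channel>.tif` as soon as it is rendered and then freed
#'   (the brightfield image and ground truth files are written as well), so
#'   gigapixel slides never hold all channels in memory. The returned `fl`
#'   element is then a named vector of file paths (directly usable by
#'   [run_panel()]) and `bf` the brightfield path.
#' @return List of class `synthetic_slide` with elements `fl` (a
#'   [multiplex_slide] of the fluorescence channels at `fl_resolution`), `bf`
#'   (RGB array, 0--255, at `bf_resolution`), and `truth` (a
#'   `ground_truth_slide`); with `output_dir`, `fl` and `bf` are file paths
#'   and the class is `synthetic_slide_files`.
#' @export
generate_slide <- function(config, keep_concentrations = FALSE,
                           output_dir = NULL) {
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  generate_slide_impl(config, keep_concentrations, output_dir)
}

## chunked noise + 8-bit quantization to integer storage (bounded transients)
noise_quantize_int <- function(ch, noise_sd, chunk_cols = 1024L) {
  nr <- nrow(ch); nc <- ncol(ch)
  out <- matrix(0L, nr, nc)
  for (j0 in seq.int(1L, nc, by = chunk_cols)) {
    j1 <- min(j0 + chunk_cols - 1L, nc)
    blk <- ch[, j0:j1, drop = FALSE]
    if (noise_sd > 0)
      blk <- blk + rnorm(length(blk), 0, noise_sd)
    out[, j0:j1] <- pmin(pmax(as.integer(round(blk)), 0L), 255L)
  }
  out
}

generate_slide_impl <- function(config, keep_concentrations = FALSE,
                                output_dir = NULL) {
  stopifnot(inherits(config, "slide_sim_config"))
  with_rng_seed(config$rng_seed, {
    truth <- sample_truth_impl(config)
    cells <- truth$cells
    u <- config$fl_resolution
    H <- config$image_height_px; W <- config$image_width_px
    bf_dim <- floor(c(H, W) * u / config$bf_resolution)
    t_phys <- planted_phys_transform(config)

    ## fluorescence channel list by scheme
    fl_markers <- if (config$scheme == "immune")
      c("nuclei", "FoxP3", "CD4", "CD45", "CD8")
    else c("nuclei", "CK18", "CK8", "CK5p63", "PanEpi")
    chrom_markers <- if (config$scheme == "immune")
      c(green = "PanEpi", red = "Ki67") else c(green = "AR", red = "AMACR")

    if (nrow(cells)) {
      pos_um <- as.matrix(cells[, c("row_um", "col_um")])
      fl_um <- apply_affine(t_phys, pos_um)
      fl_px <- fl_um / u - 0.5
      bf_px <- pos_um / config$bf_resolution - 0.5
      sig_fl <- cells$radius_px / 2
      sig_bf <- sig_fl * u / config$bf_resolution
    }

    cache <- new.env(parent = emptyenv())
    channels <- list()
    fp <- function(m) {
      f <- config$marker_footprint
      if (!is.null(f) && m %in% names(f)) f[[m]] else 1
    }
    for (m in fl_markers) {
      ch <- matrix(config$autofluorescence_level, H, W)
      if (nrow(cells)) {
        peaks <- cells[[m]]
        keep <- peaks > config$autofluorescence_level / 4
        ch <- paint_blobs(ch, fl_px[keep, 1], fl_px[keep, 2],
                          fp(m) * sig_fl[keep], peaks[keep], cache)
      }
      ch <- noise_quantize_int(ch, config$noise_sd)
      if (is.null(output_dir)) {
        channels[[m]] <- ch
      } else {
        path <- file.path(output_dir, paste0(m, ".tif"))
        write_channel_tiff(ch, path)
        channels[[m]] <- path
      }
      rm(ch)
    }

    ## concentration maps: haematoxylin from all nuclei, chromogens from
    ## their marker-positive cells; concentration = blob peak / 255
    cache_bf <- new.env(parent = emptyenv())
    conc <- list()
    stains <- rownames(config$stain_matrix)
    conc[[stains[1]]] <- matrix(0, bf_dim[1], bf_dim[2])
    if (nrow(cells))
      conc[[stains[1]]] <- paint_blobs(conc[[stains[1]]], bf_px[, 1], bf_px[, 2],
                                       sig_bf, cells$nuclei / 255, cache_bf)
    for (k in c("green", "red")) {
      m <- chrom_markers[[k]]
      cm <- matrix(0, bf_dim[1], bf_dim[2])
      if (nrow(cells)) {
        peaks <- cells[[m]] / 255
        keep <- peaks > 0.02
        cm <- paint_blobs(cm, bf_px[keep, 1], bf_px[keep, 2],
                          fp(m) * sig_bf[keep], peaks[keep], cache_bf)
      }
      conc[[k]] <- cm
    }
    names(conc) <- stains[seq_along(conc)]

    bf <- render_brightfield(conc, config$stain_matrix)
    if (!keep_concentrations) rm(conc)
    bf_int <- array(0L, dim(bf))
    for (k in 1:3)
      bf_int[, , k] <- noise_quantize_int(bf[, , k], config$noise_sd)
    rm(bf)
    if (keep_concentrations) truth$concentration_maps <- conc

    if (is.null(output_dir)) {
      structure(list(fl = multiplex_slide(channels, u), bf = bf_int,
                     truth = truth),
                class = "synthetic_slide")
    } else {
      bf_path <- file.path(output_dir, "brightfield.tif")
      write_rgb_tiff(bf_int, bf_path)
      rm(bf_int)
      write_truth_bundle(truth, output_dir)
      structure(list(fl = unlist(channels), bf = bf_path, truth = truth,
                     fl_resolution = u,
                     bf_resolution = config$bf_resolution),
                class = "synthetic_slide_files")
    }
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> fl %d x %d @ %.2f um/px (%s); bf %d x %d @ %.2f um/px\n",
              nrow(x$fl$channels[[1]]), ncol(x$fl$channels[[1]]),
              x$fl$resolution, paste(names(x$fl$channels), collapse = ", "),
              nrow(x$bf), ncol(x$bf), x$truth$config$bf_resolution))
  print(x$truth)
  invisible(x)
}

#' Simulate a registration test pair
#'
#' Renders the same random blob field in a reference frame and in a moving
#' frame related by a planted similarity transform (rotation about the image
#' centre, uniform scale, translation), with additive noise -- a light-weight
#' fixture for exercising the keypoint registration chain in isolation.
#'
#' @param n_blobs number of blobs.
#' @param shape image shape `(rows, cols)` px.
#' @param rotation_deg,scale,translation_px planted similarity parameters
#'   (moving to reference, about the reference image centre).
#' @param blob_sigma range of blob Gaussian sigmas, px.
#' @param noise_sd additive Gaussian noise, gray levels.
#' @param resolution nominal resolution attached to both images.
#' @param seed RNG seed.
#' @return List with `reference`, `moving` ([channel_image]s) and
#'   `transform` (planted [affine_transform] moving -> reference).
#' @export
simulate_registration_pair <- function(n_blobs = 150L, shape = c(512L, 512L),
                                       rotation_deg = 5, scale = 1.0,
                                       translation_px = c(8.3, -5.7),
                                       blob_sigma = c(2.5, 4),
                                       noise_sd = 2, resolution = 1,
                                       seed = 1L) {
  with_rng_seed(seed, {
    th <- rotation_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    ctr <- (shape - 1) / 2
    A <- scale * R
    tf <- affine_transform(A, ctr + translation_px - as.vector(A %*% ctr))
    margin <- 10 * max(blob_sigma) + max(abs(translation_px)) +
      max(shape) * abs(th) + 4
    pos_ref <- cbind(runif(n_blobs, margin, shape[1] - 1 - margin),
                     runif(n_blobs, margin, shape[2] - 1 - margin))
    pos_mov <- apply_affine(invert_affine(tf), pos_ref)
    sig <- runif(n_blobs, blob_sigma[1], blob_sigma[2])
    peak <- runif(n_blobs, 120, 220)
    cache <- new.env(parent = emptyenv())
    ref <- paint_blobs(matrix(5, shape[1], shape[2]),
                       pos_ref[, 1], pos_ref[, 2], sig, peak, cache)
    mov <- paint_blobs(matrix(5, shape[1], shape[2]),
                       pos_mov[, 1], pos_mov[, 2], sig / scale, peak, cache)
    if (noise_sd > 0) {
      ref <- ref + matrix(rnorm(prod(shape), 0, noise_sd), shape[1], shape[2])
      mov <- mov + matrix(rnorm(prod(shape), 0, noise_sd), shape[1], shape[2])
    }
    list(reference = channel_image(quantize8(ref), resolution, "reference"),
         moving = channel_image(quantize8(mov), resolution, "moving"),
         transform = tf)
  })
}

#' Write a synthetic slide bundle to disk
#'
#' One 8-bit TIFF per fluorescence channel (file name = channel name), the
#' brightfield image as RGB TIFF, ground-truth cells as CSV, glands as a
#' GeoJSON-style polygon list, and the planted transform + stain matrix as
#' JSON.
#'
#' @param slide a `synthetic_slide` from [generate_slide()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "synthetic_slide"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(slide$fl$channels))
    write_channel_tiff(slide$fl$channels[[m]],
                       file.path(dir, paste0(m, ".tif")))
  write_rgb_tiff(slide$bf, file.path(dir, "brightfield.tif"))
  write_truth_bundle(slide$truth, dir)
  invisible(dir)
}

## ground-truth files of a slide bundle (cells CSV, glands GeoJSON-style
## polygons, planted transform + stain matrix JSON)
write_truth_bundle <- function(truth, dir) {
  utils::write.csv(truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  g <- truth$glands
  phi <- seq(0, 2 * pi, length.out = 65L)[-65L]
  feats <- lapply(seq_len(nrow(g)), function(i) {
    lr <- g$a_um[i] * cos(phi); lc <- g$b_um[i] * sin(phi)
    list(gland_id = g$gland_id[i], malignant = g$malignant[i],
         polygon_um = cbind(g$row_um[i] + lr * cos(g$theta[i]) - lc * sin(g$theta[i]),
                            g$col_um[i] + lr * sin(g$theta[i]) + lc * cos(g$theta[i])))
  })
  jsonlite::write_json(feats, file.path(dir, "truth_glands.json"), digits = NA)
  write_transform_json(truth$transform, file.path(dir, "truth_transform.json"))
  jsonlite::write_json(list(stain_matrix = unclass(truth$stain_matrix),
                            stains = rownames(truth$stain_matrix)),
                       file.path(dir, "stain_matrix.json"), digits = NA)
  invisible(dir)
}
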