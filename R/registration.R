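## Multimodal registration of the brightfield haematoxylin channel (reference)
## with the fluorescence nuclear channel (moving image).
##
## Both modalities image the same nuclei, so registration runs on blob
## features: a scale-normalized determinant-of-Hessian blob detector in the
## SURF family, upright SURF-style gradient descriptors, Lowe-ratio + mutual
## nearest-neighbour matching, and a random-sample-consensus affine fit
## refined by least squares on the consensus set.

## ---- affine transforms ------------------------------------------------------

#' 2D affine transform between pixel grids
#'
#' Maps moving-image pixel coordinates to reference-image pixel coordinates:
#' `x_ref = A %*% x_mov + t`, with coordinates `(row, col)`, 0-based, at
#' pixel centres.
#'
#' @param A 2 x 2 non-singular linear part.
#' @param t length-2 translation (pixels).
#' @param target_resolution optional micrometres per pixel of the target grid.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(2), t = c(0, 0), target_resolution = NULL) {
  A <- matrix(as.numeric(A), 2, 2)
  t <- as.numeric(t)
  stopifnot(length(t) == 2L, all(is.finite(A)), all(is.finite(t)))
  if (abs(det(A)) < 1e-12) stop("affine linear part is singular")
  structure(list(A = A, t = t, target_resolution = target_resolution),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> x_ref = A x_mov + t\n")
  cat(sprintf("  A = [%8.5f %8.5f; %8.5f %8.5f]   t = (%.3f, %.3f)\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2]))
  rot <- atan2(x$A[2, 1], x$A[1, 1]) * 180 / pi
  cat(sprintf("  ~rotation %.4f deg, ~scale %.5f", rot, sqrt(abs(det(x$A)))))
  if (!is.null(x$target_resolution))
    cat(sprintf(", target %.3g um/px", x$target_resolution))
  cat("\n")
  invisible(x)
}

#' Apply, invert and compose affine transforms
#'
#' @param tf,f,g [affine_transform] objects (`compose_affine(f, g)` applies
#'   `g` first).
#' @param points n x 2 matrix of `(row, col)` coordinates.
#' @return Transformed points / the inverse / the composition.
#' @export
apply_affine <- function(tf, points) {
  points <- matrix(as.numeric(points), ncol = 2L)
  sweep(points %*% t(tf$A), 2L, tf$t, "+")
}

#' @rdname apply_affine
#' @export
invert_affine <- function(tf) {
  Ai <- solve(tf$A)
  affine_transform(Ai, -as.vector(Ai %*% tf$t), tf$target_resolution)
}

#' @rdname apply_affine
#' @export
compose_affine <- function(f, g) {
  affine_transform(f$A %*% g$A, as.vector(f$A %*% g$t) + f$t,
                   f$target_resolution)
}

#' Pixel-grid rescaling as an affine transform
#'
#' Maps 0-based pixel-centre coordinates of a grid at `from_res` um/px onto
#' the coordinates of the same physical frame sampled at `to_res` um/px:
#' `x_to = (from/to) * x_from + from/(2 to) - 1/2`.
#'
#' @param from_res,to_res resolutions in micrometres per pixel.
#' @return An [affine_transform].
#' @export
scale_transform <- function(from_res, to_res) {
  s <- from_res / to_res
  affine_transform(diag(2) * s, rep(s / 2 - 0.5, 2), to_res)
}

#' Serialize an affine transform to JSON
#'
#' Written as a 3 x 3 homogeneous matrix plus the target resolution.
#' @param tf an [affine_transform].
#' @param path file path.
#' @export
write_transform_json <- function(tf, path) {
  H <- rbind(cbind(tf$A, tf$t), c(0, 0, 1))
  jsonlite::write_json(list(matrix = H,
                            target_resolution = tf$target_resolution),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(unlist(o$matrix), 3, 3)
  affine_transform(H[1:2, 1:2], H[1:2, 3], o$target_resolution)
}

## ---- raster resampling ------------------------------------------------------

## bilinear sampling of matrix m at 0-based continuous (r, c); coordinates up
## to 0.5 px outside the grid are clamped, anything farther gets `fill`
bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- r > -0.5 & r < nr - 0.5 & c > -0.5 & c < nc - 0.5
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + 1L + c0 * nr
  v <- (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i00 + 1L] +
    (1 - fr) * fc * m[i00 + nr] + fr * fc * m[i00 + nr + 1L]
  v[!ok] <- fill
  v
}

#' Warp an image through an affine transform
#'
#' Resamples `image` onto an output grid of `out_dim` pixels by inverse
#' mapping with bilinear interpolation; positions mapping outside the input
#' are zero-filled.
#'
#' @param image [channel_image] or numeric matrix.
#' @param tf [affine_transform] mapping input pixel coordinates to output
#'   pixel coordinates.
#' @param out_dim integer `(rows, cols)` of the output.
#' @param chunk_rows rows processed per block (memory bound).
#' @param out_mode `"double"` for a numeric result, `"int8"` to quantize each
#'   chunk to the 8-bit grid and store the result as an integer matrix
#'   (halves the memory of whole-slide warps).
#' @return Numeric (or integer, `out_mode = "int8"`) matrix
#'   `out_dim[1] x out_dim[2]`.
#' @export
warp_affine <- function(image, tf, out_dim, chunk_rows = 512L,
                        out_mode = c("double", "int8")) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_pixel_matrix(image)
  out_mode <- match.arg(out_mode)
  inv <- invert_affine(tf)
  nr <- as.integer(out_dim[1]); nc <- as.integer(out_dim[2])
  out <- if (out_mode == "int8") matrix(0L, nr, nc) else matrix(0, nr, nc)
  cols0 <- seq_len(nc) - 1
  for (start in seq.int(1L, nr, by = chunk_rows)) {
    end <- min(start + chunk_rows - 1L, nr)
    rows0 <- seq.int(start, end) - 1
    nb <- length(rows0)
    rg <- rep(rows0, times = nc)
    cg <- rep(cols0, each = nb)
    sr <- inv$A[1, 1] * rg + inv$A[1, 2] * cg + inv$t[1]
    sc <- inv$A[2, 1] * rg + inv$A[2, 2] * cg + inv$t[2]
    v <- bilinear_sample(px, sr, sc)
    if (out_mode == "int8") v <- pmin(pmax(as.integer(round(v)), 0L), 255L)
    out[start:end, ] <- v
  }
  out
}

#' Resample a channel to a new resolution
#'
#' Integer downscale factors use exact area averaging; other factors use
#' bilinear interpolation, preceded by a Gaussian anti-alias blur when
#' downscaling.
#'
#' @param image a [channel_image].
#' @param to_res target resolution, micrometres per pixel.
#' @return A [channel_image] at `to_res`.
#' @export
resample_channel <- function(image, to_res) {
  stopifnot(inherits(image, "channel_image"))
  from_res <- image$resolution
  k <- to_res / from_res
  if (abs(k - 1) < 1e-9) return(image)
  if (abs(k - round(k)) < 1e-9 && k > 1) {
    px <- block_mean(image$pixels, as.integer(round(k)))
  } else {
    px <- image$pixels
    if (k > 1) px <- gauss_blur(px, 0.5 * k)
    out_dim <- c(max(1L, floor(nrow(px) / k)), max(1L, floor(ncol(px) / k)))
    px <- warp_affine(px, scale_transform(from_res, to_res), out_dim)
  }
  channel_image(pmin(pmax(px, 0), 255), to_res, image$channel_name)
}

## ---- keypoint detection and description ------------------------------------

## shifted second differences of a smoothed image (interior; borders zero)
hessian_components <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  Lxx <- matrix(0, nr, nc); Lyy <- Lxx; Lxy <- Lxx
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  Lxx[i, j] <- s[i - 1, j] - 2 * s[i, j] + s[i + 1, j]
  Lyy[i, j] <- s[i, j - 1] - 2 * s[i, j] + s[i, j + 1]
  Lxy[i, j] <- (s[i + 1, j + 1] + s[i - 1, j - 1] -
                  s[i + 1, j - 1] - s[i - 1, j + 1]) / 4
  list(Lxx = Lxx, Lyy = Lyy, Lxy = Lxy)
}

## central-difference gradients of a matrix (borders zero)
gradient_maps <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  dr <- matrix(0, nr, nc); dc <- matrix(0, nr, nc)
  dr[2:(nr - 1), ] <- (s[3:nr, ] - s[1:(nr - 2), ]) / 2
  dc[, 2:(nc - 1)] <- (s[, 3:nc] - s[, 1:(nc - 2)]) / 2
  list(dr = dr, dc = dc)
}

#' Detect blob keypoints and compute local descriptors
#'
#' Scale-normalized determinant-of-Hessian blob detection over a fixed scale
#' ladder, 3D (space x scale) non-maximum suppression, quadratic sub-pixel
#' localisation, and an upright SURF-style 64-dimensional descriptor (4 x 4
#' cells of Gaussian-weighted gradient sums `(sum dr, sum dc, sum |dr|,
#' sum |dc|)`, L2-normalized). Deterministic for a fixed input.
#'
#' @param image [channel_image] or numeric matrix (8-bit scale).
#' @param scales Gaussian scale ladder in pixels.
#' @param response_rel relative response threshold (fraction of the maximum
#'   response over the whole scale stack).
#' @param response_abs absolute response floor (uniform images yield no
#'   keypoints).
#' @param max_keypoints keep at most this many strongest keypoints.
#' @return List with `keypoints` (data.frame `row`, `col`, `scale`,
#'   `orientation`, `response`; 0-based sub-pixel positions) and
#'   `descriptors` (n x 64 matrix).
#' @export
detect_and_describe <- function(image,
                                scales = 1.6 * 1.33^(0:5),
                                response_rel = 0.02,
                                response_abs = 1e-7,
                                max_keypoints = 2000L) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_pixel_matrix(image)
  if (min(dim(px)) < 16L) stop("image smaller than the minimum filter size")
  img <- px / 255
  ns <- length(scales)
  smoothed <- vector("list", ns)
  resp <- vector("list", ns)
  for (k in seq_len(ns)) {
    s <- gauss_blur(img, scales[k])
    smoothed[[k]] <- s
    h <- hessian_components(s)
    resp[[k]] <- scales[k]^4 * (h$Lxx * h$Lyy - h$Lxy^2)
  }
  gmax <- max(vapply(resp, max, 0))
  thr <- max(response_abs, response_rel * gmax)
  kp <- list(); desc <- list()
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_len(ns)) {
    R <- resp[[k]]
    margin <- max(3L, ceiling(scales[k]))
    cand <- which(R > thr)
    if (!length(cand)) next
    rr <- (cand - 1L) %% nr; cc <- (cand - 1L) %/% nr
    keep <- rr >= margin & rr < nr - margin & cc >= margin & cc < nc - margin
    cand <- cand[keep]
    if (!length(cand)) next
    v <- R[cand]
    ## 8-neighbour spatial maximum at this scale
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      v_ok <- v >= R[cand + dr + dc * nr]
      cand <- cand[v_ok]; v <- v[v_ok]
      if (!length(cand)) break
    }
    if (!length(cand)) next
    ## scale neighbours (same pixel)
    if (k > 1) { ok <- v >= resp[[k - 1]][cand]; cand <- cand[ok]; v <- v[ok] }
    if (k < ns && length(cand)) {
      ok <- v >= resp[[k + 1]][cand]; cand <- cand[ok]; v <- v[ok]
    }
    if (!length(cand)) next
    rr <- (cand - 1L) %% nr; cc <- (cand - 1L) %/% nr
    ## quadratic sub-pixel refinement along rows and columns
    d_r <- 0.5 * (R[cand - 1L] - R[cand + 1L]) /
      (R[cand - 1L] - 2 * v + R[cand + 1L])
    d_c <- 0.5 * (R[cand - nr] - R[cand + nr]) /
      (R[cand - nr] - 2 * v + R[cand + nr])
    d_r[!is.finite(d_r) | abs(d_r) > 0.6] <- 0
    d_c[!is.finite(d_c) | abs(d_c) > 0.6] <- 0
    kp[[k]] <- data.frame(row = rr + d_r, col = cc + d_c,
                          scale = scales[k], response = v)
  }
  resp <- NULL                      # response stack is no longer needed
  kp <- do.call(rbind, kp)
  if (is.null(kp) || nrow(kp) == 0L) {
    return(list(keypoints = data.frame(row = numeric(), col = numeric(),
                                       scale = numeric(),
                                       orientation = numeric(),
                                       response = numeric()),
                descriptors = matrix(0, 0L, 64L)))
  }
  ## strongest first; cap the count (deterministic order: response, then pos)
  o <- order(-kp$response, kp$row, kp$col)
  kp <- kp[o, , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]
  rownames(kp) <- NULL
  des <- describe_keypoints(smoothed, scales, kp)
  kp$orientation <- des$orientation
  kp <- kp[des$valid, , drop = FALSE]
  rownames(kp) <- NULL
  list(keypoints = kp[, c("row", "col", "scale", "orientation", "response")],
       descriptors = des$descriptors[des$valid, , drop = FALSE])
}

## upright SURF-style descriptors; support window 16 sigma (16 x 16 samples at
## sigma spacing, 4 x 4 cells); keypoints whose support exits the image are
## marked invalid
describe_keypoints <- function(smoothed, scales, kp) {
  n <- nrow(kp)
  grid1 <- seq(-7.5, 7.5, length.out = 16)
  offs <- expand.grid(gr = grid1, gc = grid1)      # 256 sample offsets (sigma units)
  w <- exp(-(offs$gr^2 + offs$gc^2) / (2 * 6^2))
  cell <- interaction((offs$gr + 8) %/% 4, (offs$gc + 8) %/% 4, drop = TRUE)
  cell_idx <- split(seq_len(256L), cell)
  desc <- matrix(0, n, 64L)
  orientation <- numeric(n)
  valid <- rep(TRUE, n)
  dims <- dim(smoothed[[which(!vapply(smoothed, is.null, logical(1)))[1]]])
  nr <- dims[1]; nc <- dims[2]
  for (k in seq_along(scales)) {
    sel <- which(abs(kp$scale - scales[k]) < 1e-9)
    if (!length(sel)) { smoothed[k] <- list(NULL); next }
    g <- gradient_maps(smoothed[[k]])
    smoothed[k] <- list(NULL)
    sig <- scales[k]
    half <- 8 * sig + 1
    bad <- kp$row[sel] < half | kp$row[sel] > nr - 1 - half |
      kp$col[sel] < half | kp$col[sel] > nc - 1 - half
    valid[sel[bad]] <- FALSE
    m <- length(sel)
    rs <- outer(kp$row[sel], offs$gr * sig, "+")   # m x 256
    cs <- outer(kp$col[sel], offs$gc * sig, "+")
    dr <- matrix(bilinear_sample(g$dr, as.vector(rs), as.vector(cs)), m, 256L)
    dc <- matrix(bilinear_sample(g$dc, as.vector(rs), as.vector(cs)), m, 256L)
    dr <- sweep(dr, 2L, w, "*")
    dc <- sweep(dc, 2L, w, "*")
    orientation[sel] <- atan2(rowSums(dr), rowSums(dc))
    feats <- vector("list", length(cell_idx))
    for (ci in seq_along(cell_idx)) {
      idx <- cell_idx[[ci]]
      feats[[ci]] <- cbind(rowSums(dr[, idx, drop = FALSE]),
                           rowSums(dc[, idx, drop = FALSE]),
                           rowSums(abs(dr[, idx, drop = FALSE])),
                           rowSums(abs(dc[, idx, drop = FALSE])))
    }
    d <- do.call(cbind, feats)
    nrm <- sqrt(rowSums(d^2))
    nrm[nrm == 0] <- 1
    desc[sel, ] <- d / nrm
  }
  list(descriptors = desc, orientation = orientation, valid = valid)
}

#' Match keypoint descriptors between two images
#'
#' Nearest-neighbour matching with a Lowe distance-ratio test and a mutual
#' (cross-check) constraint; no keypoint is matched twice.
#'
#' @param a,b results of [detect_and_describe()] (or bare descriptor
#'   matrices with equal column count).
#' @param ratio Lowe ratio-test threshold (default 0.75).
#' @return Two-column integer matrix of index pairs `(index_a, index_b)`.
#' @export
match_descriptors <- function(a, b, ratio = 0.75) {
  da <- if (is.list(a)) a$descriptors else a
  db <- if (is.list(b)) b$descriptors else b
  if (ncol(da) != ncol(db) && nrow(da) && nrow(db))
    stop("descriptor lengths differ")
  empty <- matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("index_a", "index_b")))
  if (nrow(da) == 0L || nrow(db) == 0L) return(empty)
  d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * tcrossprod(da, db)
  d2[d2 < 0] <- 0
  nn_b <- max.col(-d2, ties.method = "first")          # best b for each a
  best <- d2[cbind(seq_len(nrow(da)), nn_b)]
  d2_second <- d2
  d2_second[cbind(seq_len(nrow(da)), nn_b)] <- Inf
  second <- apply(d2_second, 1L, min)
  pass <- sqrt(best) <= ratio * sqrt(second)
  nn_a <- max.col(-t(d2), ties.method = "first")       # best a for each b
  mutual <- nn_a[nn_b] == seq_len(nrow(da))
  keep <- which(pass & mutual)
  out <- cbind(index_a = keep, index_b = nn_b[keep])
  out[!duplicated(out[, 2L]), , drop = FALSE]
}

## ---- robust affine estimation ----------------------------------------------

## closed-form least-squares affine a -> b
ls_affine_fit <- function(pa, pb) {
  X <- cbind(pa, 1)
  beta <- qr.solve(X, pb)                               # 3 x 2
  affine_transform(t(beta[1:2, ]), beta[3, ])
}

#' Estimate an affine transform from matched keypoints
#'
#' Random-sample consensus over matched position pairs (3-point minimal
#' samples, fixed iteration count and internal seed, inlier threshold in
#' pixels) followed by a least-squares refit on the consensus set.
#'
#' @param matches two-column index matrix from [match_descriptors()].
#' @param positions_a,positions_b n x 2 `(row, col)` keypoint positions of the
#'   moving (`a`) and reference (`b`) image.
#' @param inlier_threshold RANSAC inlier distance in pixels (default 2).
#' @param iterations RANSAC iterations (default 2000).
#' @param seed seed of the private RANSAC random stream.
#' @return An [affine_transform] mapping `a` positions onto `b` positions,
#'   with attribute `fit`: list with `n_matches`, `n_inliers`, `rms`
#'   (root-mean-square inlier residual, pixels) and `inliers` (indices into
#'   `matches`). Fewer than 3 consensus inliers raise an error of class
#'   `wsicyto_registration_error`.
#' @export
estimate_affine <- function(matches, positions_a, positions_b,
                            inlier_threshold = 2, iterations = 2000L,
                            seed = 0L) {
  pa <- matrix(as.numeric(positions_a), ncol = 2L)[matches[, 1L], , drop = FALSE]
  pb <- matrix(as.numeric(positions_b), ncol = 2L)[matches[, 2L], , drop = FALSE]
  n <- nrow(pa)
  if (n < 3L)
    stop(structure(class = c("wsicyto_registration_error", "error", "condition"),
                   list(message = "fewer than 3 matches", call = sys.call())))
  best_inl <- integer(); best_rms <- Inf
  with_rng_seed(seed, {
    for (it in seq_len(iterations)) {
      tri <- sample.int(n, 3L)
      X <- cbind(pa[tri, , drop = FALSE], 1)
      if (abs(det(X)) < 1e-6) next
      beta <- tryCatch(solve(X, pb[tri, , drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(beta)) next
      pred <- cbind(pa, 1) %*% beta
      res2 <- rowSums((pred - pb)^2)
      inl <- which(res2 < inlier_threshold^2)
      rms <- if (length(inl)) sqrt(mean(res2[inl])) else Inf
      if (length(inl) > length(best_inl) ||
          (length(inl) == length(best_inl) && rms < best_rms)) {
        best_inl <- inl; best_rms <- rms
      }
    }
  })
  if (length(best_inl) < 3L)
    stop(structure(class = c("wsicyto_registration_error", "error", "condition"),
                   list(message = sprintf(
                     "consensus too small (%d inliers of %d matches)",
                     length(best_inl), n), call = sys.call())))
  ## least-squares refit on the consensus set
  tf <- ls_affine_fit(pa[best_inl, , drop = FALSE], pb[best_inl, , drop = FALSE])
  res <- apply_affine(tf, pa[best_inl, , drop = FALSE]) - pb[best_inl, , drop = FALSE]
  attr(tf, "fit") <- list(n_matches = n, n_inliers = length(best_inl),
                          rms = sqrt(mean(rowSums(res^2))), inliers = best_inl)
  tf
}

## ---- full modality registration --------------------------------------------

#' Register the fluorescence nuclear channel to the brightfield haematoxylin
#'
#' The haematoxylin channel is the reference. Both inputs are downscaled to
#' working resolutions (defaults 1.76 and 2.56 um/px), blob keypoints are
#' detected, described and matched, and a robust affine transform is
#' estimated at the working scale, then composed with the grid rescalings so
#' it maps native moving pixels onto the common output grid (default 0.64
#' um/px, the reference frame). Both nuclear images are returned resampled
#' onto that grid.
#'
#' @param haematoxylin reference [channel_image] (brightfield haematoxylin).
#' @param nuclear_fl moving [channel_image] (fluorescence nuclear channel).
#' @param ref_work_res,mov_work_res working resolutions, um/px.
#' @param out_res output grid resolution, um/px (default 0.64).
#' @param resample_reference also resample the reference image onto the
#'   output grid (set `FALSE` to save memory when only the transform and the
#'   registered moving image are needed).
#' @param ... passed to [estimate_affine()] (`inlier_threshold`,
#'   `iterations`, `seed`).
#' @return List with `transform` (moving native px to output-grid px),
#'   `transform_working`, `reference`, `moving` (both [channel_image]s on the
#'   output grid), `out_dim`, and `diagnostics` (keypoint/match/inlier counts
#'   and RMS residual at working resolution).
#' @export
register_modalities <- function(haematoxylin, nuclear_fl,
                                ref_work_res = 1.76, mov_work_res = 2.56,
                                out_res = 0.64, resample_reference = TRUE,
                                ...) {
  stopifnot(inherits(haematoxylin, "channel_image"),
            inherits(nuclear_fl, "channel_image"))
  ref_w <- resample_channel(haematoxylin, ref_work_res)
  mov_w <- resample_channel(nuclear_fl, mov_work_res)
  kr <- detect_and_describe(ref_w)
  km <- detect_and_describe(mov_w)
  matches <- match_descriptors(km, kr)
  tf_w <- tryCatch(
    estimate_affine(matches, as.matrix(km$keypoints[, c("row", "col")]),
                    as.matrix(kr$keypoints[, c("row", "col")]), ...),
    error = function(e) {
      if (inherits(e, "wsicyto_registration_error"))
        stop(structure(class = class(e), list(message = sprintf(
          "registration failed: %s [keypoints ref=%d mov=%d, matches=%d]",
          conditionMessage(e), nrow(kr$keypoints), nrow(km$keypoints),
          nrow(matches)), call = sys.call())))
      stop(e)
    })
  fit <- attr(tf_w, "fit")
  ## compose: moving native -> working -> reference working -> output grid
  tf_out <- compose_affine(scale_transform(ref_work_res, out_res),
                           compose_affine(tf_w,
                                          scale_transform(nuclear_fl$resolution,
                                                          mov_work_res)))
  tf_out$target_resolution <- out_res
  out_dim <- c(ceiling(nrow(haematoxylin$pixels) * haematoxylin$resolution / out_res),
               ceiling(ncol(haematoxylin$pixels) * haematoxylin$resolution / out_res))
  n_kp_ref <- nrow(kr$keypoints)
  n_kp_mov <- nrow(km$keypoints)
  rm(kr, km, matches, ref_w, mov_w); gc(FALSE)
  ref_out <- if (resample_reference)
    warp_affine(haematoxylin, scale_transform(haematoxylin$resolution, out_res),
                out_dim, out_mode = "int8")
  mov_out <- warp_affine(nuclear_fl, tf_out, out_dim, out_mode = "int8")
  list(transform = tf_out,
       transform_working = tf_w,
       reference = if (resample_reference)
         channel_image(ref_out, out_res, haematoxylin$channel_name),
       moving = channel_image(mov_out, out_res, nuclear_fl$channel_name),
       out_dim = out_dim,
       diagnostics = list(n_keypoints_ref = n_kp_ref,
                          n_keypoints_mov = n_kp_mov,
                          n_matches = fit$n_matches,
                          n_inliers = fit$n_inliers,
                          rms_working_px = fit$rms))
}
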