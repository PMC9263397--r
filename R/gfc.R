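#' Threshold a gray-matter probability volume into an analysis mask
#'
#' A voxel enters the mask iff its gray-matter probability strictly exceeds
#' `threshold` (default 0.2, the usual probabilistic-segmentation cutoff).
#'
#' @param prob_volume 3D array of probabilities in `[0, 1]`.
#' @param threshold Strict lower probability bound.
#' @param affine Optional 4x4 voxel-to-world transform carried with the mask.
#' @return A `gm_mask`: list with `mask` (logical 3D array), `affine`,
#'   `threshold`, and `n_voxels`.
#' @export
make_gm_mask <- function(prob_volume, threshold = 0.2, affine = diag(4)) {
  if (any(prob_volume < 0 | prob_volume > 1, na.rm = TRUE))
    stop_input("probabilities must lie in [0, 1]")
  m <- prob_volume > threshold
  m[is.na(m)] <- FALSE
  if (!any(m)) stop_input("gray-matter mask is empty at threshold %g", threshold)
  structure(list(mask = m, affine = affine, threshold = threshold,
                 n_voxels = sum(m)), class = "gm_mask")
}

#' @export
print.gm_mask <- function(x, ...) {
  cat(sprintf("<gm_mask> %d voxels (probability > %g)\n", x$n_voxels,
              x$threshold))
  invisible(x)
}

# clip |r| away from 1 so atanh stays finite
clip_r <- function(r, eps = 1e-7) pmin(pmax(r, -1 + eps), 1 - eps)

# standardize t x N matrix columns to mean 0, unit L2 norm; flags
# zero-variance columns
unit_columns <- function(m) {
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  nrm <- sqrt(colSums(mc^2))
  ok <- nrm > 0
  mc[, ok] <- sweep(mc[, ok, drop = FALSE], 2, nrm[ok], "/")
  list(m = mc, ok = ok)
}

#' Voxel-wise global functional connectivity map
#'
#' For every gray-matter voxel i, computes
#' `GFC(i) = mean_{j != i} atanh(r_ij)` — the mean Fisher-z-transformed
#' Pearson correlation between voxel i's time series and every other mask
#' voxel's series.  The Fisher transform is applied before averaging, so the
#' pairwise correlations are evaluated in blocks of `chunk_size` mask voxels
#' against all N voxels; peak additional memory is O(N * chunk_size), never
#' O(N^2).  Correlations are clipped to `|r| <= 1 - 1e-7` before `atanh`.
#'
#' Zero-variance voxels cannot carry a correlation: they are excluded from
#' every other voxel's mean (numerator and denominator) and their own GFC is
#' returned as `NaN` with a warning.
#'
#' @param bold A preprocessed [bold4d] with at least 3 volumes.
#' @param mask A `gm_mask` on the same grid with >= 2 voxels.
#' @param chunk_size Number of mask voxels per block (result is independent
#'   of this choice to ~1e-10).
#' @return A `gfc_map`: list with `z` (3D array, `NA` outside mask, `NaN` for
#'   undefined voxels), `affine`, `mask`, `n_undefined`.
#' @export
gfc_map <- function(bold, mask, chunk_size = 2048L) {
  check_mask_grid(bold, mask)
  if (n_volumes(bold) < 3L) stop_input("GFC needs at least 3 volumes")
  vox <- which(mask$mask, arr.ind = TRUE)
  if (nrow(vox) < 2L) stop_input("mask must contain at least 2 voxels")
  m <- bold_matrix(bold, vox)                 # t x N
  u <- unit_columns(m)
  N <- ncol(m)
  n_ok <- sum(u$ok)
  if (n_ok < 2L) stop_input("fewer than 2 voxels with temporal variance")
  zsum <- numeric(N)
  X <- u$m[, u$ok, drop = FALSE]
  ok_idx <- which(u$ok)
  for (start in seq(1L, n_ok, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n_ok)
    r <- crossprod(X[, idx, drop = FALSE], X)  # |idx| x n_ok
    z <- atanh(clip_r(r))
    # remove self-correlation terms before averaging
    z[cbind(seq_along(idx), idx)] <- 0
    zsum[ok_idx[idx]] <- rowSums(z)
  }
  gfc <- rep(NaN, N)
  gfc[u$ok] <- zsum[u$ok] / (n_ok - 1)
  if (any(!u$ok))
    warn(sprintf("%d mask voxel(s) had zero temporal variance; GFC set to NaN",
                 sum(!u$ok)))
  out <- array(NA_real_, dim = dim(bold$data)[1:3])
  out[vox] <- gfc
  structure(list(z = out, affine = bold$affine, mask = mask,
                 n_undefined = sum(!u$ok)), class = "gfc_map")
}

#' Brute-force GFC reference implementation
#'
#' Materializes the full N x N Pearson correlation matrix, Fisher-transforms
#' it, and averages each row excluding the diagonal.  Used as the oracle the
#' chunked [gfc_map()] is tested against; only suitable for small masks.
#'
#' @inheritParams gfc_map
#' @return A `gfc_map`.
#' @export
gfc_map_bruteforce <- function(bold, mask) {
  check_mask_grid(bold, mask)
  vox <- which(mask$mask, arr.ind = TRUE)
  if (nrow(vox) < 2L) stop_input("mask must contain at least 2 voxels")
  m <- bold_matrix(bold, vox)
  sds <- apply(m, 2, sd)
  ok <- sds > 0
  N <- ncol(m)
  gfc <- rep(NaN, N)
  if (sum(ok) >= 2L) {
    R <- cor(m[, ok, drop = FALSE])
    Z <- atanh(clip_r(R))
    diag(Z) <- 0
    gfc[ok] <- rowSums(Z) / (sum(ok) - 1)
  }
  if (any(!ok))
    warn(sprintf("%d mask voxel(s) had zero temporal variance; GFC set to NaN",
                 sum(!ok)))
  out <- array(NA_real_, dim = dim(bold$data)[1:3])
  out[vox] <- gfc
  structure(list(z = out, affine = bold$affine, mask = mask,
                 n_undefined = sum(!ok)), class = "gfc_map")
}

check_mask_grid <- function(bold, mask) {
  if (!inherits(mask, "gm_mask")) stop_input("`mask` must be a gm_mask")
  if (!identical(dim(mask$mask), dim(bold$data)[1:3]))
    stop_input("mask grid %s does not match image grid %s",
               paste(dim(mask$mask), collapse = "x"),
               paste(dim(bold$data)[1:3], collapse = "x"))
  invisible(TRUE)
}

#' @export
print.gfc_map <- function(x, ...) {
  v <- x$z[x$mask$mask]
  cat(sprintf("<gfc_map> %d mask voxels, mean z = %.4f, sd = %.4f, %d undefined\n",
              x$mask$n_voxels, mean(v, na.rm = TRUE), sd(v, na.rm = TRUE),
              x$n_undefined))
  invisible(x)
}

#' Mean GFC over a cluster of voxels
#'
#' The per-subject scalar feature used by the correlation and classification
#' stages: the arithmetic mean of the Fisher-z GFC map over a cluster's
#' voxels.
#'
#' @param map A `gfc_map`.
#' @param cluster_voxels Integer matrix (rows = voxels, columns = i, j, k;
#'   1-based) inside the map's mask.
#' @return Scalar mean z.
#' @export
extract_cluster_mean_z <- function(map, cluster_voxels) {
  cluster_voxels <- matrix(as.integer(cluster_voxels), ncol = 3)
  if (nrow(cluster_voxels) == 0L) stop_input("cluster is empty")
  vals <- map$z[cluster_voxels]
  if (any(is.na(vals) & !is.nan(vals)))
    stop_input("cluster contains voxels outside the mask")
  mean(vals)
}

#' Tidy a GFC map into a voxel table
#'
#' @param x A `gfc_map`.
#' @param ... Unused.
#' @return Tibble with voxel indices (1-based), world mm coordinates, and z.
#' @method tidy gfc_map
#' @export
tidy.gfc_map <- function(x, ...) {
  vox <- which(x$mask$mask, arr.ind = TRUE)
  w <- voxel_to_world(vox - 1L, x$affine)
  zv <- x$z[vox]
  tibble(i = vox[, 1], j = vox[, 2], k = vox[, 3],
         x = w[, 1], y = w[, 2], z_mm = w[, 3], z = zv)
}

#' @method glance gfc_map
#' @export
glance.gfc_map <- function(x, ...) {
  v <- x$z[x$mask$mask]
  tibble(n_mask = x$mask$n_voxels, n_undefined = x$n_undefined,
         mean_z = mean(v, na.rm = TRUE), sd_z = sd(v, na.rm = TRUE))
}

#' Plot an axial slice of a GFC map
#'
#' @param object A `gfc_map`.
#' @param slice Axial (k) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gfc_map
#' @export
autoplot.gfc_map <- function(object, slice = NULL, ...) {
  d <- dim(object$z)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$z <- object$z[cbind(df$i, df$j, slice)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("GFC map, axial slice k = %d", slice),
                  fill = "Fisher z") +
    ggplot2::theme_minimal()
}
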