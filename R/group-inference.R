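#' Stack per-subject GFC maps into a voxel-by-subject matrix
#'
#' @param maps List of `gfc_map` objects on a common mask.
#' @return List with `Y` (n_subjects x n_mask matrix), `vox` (mask voxel
#'   index matrix), `mask`, `affine`.
#' @export
stack_gfc_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  mask <- maps[[1]]$mask
  vox <- which(mask$mask, arr.ind = TRUE)
  Y <- do.call(rbind, lapply(maps, function(m) {
    if (!identical(dim(m$z), dim(mask$mask)))
      stop_input("GFC maps are on different grids")
    m$z[vox]
  }))
  list(Y = Y, vox = vox, mask = mask, affine = maps[[1]]$affine)
}

#' Build the group-analysis design matrix
#'
#' Intercept, two group dummies (reference = last level), and the covariates
#' age, gender (0/1), education years, and mean FD.  Continuous covariates
#' are mean-centred for numerical stability (this does not change F or t
#' statistics for the group terms).
#'
#' @param subjects Tibble with columns `group`, `age`, `gender`,
#'   `education_years`, `mean_fd` (ordered as the map stack).
#' @param covariates Character vector of covariate columns to include.
#' @param reference Group level used as the dummy-coding reference.
#' @return List with `X` (n x k design), `group_cols` (indices of the group
#'   dummies), `groups` (factor).
#' @export
group_design <- function(subjects,
                         covariates = c("age", "gender", "education_years",
                                        "mean_fd"),
                         reference = "HC") {
  g <- factor(subjects$group)
  if (reference %in% levels(g)) g <- stats::relevel(g, ref = reference)
  lv <- levels(g)
  X <- matrix(1, nrow(subjects), 1, dimnames = list(NULL, "intercept"))
  for (l in lv[-1]) X <- cbind(X, as.numeric(g == l))
  colnames(X)[-1] <- paste0("group_", lv[-1])
  group_cols <- seq_len(length(lv) - 1L) + 1L
  for (cv in covariates) {
    v <- subjects[[cv]]
    if (is.null(v)) stop_input("covariate '%s' missing from subject table", cv)
    if (cv == "gender") v <- as.numeric(v %in% c("male", "M", 1, "1"))
    v <- as.numeric(v)
    v <- v - mean(v)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop_input("group design is rank deficient")
  list(X = X, group_cols = group_cols, groups = g)
}

# residual sums of squares of Y (n x V) on design X, per column
rss_columns <- function(Y, X) {
  r <- qr.resid(qr(X), Y)
  colSums(r^2)
}

#' Mass-univariate ANCOVA over GFC maps
#'
#' Per voxel, compares the full linear model (intercept + group dummies +
#' covariates) against the reduced model without the group dummies:
#' `F = ((RSS_reduced - RSS_full) / (g - 1)) / (RSS_full / (n - k))`,
#' df = (g - 1, n - k), p from the F distribution.  Voxels with (near-)zero
#' full-model residual variance are flagged and get `NA` statistics rather
#' than spurious F values.
#'
#' @param stack Output of [stack_gfc_maps()] (or a compatible list).
#' @param design Output of [group_design()].
#' @return A `stat_map`: per-voxel `stat`, `p`, `df` pair, statistic type
#'   `"F"`, plus grid bookkeeping.  Undefined (`NaN`) map voxels propagate
#'   to flagged voxels.
#' @export
fit_voxel_ancova <- function(stack, design) {
  X <- design$X
  n <- nrow(X)
  k <- ncol(X)
  if (length(unique(design$groups)) < 2L) stop_input("need >= 2 groups")
  if (n <= k) stop_input("n = %d subjects but k = %d design columns", n, k)
  X0 <- X[, -design$group_cols, drop = FALSE]
  df1 <- length(design$group_cols)
  df2 <- n - k
  Y <- stack$Y
  defined <- apply(is.finite(Y), 2, all)
  stat <- p <- rep(NA_real_, ncol(Y))
  if (any(defined)) {
    Yd <- Y[, defined, drop = FALSE]
    rss1 <- rss_columns(Yd, X)
    rss0 <- rss_columns(Yd, X0)
    scale <- colSums(Yd^2) + 1e-300
    good <- rss1 / scale > 1e-12      # flag voxels with ~zero residual variance
    Fv <- ((rss0 - rss1) / df1) / (rss1 / df2)
    Fv[!good] <- NA_real_
    stat[defined] <- Fv
    p[defined] <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  new_stat_map(stat, p, c(df1, df2), "F", stack)
}

#' Covariate-adjusted post hoc t contrast between two groups
#'
#' Restricts the stack and subject table to two groups and tests the group
#' indicator's coefficient in the covariate-adjusted model; df = n - k,
#' two-sided p.  Positive t means the first group of `pair` exceeds the
#' second.
#'
#' @param stack Output of [stack_gfc_maps()] for all subjects.
#' @param subjects Subject tibble aligned with the stack rows.
#' @param pair Character vector of two group labels, `c(a, b)`; the contrast
#'   is a minus b.
#' @param covariates As in [group_design()].
#' @return A `stat_map` with statistic type `"t"`.
#' @export
posthoc_t <- function(stack, subjects, pair,
                      covariates = c("age", "gender", "education_years",
                                     "mean_fd")) {
  stopifnot(length(pair) == 2L)
  sel <- subjects$group %in% pair
  if (sum(subjects$group == pair[1]) < 2L || sum(subjects$group == pair[2]) < 2L)
    stop_input("both groups need >= 2 subjects")
  sub <- subjects[sel, , drop = FALSE]
  d <- group_design(sub, covariates = covariates, reference = pair[2])
  X <- d$X
  j <- d$group_cols[1]
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop_input("n = %d subjects but k = %d design columns", n, k)
  Y <- stack$Y[sel, , drop = FALSE]
  defined <- apply(is.finite(Y), 2, all)
  stat <- p <- rep(NA_real_, ncol(Y))
  if (any(defined)) {
    Yd <- Y[, defined, drop = FALSE]
    XtXi <- chol2inv(chol(crossprod(X)))
    beta <- XtXi %*% crossprod(X, Yd)
    rss <- colSums((Yd - X %*% beta)^2)
    scale <- colSums(Yd^2) + 1e-300
    good <- rss / scale > 1e-12
    se <- sqrt(rss / (n - k) * XtXi[j, j])
    tv <- beta[j, ] / se
    tv[!good] <- NA_real_
    stat[defined] <- tv
    p[defined] <- 2 * pt(abs(tv), n - k, lower.tail = FALSE)
  }
  new_stat_map(stat, p, c(NA_real_, n - k), "t", stack,
               contrast = paste(pair, collapse = " vs "))
}

new_stat_map <- function(stat, p, df, type, stack, contrast = NULL) {
  structure(list(stat = stat, p = p, df = df, type = type,
                 vox = stack$vox, mask = stack$mask, affine = stack$affine,
                 contrast = contrast),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s statistic over %d voxels, df = (%s)%s\n",
              x$type, length(x$stat),
              paste(format(x$df), collapse = ", "),
              if (is.null(x$contrast)) "" else paste0(", ", x$contrast)))
  invisible(x)
}

#' Tidy a statistic map into a voxel table
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return Tibble with voxel indices, world coordinates, statistic and p.
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  w <- voxel_to_world(x$vox - 1L, x$affine)
  stat <- x$stat
  p <- x$p
  tibble(i = x$vox[, 1], j = x$vox[, 2], k = x$vox[, 3],
         x = w[, 1], y = w[, 2], z_mm = w[, 3],
         stat = stat, p = p)
}

#' @method glance stat_map
#' @export
glance.stat_map <- function(x, ...) {
  tibble(type = x$type, n_voxels = length(x$stat),
         n_defined = sum(is.finite(x$stat)),
         max_abs_stat = max(abs(x$stat), na.rm = TRUE),
         min_p = min(x$p, na.rm = TRUE))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure: with ordered p-values p_(1) <= ... <= p_(m), reject all
#' hypotheses with p <= p_(i*) where i* is the largest i such that
#' p_(i) <= i q / m.  `NA` p-values are never rejected and do not count
#' toward m.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical vector, same length as `p`),
#'   `threshold` (the adaptive p cutoff p_(i*), or 0 if none rejected),
#'   `p_adjusted` (BH-adjusted p-values), `n_rejected`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0L)
    return(list(reject = logical(0), threshold = 0,
                p_adjusted = numeric(0), n_rejected = 0L))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_input("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  reject <- !is.na(adj) & adj <= q
  thr <- if (any(reject)) max(p[reject]) else 0
  list(reject = reject, threshold = thr, p_adjusted = adj,
       n_rejected = sum(reject))
}

# 26/18/6-connectivity neighbourhood offsets
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[ord == 1, , drop = FALSE],
         "18" = off[ord <= 2, , drop = FALSE],
         "26" = off,
         stop_config("connectivity must be 6, 18 or 26"))
}

# connected components of a set of voxels (integer index matrix) via the
# voxel-adjacency graph
connected_components <- function(vox, grid, connectivity = 26) {
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  lin <- vox[, 1] + (vox[, 2] - 1L) * grid[1] + (vox[, 3] - 1L) * grid[1] * grid[2]
  pos <- integer(prod(grid))
  pos[lin] <- seq_len(n)
  off <- connectivity_offsets(connectivity)
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(vox, 2, -off[r, ])
    inside <- nb[, 1] >= 1 & nb[, 1] <= grid[1] &
              nb[, 2] >= 1 & nb[, 2] <= grid[2] &
              nb[, 3] >= 1 & nb[, 3] <= grid[3]
    if (!any(inside)) next
    nl <- nb[inside, 1] + (nb[inside, 2] - 1L) * grid[1] +
          (nb[inside, 3] - 1L) * grid[1] * grid[2]
    tgt <- pos[nl]
    src <- which(inside)[tgt > 0]
    tgt <- tgt[tgt > 0]
    if (length(src)) edges <- rbind(edges, cbind(src, tgt))
  }
  if (is.null(edges)) return(seq_len(n))  # no adjacencies: all singletons
  edges <- unique(edges[edges[, 1] < edges[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Applies the FDR mask (computed here at level `q` over the map's defined
#' voxels), splits surviving voxels by sign for t maps, labels connected
#' components under the chosen 3D connectivity, and reports each cluster's
#' size, peak statistic and peak world (MNI mm) coordinate.  Ties in
#' |statistic| break toward the lowest linear voxel index.  Clusters are
#' sorted by size, descending.
#'
#' @param stat_map A `stat_map`.
#' @param q FDR level.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_extent Minimum cluster size in voxels (default 1).
#' @param reject Optional logical vector overriding the FDR mask (e.g. to
#'   restrict post hoc maps to ANCOVA-surviving voxels).
#' @return A tibble: `cluster`, `sign`, `n_voxels`, `peak_x`, `peak_y`,
#'   `peak_z`, `peak_stat`, and a `voxels` list-column of index matrices.
#' @export
label_clusters <- function(stat_map, q = 0.05, connectivity = 26,
                           min_extent = 1L, reject = NULL) {
  if (is.null(reject)) reject <- fdr_bh(stat_map$p, q)$reject
  empty <- tibble(cluster = integer(), sign = character(),
                  n_voxels = integer(), peak_x = numeric(),
                  peak_y = numeric(), peak_z = numeric(),
                  peak_stat = numeric(), voxels = list())
  if (!any(reject)) return(empty)
  grid <- dim(stat_map$mask$mask)
  res <- list()
  signs <- if (stat_map$type == "t") c("positive", "negative") else "positive"
  for (sg in signs) {
    sel <- reject & is.finite(stat_map$stat) &
      (if (stat_map$type != "t") TRUE
       else if (sg == "positive") stat_map$stat > 0 else stat_map$stat < 0)
    if (!any(sel)) next
    vox <- stat_map$vox[sel, , drop = FALSE]
    st <- stat_map$stat[sel]
    memb <- connected_components(vox, grid, connectivity)
    for (cc in unique(memb)) {
      m <- memb == cc
      if (sum(m) < min_extent) next
      cv <- vox[m, , drop = FALSE]
      cs <- st[m]
      lin <- cv[, 1] + (cv[, 2] - 1L) * grid[1] +
             (cv[, 3] - 1L) * grid[1] * grid[2]
      ord <- order(-abs(cs), lin)
      peak <- cv[ord[1], , drop = FALSE]
      w <- voxel_to_world(peak - 1L, stat_map$affine)
      res[[length(res) + 1L]] <- tibble(
        sign = sg, n_voxels = sum(m),
        peak_x = w[1], peak_y = w[2], peak_z = w[3],
        peak_stat = cs[ord[1]], voxels = list(cv))
    }
  }
  if (!length(res)) return(empty)
  out <- dplyr::bind_rows(res)
  out <- dplyr::arrange(out, dplyr::desc(.data$n_voxels))
  dplyr::mutate(out, cluster = dplyr::row_number(), .before = 1)
}

#' Write a cluster table as TSV
#'
#' Mirrors the conventional cluster-report layout: location label (blank for
#' synthetic data), peak x/y/z in mm, voxel count, statistic value.
#'
#' @param clusters Tibble from [label_clusters()].
#' @param path Output path.
#' @param contrast Optional contrast label column value.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path, contrast = NA_character_) {
  out <- dplyr::transmute(clusters,
    contrast = contrast, location = "", peak_x = .data$peak_x,
    peak_y = .data$peak_y, peak_z = .data$peak_z,
    n_voxels = .data$n_voxels, statistic = .data$peak_stat)
  write_tsv(out, path)
}

#' Plot a statistic-map slice with its FDR mask
#'
#' @param object A `stat_map`.
#' @param q FDR level for the overlay.
#' @param slice Axial slice; defaults to the slice containing the peak
#'   |statistic|.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, q = 0.05, slice = NULL, ...) {
  rej <- fdr_bh(object$p, q)$reject
  if (is.null(slice)) {
    pk <- which.max(abs(object$stat))
    slice <- if (length(pk)) object$vox[pk, 3] else 1L
  }
  sel <- object$vox[, 3] == slice
  df <- tibble(i = object$vox[sel, 1], j = object$vox[sel, 2],
               stat = object$stat[sel], reject = rej[sel])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$stat)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$reject),
                        ggplot2::aes(x = .data$i, y = .data$j),
                        inherit.aes = FALSE, shape = 0, size = 2) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s map, slice k = %d (squares: FDR q = %g)",
                                  object$type, slice, q),
                  fill = object$type) +
    ggplot2::theme_minimal()
}
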