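#' Run one seeded cohort through the inference chain and score it
#'
#' Generates a synthetic cohort, preprocesses every subject, computes GFC
#' maps, fits the three-group ANCOVA with the standard covariates, applies
#' BH-FDR, extracts clusters, and scores the run against the planted ground
#' truth: whether any voxel survived FDR, and, per planted region, whether a
#' surviving cluster overlaps it and the post hoc t peak inside the region
#' has the planted sign.  This is the unit of the null-calibration and
#' planted-effect-recovery checks.
#'
#' @param seed Seed for this cohort.
#' @param delta Planted effect magnitude; `0` plants nothing (null cohort).
#' @param n_per_group Subjects per group.
#' @param n_volumes Acquired volumes per subject.
#' @param q FDR level.
#' @return One-row tibble: `seed`, `n_subjects`, `mask_voxels`,
#'   `n_fdr_voxels`, `any_discovery`, `n_regions`, `n_recovered`
#'   (regions overlapped by a surviving cluster with matching post hoc t
#'   sign), `all_recovered`.
#' @export
evaluate_cohort_inference <- function(seed, delta = 0.5,
                                      n_per_group = c(15L, 15L, 15L),
                                      n_volumes = 250L, q = 0.05) {
  cfg <- cohort_config(
    n_per_group = n_per_group, n_volumes = n_volumes,
    effect_regions = if (delta == 0) NULL else default_effect_regions(delta),
    seed = seed)
  b <- generate_cohort(cfg)
  n <- nrow(b$subjects)
  mask <- make_gm_mask(b$template$gm_prob, 0.2, affine = cfg$affine)
  prep <- lapply(seq_len(n), function(i)
    preprocess_bold(b$images[[i]], b$motion[[i]], b$template))
  maps <- lapply(prep, function(p) gfc_map(p$bold, mask))
  sub <- b$subjects
  sub$mean_fd <- vapply(prep, function(p) p$fd$mean_fd, numeric(1))
  stack <- stack_gfc_maps(maps)
  fmap <- fit_voxel_ancova(stack, group_design(sub))
  fdr <- fdr_bh(fmap$p, q)
  cl <- label_clusters(fmap, q = q)
  grid <- cfg$grid_shape
  lin <- function(v) v[, 1] + (v[, 2] - 1L) * grid[1] +
    (v[, 3] - 1L) * grid[1] * grid[2]
  n_regions <- nrow(b$truth)
  n_recovered <- 0L
  if (n_regions > 0 && nrow(cl) > 0) {
    tmap <- posthoc_t(stack, sub, c("S1", "HC"))
    tlin <- lin(tmap$vox)
    for (i in seq_len(n_regions)) {
      lt <- lin(b$truth$voxels[[i]])
      overlapped <- any(vapply(cl$voxels, function(cv)
        length(intersect(lt, lin(cv))) > 0, logical(1)))
      tin <- tmap$stat[match(lt, tlin)]
      peak_sign <- sign(tin[which.max(abs(tin))])
      if (overlapped && peak_sign == sign(b$truth$delta[i]))
        n_recovered <- n_recovered + 1L
    }
  }
  tibble(seed = seed, n_subjects = n, mask_voxels = mask$n_voxels,
         n_fdr_voxels = fdr$n_rejected, any_discovery = fdr$n_rejected > 0,
         n_regions = n_regions, n_recovered = n_recovered,
         all_recovered = n_regions > 0 && n_recovered == n_regions)
}
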