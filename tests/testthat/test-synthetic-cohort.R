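test_that("cohort bookkeeping matches the configured group sizes", {
  cfg <- cohort_config(n_per_group = c(35L, 17L, 28L), grid_shape = c(8, 8, 8),
                       n_volumes = 20L, seed = 2)
  b <- generate_cohort(cfg)
  expect_equal(nrow(b$subjects), 80L)
  expect_length(b$images, 80L)
  expect_length(b$motion, 80L)
  expect_equal(as.vector(table(factor(b$subjects$group,
                                      c("S1", "S0", "HC")))),
               c(35L, 17L, 28L))
  expect_true(all(vapply(b$images, function(im) dim(im$data)[4] == 20L,
                         logical(1))))
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_cohort_config(seed = 11, n_per_group = c(3L, 3L, 3L),
                             n_volumes = 24L)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$subjects, b2$subjects)
  expect_identical(substream_seed(11, "bold", 1), substream_seed(11, "bold", 1))
  expect_identical(gfcmap:::content_hash(b1$images[[1]]$data),
                   gfcmap:::content_hash(b2$images[[1]]$data))
  expect_identical(gfcmap:::content_hash(b1$motion),
                   gfcmap:::content_hash(b2$motion))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_group = c(5, 5)), class = "gfcmap_config_error")
  expect_error(cohort_config(grid_shape = c(4, 12, 12)), class = "gfcmap_config_error")
  expect_error(cohort_config(n_volumes = 10), class = "gfcmap_config_error")
  expect_error(cohort_config(noise_sd = 0, network_loading = 0),
               class = "gfcmap_config_error")
})

test_that("clinical scores track the configured moments and respect ranges", {
  cfg <- cohort_config(seed = 3)
  set.seed(substream_seed(3, "mc-clinical"))
  draws <- purrr::map_dfr(1:10000, function(i)
    generate_clinical_scores("S1", cfg, id = "x"))
  expect_lt(abs(mean(draws$hrsd17) - 22.69), 0.15)
  expect_lt(abs(mean(draws$anx_som) - 7.31), 0.15)
  expect_true(all(draws$hrsd17 >= 0 & draws$hrsd17 <= 52))
  expect_true(all(draws$anx_som >= 0 & draws$anx_som <= 18))
  expect_true(all(draws$weight_loss >= 0 & draws$weight_loss <= 2))
  expect_true(all(draws$sleep >= 0 & draws$sleep <= 6))
  expect_true(all(draws$hrsd17 == round(draws$hrsd17)))

  set.seed(substream_seed(3, "mc-clinical-hc"))
  hc <- purrr::map_dfr(1:200, function(i)
    generate_clinical_scores("HC", cfg, id = "x"))
  expect_true(all(hc$weight_loss == 0))
  expect_true(all(hc$cognitive == 0))
  expect_true(all(is.na(hc$illness_duration_months)))
})

test_that("motion traces honour step size, spikes and determinism", {
  cfg0 <- cohort_config(motion_step_sd_trans = 0, motion_step_sd_rot = 0,
                        n_volumes = 30L, seed = 4)
  m0 <- generate_motion(cfg0)
  expect_true(all(m0$params == 0))
  expect_equal(compute_fd(m0)$fd, rep(0, 30))

  cfg_sp <- cohort_config(n_volumes = 60L, seed = 4,
                          motion_spikes = tibble::tibble(frame = 50L,
                                                         magnitude_mm = 3))
  set.seed(substream_seed(4, "motion", 1))
  msp <- generate_motion(cfg_sp)
  expect_false(motion_qc(msp)$pass)
  expect_true(50L %in% motion_qc(msp)$offending_frames)

  cfg <- cohort_config(n_volumes = 40L, seed = 9)
  set.seed(substream_seed(9, "motion", 1)); a <- generate_motion(cfg)
  set.seed(substream_seed(9, "motion", 1)); b <- generate_motion(cfg)
  expect_identical(a$params, b$params)
})

test_that("tissue template yields a connected, bounded gray-matter blob", {
  tpl <- generate_tissue_template(c(12, 12, 12))
  expect_true(all(tpl$gm_prob >= 0 & tpl$gm_prob <= 1))
  mask <- make_gm_mask(tpl$gm_prob, 0.2)
  expect_gte(mask$n_voxels, 0.3 * 12^3)
  vox <- which(mask$mask, arr.ind = TRUE)
  memb <- gfcmap:::connected_components(vox, c(12L, 12L, 12L), 26)
  expect_equal(length(unique(memb)), 1L)
  expect_error(make_gm_mask(tpl$gm_prob, 1.0), class = "gfcmap_input_error")
})

test_that("planted positive effect raises region GFC in the target group", {
  cfg <- cohort_config(
    n_per_group = c(15L, 1L, 15L),  # S0 minimal, unused in this check
    n_volumes = 120L,
    effect_regions = tibble::tibble(region = "r1", group = "S1", delta = 0.4,
                                    centre_offset = list(c(3L, 0L, 2L)),
                                    radius = 2.2),
    seed = 21)
  b <- generate_cohort(cfg)
  mask <- make_gm_mask(b$template$gm_prob, 0.2)
  idx <- b$subjects$group %in% c("S1", "HC")
  region <- b$truth$voxels[[1]]
  means <- vapply(which(idx), function(i) {
    p <- preprocess_bold(b$images[[i]], b$motion[[i]], b$template)
    extract_cluster_mean_z(gfc_map(p$bold, mask), region)
  }, numeric(1))
  grp <- b$subjects$group[idx]
  tt <- stats::t.test(means[grp == "S1"], means[grp == "HC"],
                      var.equal = TRUE)
  expect_gt(unname(tt$statistic), 0)
})

test_that("noise-only images give near-zero mean GFC", {
  cfg <- cohort_config(n_per_group = c(1L, 1L, 1L), n_volumes = 120L,
                       network_loading = 0, effect_regions = NULL, seed = 31)
  b <- generate_cohort(cfg)
  mask <- make_gm_mask(b$template$gm_prob, 0.2)
  p <- preprocess_bold(b$images[[1]], b$motion[[1]], b$template)
  g <- gfc_map(p$bold, mask)
  v <- g$z[mask$mask]
  # mean over N voxels of z ~ atanh(r), r centred on 0; SE of the map mean
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v)), 3 * se + 0.01)
})

test_that("doubling the latent amplitude leaves noise-free GFC unchanged", {
  base <- list(n_per_group = c(1L, 1L, 1L), n_volumes = 40L,
               grid_shape = c(8L, 8L, 8L), noise_sd = 0,
               subject_loading_sd = 0, effect_regions = NULL, seed = 41)
  b1 <- generate_cohort(do.call(cohort_config, c(base, network_loading = 0.4)))
  b2 <- generate_cohort(do.call(cohort_config, c(base, network_loading = 0.8)))
  # restrict to cortical voxels (p > 0.5): these share the one network latent,
  # so with zero noise their series differ only by the per-voxel scale
  mask <- make_gm_mask(b1$template$gm_prob, 0.5)
  g1 <- gfc_map(detrend_linear(b1$images[[1]]), mask)
  g2 <- gfc_map(detrend_linear(b2$images[[1]]), mask)
  expect_lt(max(abs(g1$z - g2$z), na.rm = TRUE), 1e-6)
})
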