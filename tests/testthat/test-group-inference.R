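test_that("covariate-free voxel ANCOVA reduces to one-way ANOVA", {
  st <- null_stack(n = 30, v = 40, seed = 1)
  d <- group_design(st$subjects, covariates = character(0))
  fmap <- fit_voxel_ancova(st, d)
  for (v in seq_len(10)) {
    ref <- oneway_anova(st$Y[, v], st$subjects$group)
    expect_equal(fmap$stat[v], ref$F, tolerance = 1e-8)
    expect_equal(fmap$p[v], ref$p, tolerance = 1e-8)
  }
  expect_equal(fmap$df, c(2, 27))

  # agreement with lm-based model comparison, covariates included
  d2 <- group_design(st$subjects)
  fmap2 <- fit_voxel_ancova(st, d2)
  for (v in c(1, 17, 33)) {
    df <- data.frame(y = st$Y[, v], st$subjects)
    full <- stats::lm(y ~ group + age + I(gender == "male") +
                        education_years + mean_fd, df)
    red <- stats::lm(y ~ age + I(gender == "male") + education_years +
                       mean_fd, df)
    ref <- stats::anova(red, full)
    expect_equal(fmap2$stat[v], ref$F[2], tolerance = 1e-8)
    expect_equal(fmap2$p[v], ref$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("null-data rejection rate is calibrated at the nominal level", {
  st <- null_stack(n = 45, v = 200, seed = 2)
  set.seed(3)
  st$subjects$group <- sample(st$subjects$group)
  fmap <- fit_voxel_ancova(st, group_design(st$subjects))
  rate <- mean(fmap$p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2] + 0.01)
})

test_that("degenerate constant voxels are flagged, not given spurious F", {
  st <- null_stack(n = 30, v = 10, seed = 4)
  st$Y[, 3] <- 1  # identical value for every subject
  fmap <- fit_voxel_ancova(st, group_design(st$subjects))
  expect_true(is.na(fmap$stat[3]))
  expect_true(all(is.finite(fmap$stat[-3])))
})

test_that("covariate-free post hoc t reduces to the pooled two-sample t", {
  st <- null_stack(n = 30, v = 20, seed = 5)
  tmap <- posthoc_t(st, st$subjects, c("S1", "HC"), covariates = character(0))
  sel1 <- st$subjects$group == "S1"
  sel2 <- st$subjects$group == "HC"
  for (v in 1:5) {
    ref <- stats::t.test(st$Y[sel1, v], st$Y[sel2, v], var.equal = TRUE)
    expect_equal(tmap$stat[v], unname(ref$statistic), tolerance = 1e-8)
    expect_equal(tmap$p[v], ref$p.value, tolerance = 1e-8)
  }
  swapped <- posthoc_t(st, st$subjects, c("HC", "S1"),
                       covariates = character(0))
  expect_equal(swapped$stat, -tmap$stat, tolerance = 1e-12)
})

test_that("BH step-up matches hand-computed decisions", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(r$reject, rep(TRUE, 4))
  expect_equal(r$n_rejected, 4L)

  expect_equal(fdr_bh(rep(1, 10))$n_rejected, 0L)
  expect_true(fdr_bh(0.049, q = 0.05)$reject)
  expect_false(fdr_bh(0.051, q = 0.05)$reject)

  # independent step-up oracle on random vectors
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    q <- 0.05
    o <- order(p)
    ok <- which(p[o] <= seq_along(p) * q / length(p))
    hand <- logical(length(p))
    if (length(ok)) hand[o[seq_len(max(ok))]] <- TRUE
    expect_equal(fdr_bh(p, q)$reject, hand)
  }

  # monotone in q, invariant to order
  set.seed(7)
  p <- runif(40)^2
  r1 <- fdr_bh(p, 0.01)$reject
  r5 <- fdr_bh(p, 0.05)$reject
  expect_true(all(!r1 | r5))
  perm <- sample(40)
  expect_equal(fdr_bh(p[perm], 0.05)$reject, fdr_bh(p, 0.05)$reject[perm])
})

test_that("cluster labelling respects connectivity, peaks and affines", {
  # single surviving voxel
  prob <- array(1, dim = c(5, 5, 5))
  mask <- make_gm_mask(prob, 0.2)
  vox <- which(mask$mask, arr.ind = TRUE)
  stat <- rep(0, nrow(vox)); p <- rep(1, nrow(vox))
  pick <- which(vox[, 1] == 2 & vox[, 2] == 3 & vox[, 3] == 4)
  stat[pick] <- 5; p[pick] <- 1e-6
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-90, -126, -72)
  sm <- gfcmap:::new_stat_map(stat, p, c(2, 27), "F",
                              list(vox = vox, mask = mask, affine = aff))
  cl <- label_clusters(sm, q = 0.05)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_voxels, 1L)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z),
               c(-90, -126, -72) + c(1, 2, 3) * 3)

  # voxel (1,1,1) maps to the affine offset itself
  stat2 <- rep(0, nrow(vox)); p2 <- rep(1, nrow(vox))
  stat2[1] <- 4; p2[1] <- 1e-6
  sm2 <- gfcmap:::new_stat_map(stat2, p2, c(2, 27), "F",
                               list(vox = vox, mask = mask, affine = aff))
  cl2 <- label_clusters(sm2)
  expect_equal(c(cl2$peak_x, cl2$peak_y, cl2$peak_z), c(-90, -126, -72))

  # corner-sharing voxels: one cluster at 26-connectivity, two at 6
  stat3 <- rep(0, nrow(vox)); p3 <- rep(1, nrow(vox))
  a <- which(vox[, 1] == 1 & vox[, 2] == 1 & vox[, 3] == 1)
  b <- which(vox[, 1] == 2 & vox[, 2] == 2 & vox[, 3] == 2)
  stat3[c(a, b)] <- c(3, 6); p3[c(a, b)] <- 1e-6
  sm3 <- gfcmap:::new_stat_map(stat3, p3, c(2, 27), "F",
                               list(vox = vox, mask = mask, affine = diag(4)))
  expect_equal(nrow(label_clusters(sm3, connectivity = 26)), 1L)
  expect_equal(nrow(label_clusters(sm3, connectivity = 6)), 2L)
  expect_equal(label_clusters(sm3, connectivity = 26)$peak_stat, 6)

  # t maps split by sign; no member exceeds the |peak|
  stat4 <- rep(0, nrow(vox)); p4 <- rep(1, nrow(vox))
  sel <- which(vox[, 3] == 1)[1:6]
  stat4[sel] <- c(3, 4, 3.5, -2.8, -3.9, -3)
  p4[sel] <- 1e-6
  sm4 <- gfcmap:::new_stat_map(stat4, p4, c(NA, 27), "t",
                               list(vox = vox, mask = mask, affine = diag(4)))
  cl4 <- label_clusters(sm4)
  expect_setequal(cl4$sign, c("positive", "negative"))
  lin <- function(v) v[, 1] + (v[, 2] - 1) * 5 + (v[, 3] - 1) * 25
  for (i in seq_len(nrow(cl4))) {
    member_stats <- stat4[match(lin(cl4$voxels[[i]]), lin(vox))]
    expect_equal(abs(cl4$peak_stat[i]), max(abs(member_stats)))
  }

  # empty mask: empty table
  sm5 <- gfcmap:::new_stat_map(rep(0, nrow(vox)), rep(1, nrow(vox)),
                               c(2, 27), "F",
                               list(vox = vox, mask = mask, affine = diag(4)))
  expect_equal(nrow(label_clusters(sm5)), 0L)
})

test_that("planted negative effects give negative post hoc peaks", {
  res <- evaluate_cohort_inference(seed = 101, delta = 0.5,
                                   n_per_group = c(12L, 3L, 12L),
                                   n_volumes = 120L)
  expect_equal(res$n_regions, 2L)
  expect_gte(res$n_recovered, 1L)
})
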