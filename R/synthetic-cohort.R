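#' Reference per-group clinical summary moments
#'
#' The per-group mean/SD moments (and gender counts) that parameterize the
#' synthetic cohort's clinical table by default.  They describe a three-group
#' depression-imaging cohort: `S1` = depressed outpatients with
#' gastrointestinal symptoms (n = 35), `S0` = depressed outpatients without
#' GI symptoms (n = 17), `HC` = healthy controls (n = 28), with HRSD-17
#' totals and the five HRSD-17 factor scores (anxiety/somatization, weight
#' loss, cognitive disturbances, retardation, sleep disturbances).  Controls
#' have weight-loss and cognitive-disturbance factors fixed at 0.
#'
#' @return A tibble with columns `group`, `variable`, `mean`, `sd`, `n`.
#' @export
reference_group_summaries <- function() {
  g <- c("S1", "S0", "HC")
  n <- c(35L, 17L, 28L)
  row <- function(variable, m, s) {
    tibble(group = g, variable = variable, mean = m, sd = s, n = n)
  }
  dplyr::bind_rows(
    row("age",              c(30.86, 30.29, 30.14), c(6.84, 8.05, 5.00)),
    row("education_years",  c(14.51, 12.94, 14.61), c(3.28, 3.46, 2.69)),
    row("illness_duration_months", c(6.23, 6.94, NA), c(4.63, 3.98, NA)),
    row("hrsd17",           c(22.69, 20.18, 0.89), c(3.41, 2.67, 0.88)),
    row("anx_som",          c(7.31, 6.41, 0.39),  c(1.92, 1.66, 0.57)),
    row("weight_loss",      c(0.80, 0.06, 0),     c(0.83, 0.24, 0)),
    row("cognitive",        c(3.71, 3.41, 0),     c(1.78, 1.50, 0)),
    row("retardation",      c(6.40, 6.76, 0.18),  c(1.42, 1.56, 0.39)),
    row("sleep",            c(4.46, 3.53, 0.32),  c(1.42, 1.28, 0.55))
  )
}

#' Gender counts per group in the reference cohort
#'
#' Male/female counts for the three groups of the reference cohort (n = 35 /
#' 17 / 28); the generator draws gender as Bernoulli with these proportions,
#' and [characteristics_table()] tests their independence from group.
#'
#' @return Tibble with columns `group`, `male`, `female`.
#' @export
reference_gender_counts <- function() {
  tibble(group = c("S1", "S0", "HC"), male = c(13L, 6L, 14L),
         female = c(22L, 11L, 14L))
}

# valid score ranges: each HRSD-17 factor is a sum of items scored 0-4 or 0-2
clinical_ranges <- function() {
  list(age = c(18, 55), education_years = c(0, 25),
       illness_duration_months = c(1, 120),
       hrsd17 = c(0, 52), anx_som = c(0, 18), weight_loss = c(0, 2),
       cognitive = c(0, 12), retardation = c(0, 14), sleep = c(0, 6))
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a three-group
#' resting-state cohort (default 35 / 17 / 28 subjects, matching the
#' reference moments of [reference_group_summaries()]), TR = 2 s, 250
#' volumes, 3 mm isotropic voxels, and planted group-specific connectivity
#' effects.
#'
#' @param n_per_group Integer vector of length 3: subjects in groups
#'   S1, S0, HC.
#' @param grid_shape Integer vector of length 3; voxels per axis (each >= 8).
#'   The default 12^3 grid is the desk-scale stand-in for a 3 mm whole-brain
#'   grid.
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of acquired volumes (>= 20), before any discard.
#' @param affine 4x4 voxel-to-world transform; default 3 mm isotropic,
#'   centred on the grid.
#' @param effect_regions Tibble with columns `region`, `group`, `delta`:
#'   within the region's voxels, the loading of subjects in `group` on the
#'   shared network signal is scaled by `1 + delta`, raising (`delta > 0`)
#'   or lowering (`delta < 0`) that region's mean connectivity with the rest
#'   of the gray-matter mask in Fisher-z units.
#' @param noise_sd Standard deviation of iid voxel noise, arbitrary units.
#' @param network_loading Baseline loading of gray-matter voxels on the
#'   shared band-limited network signal.
#' @param subject_loading_sd Log-normal SD of the per-subject loading jitter
#'   (between-subject variability of overall connectivity strength).
#' @param motion_step_sd_trans,motion_step_sd_rot Random-walk step SDs for
#'   translations (mm) and rotations (radians).
#' @param motion_spikes Optional tibble with columns `frame`, `magnitude_mm`
#'   giving injected translation spikes (applied to every subject).
#' @param clinical_moments Tibble like [reference_group_summaries()].
#' @param seed Master seed; every random draw derives from it through
#'   [substream_seed()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(35L, 17L, 28L),
                          grid_shape = c(12L, 12L, 12L),
                          tr = 2,
                          n_volumes = 250L,
                          affine = NULL,
                          effect_regions = default_effect_regions(),
                          noise_sd = 1,
                          network_loading = 0.4,
                          subject_loading_sd = 0.1,
                          motion_step_sd_trans = 0.02,
                          motion_step_sd_rot = 4e-4,
                          motion_spikes = NULL,
                          clinical_moments = reference_group_summaries(),
                          seed = 1L) {
  if (length(n_per_group) != 3L || any(n_per_group < 1))
    stop_config("`n_per_group` must be 3 positive integers")
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop_config("`grid_shape` must be 3 integers, each >= 8")
  if (n_volumes < 20L) stop_config("`n_volumes` must be >= 20")
  if (!is.null(effect_regions) && nrow(effect_regions) > 0 &&
      !all(is.finite(effect_regions$delta)))
    stop_config("effect deltas must be finite")
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0")
  if (noise_sd == 0 && network_loading == 0)
    stop_config("zero noise with zero loadings gives degenerate signals")
  if (is.null(affine)) {
    affine <- diag(c(3, 3, 3, 1))
    affine[1:3, 4] <- -3 * (grid_shape - 1) / 2  # centre the grid at 0 mm
  }
  structure(list(
    n_per_group = as.integer(n_per_group), grid_shape = as.integer(grid_shape),
    tr = tr, n_volumes = as.integer(n_volumes), affine = affine,
    effect_regions = effect_regions, noise_sd = noise_sd,
    network_loading = network_loading, subject_loading_sd = subject_loading_sd,
    motion_step_sd_trans = motion_step_sd_trans,
    motion_step_sd_rot = motion_step_sd_rot, motion_spikes = motion_spikes,
    clinical_moments = clinical_moments, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default planted effect regions
#'
#' Two spherical regions in the gray-matter shell: one where group S1's
#' connectivity is reduced (mimicking the medial-prefrontal/posterior-midline
#' reductions seen in depression cohorts) and one where it is elevated
#' (insula/thalamus-like).
#'
#' @param delta Absolute effect size in loading-scale units.
#' @return Tibble with columns `region`, `group`, `delta`, `centre_offset`
#'   (list of length-3 integer offsets from the grid centre, voxels) and
#'   `radius` (voxels).
#' @export
default_effect_regions <- function(delta = 0.5) {
  tibble(
    region = c("reduced_a", "elevated_a"),
    group = c("S1", "S1"),
    delta = c(-delta, delta),
    centre_offset = list(c(3L, 0L, 2L), c(-3L, 1L, -2L)),
    radius = c(2.2, 2.2)
  )
}

#' Generate the tissue probability template
#'
#' Builds a contiguous "brain" blob of gray-matter probability on the given
#' grid: a sphere covering roughly 40% of the grid with probability 0.85,
#' a deep "white-matter" core at probability 0.3 (still above the usual 0.2
#' gray-matter threshold, as at tissue boundaries in probabilistic
#' segmentations), a small central "ventricle" at 0.05, and background 0.
#'
#' @param grid_shape Integer vector of length 3.
#' @return List with `gm_prob` (3D array in `[0, 1]`), logical arrays
#'   `wm_mask` and `csf_mask` (the nuisance compartments), and `brain_mask`.
#' @export
generate_tissue_template <- function(grid_shape) {
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop_config("`grid_shape` must be 3 integers, each >= 8")
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(i) (seq_len(grid_shape[i]) - ctr[i]))
  dist <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  r_brain <- min(grid_shape) * 0.46
  gm <- array(0, dim = grid_shape)
  gm[dist <= r_brain] <- 0.85
  # soft edge just inside the boundary
  edge <- dist > (r_brain - 1) & dist <= r_brain
  gm[edge] <- 0.5
  # deep compartments: the innermost voxels are "ventricle", the shell
  # around them "white matter"; rank-based so they are nonempty on any grid
  ord <- order(dist)
  csf <- array(FALSE, dim = grid_shape)
  csf[ord[1:8]] <- TRUE
  n_wm <- max(24L, sum(dist <= r_brain / 3) - 8L)
  wm <- array(FALSE, dim = grid_shape)
  wm[ord[9:(8 + n_wm)]] <- TRUE
  gm[wm] <- 0.3
  gm[csf] <- 0.05
  gm <- pmin(pmax(gm, 0), 1)
  list(gm_prob = gm, wm_mask = wm, csf_mask = csf, brain_mask = dist <= r_brain)
}

# voxel index matrix (1-based) of a spherical region; clipped to the
# gray-matter blob so planted truth is always inside the analysis mask
region_voxels <- function(grid_shape, centre_offset, radius, gm_prob,
                          threshold = 0.2) {
  ctr <- round((grid_shape + 1) / 2) + centre_offset
  idx <- which(array(TRUE, grid_shape))
  vox <- arrayInd(idx, grid_shape)
  d <- sqrt(rowSums(sweep(vox, 2, ctr)^2))
  keep <- d <= radius & gm_prob[idx] > threshold
  vox[keep, , drop = FALSE]
}

#' Generate one subject's clinical record
#'
#' Scores are drawn from truncated normal distributions with the configured
#' per-group moments, rounded to integers and clipped to each scale's valid
#' range (HRSD items are integers; factors are item sums).  Moments printed
#' as exactly 0 (controls' weight-loss and cognitive factors) are generated
#' as the constant 0.
#'
#' @param group One of `"S1"`, `"S0"`, `"HC"`.
#' @param config A [cohort_config()].
#' @param id Subject identifier.
#' @return One-row tibble with the subject's demographic and clinical fields.
#' @export
generate_clinical_scores <- function(group, config, id = "sub-001") {
  cm <- config$clinical_moments
  cm <- cm[cm$group == group, ]
  if (nrow(cm) == 0) stop_config("no clinical moments for group %s", group)
  rng <- clinical_ranges()
  draw <- function(variable) {
    r <- cm[cm$variable == variable, ]
    if (nrow(r) == 0 || is.na(r$mean)) return(NA_real_)
    if (r$sd == 0) return(r$mean)
    lim <- rng[[variable]]
    x <- rnorm(1, r$mean, r$sd)
    x <- round(x)
    min(max(x, lim[1]), lim[2])
  }
  male_p <- {
    gc <- reference_gender_counts()
    gc <- gc[gc$group == group, ]
    gc$male / (gc$male + gc$female)
  }
  tibble(
    id = id, group = group,
    age = draw("age"),
    gender = ifelse(rbinom(1, 1, male_p) == 1, "male", "female"),
    education_years = draw("education_years"),
    illness_duration_months = if (group == "HC") NA_real_ else
      draw("illness_duration_months"),
    hrsd17 = draw("hrsd17"), anx_som = draw("anx_som"),
    weight_loss = draw("weight_loss"), cognitive = draw("cognitive"),
    retardation = draw("retardation"), sleep = draw("sleep")
  )
}

#' Generate a subject's rigid-body motion trace
#'
#' A 6-parameter random walk (translations mm, rotations radians) starting at
#' zero, with optional injected translation spikes.
#'
#' @param config A [cohort_config()].
#' @return A `motion_trace`.
#' @export
generate_motion <- function(config) {
  nt <- config$n_volumes
  steps <- cbind(
    matrix(rnorm(3 * (nt - 1), 0, config$motion_step_sd_trans), nt - 1, 3),
    matrix(rnorm(3 * (nt - 1), 0, config$motion_step_sd_rot), nt - 1, 3)
  )
  params <- rbind(0, apply(steps, 2, cumsum))
  if (!is.null(config$motion_spikes)) {
    for (i in seq_len(nrow(config$motion_spikes))) {
      f <- config$motion_spikes$frame[i]
      params[f, 1] <- params[f, 1] + config$motion_spikes$magnitude_mm[i]
    }
  }
  motion_trace(params)
}

# band-limited unit-SD latent signal: white noise passed through the ideal
# band filter used by the preprocessing stage
band_limited_latent <- function(nt, tr, low = 0.01, high = 0.08) {
  x <- rnorm(nt)
  y <- ideal_bandpass_series(x, tr, low, high)
  s <- sd(y)
  if (s == 0) y else y / s
}

#' Generate one subject's 4D BOLD image
#'
#' Latent-network model: every gray-matter voxel's series is
#' `loading * shared(t) + noise`, where `shared(t)` is a band-limited
#' (0.01-0.08 Hz) unit-SD Gaussian signal.  Within a planted effect region,
#' the loading of subjects in the region's target group is scaled by
#' `1 + delta`, which raises (or lowers) that region's mean Fisher-z
#' connectivity with the rest of the mask.  White-matter and ventricle
#' compartments follow their own independent latents, and a small random
#' linear drift is added so detrending has work to do.
#'
#' @param subject One-row tibble with at least `group` (and optionally a
#'   per-subject loading jitter drawn by [generate_cohort()]).
#' @param config A [cohort_config()].
#' @param template Output of [generate_tissue_template()]; regenerated from
#'   `config` if omitted.
#' @return A [bold4d].
#' @export
generate_bold <- function(subject, config, template = NULL) {
  if (is.null(subject$group)) stop_input("subject must carry a group label")
  if (is.null(template)) template <- generate_tissue_template(config$grid_shape)
  gs <- config$grid_shape
  nt <- config$n_volumes
  nv <- prod(gs)

  loading <- array(0, dim = gs)
  loading[template$gm_prob > 0.2] <- config$network_loading
  jitter <- subject$loading_jitter %||% 1
  loading <- loading * jitter
  if (!is.null(config$effect_regions) && nrow(config$effect_regions) > 0) {
    for (i in seq_len(nrow(config$effect_regions))) {
      er <- config$effect_regions[i, ]
      if (er$group != subject$group) next
      vox <- region_voxels(gs, er$centre_offset[[1]], er$radius,
                           template$gm_prob)
      lin <- vox[, 1] + (vox[, 2] - 1L) * gs[1] + (vox[, 3] - 1L) * gs[1] * gs[2]
      loading[lin] <- loading[lin] * (1 + er$delta)
    }
  }
  if (config$noise_sd == 0 && all(loading == 0))
    stop_input("zero noise with zero loadings gives degenerate signals")

  shared <- band_limited_latent(nt, config$tr)
  wm_lat <- band_limited_latent(nt, config$tr)
  csf_lat <- band_limited_latent(nt, config$tr)

  dat <- matrix(rnorm(nv * nt, 0, config$noise_sd), nv, nt)
  lvec <- as.vector(loading)
  dat <- dat + outer(lvec, shared)
  wm_lin <- which(template$wm_mask)
  csf_lin <- which(template$csf_mask)
  dat[wm_lin, ] <- dat[wm_lin, ] + matrix(0.5 * wm_lat, length(wm_lin), nt,
                                          byrow = TRUE)
  dat[csf_lin, ] <- dat[csf_lin, ] + matrix(0.5 * csf_lat, length(csf_lin), nt,
                                            byrow = TRUE)
  # per-voxel linear drift, small relative to signal
  drift <- rnorm(nv, 0, 0.3)
  dat <- dat + outer(drift, seq_len(nt) / nt)
  bold4d(array(dat, dim = c(gs, nt)), affine = config$affine, tr = config$tr)
}

#' Generate a complete synthetic cohort
#'
#' Produces subject records, per-subject BOLD images and motion traces, the
#' tissue template, and the ground-truth map of planted effect regions.
#' Deterministic for a fixed config (every draw flows from `config$seed`
#' through per-stage, per-subject substreams).
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle`: list with `subjects` (tibble), `images` (list
#'   of [bold4d]), `motion` (list of `motion_trace`), `template`, and `truth`
#'   (tibble of planted regions with voxel index matrices and deltas).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(c("S1", "S0", "HC"), times = config$n_per_group)
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  template <- generate_tissue_template(config$grid_shape)

  subjects <- purrr::map_dfr(seq_len(n), function(i) {
    with_seed(substream_seed(config$seed, "clinical", i), {
      rec <- generate_clinical_scores(groups[i], config, id = ids[i])
      rec$loading_jitter <- exp(rnorm(1, 0, config$subject_loading_sd))
      rec
    })
  })

  motion <- lapply(seq_len(n), function(i) {
    with_seed(substream_seed(config$seed, "motion", i), generate_motion(config))
  })
  images <- lapply(seq_len(n), function(i) {
    with_seed(substream_seed(config$seed, "bold", i),
              generate_bold(subjects[i, ], config, template))
  })

  truth <- if (is.null(config$effect_regions) ||
               nrow(config$effect_regions) == 0) {
    tibble(region = character(), group = character(), delta = numeric(),
           voxels = list())
  } else {
    dplyr::mutate(config$effect_regions,
      voxels = purrr::map2(.data$centre_offset, .data$radius,
        ~region_voxels(config$grid_shape, .x, .y, template$gm_prob)))
  }

  structure(list(subjects = subjects, images = images, motion = motion,
                 template = template, truth = truth, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d subjects (%s), grid %s, %d volumes\n",
              nrow(x$subjects),
              paste(x$config$n_per_group, collapse = "/"),
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_volumes))
  invisible(x)
}

#' Write a cohort to disk in standard formats
#'
#' Writes per-subject `sub-<id>_bold.nii.gz` and `sub-<id>_rp.txt`, a
#' `participants.tsv`, the gray-matter probability volume `gm_prob.nii.gz`,
#' compartment masks, and `truth.json` with planted-region voxel indices
#' (0-based) and deltas.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- bundle$subjects
  for (i in seq_len(nrow(sub))) {
    write_bold(bundle$images[[i]], file.path(dir, paste0(sub$id[i], "_bold.nii.gz")))
    write_motion(bundle$motion[[i]], file.path(dir, paste0(sub$id[i], "_rp.txt")))
  }
  out <- dplyr::select(sub, -dplyr::any_of("loading_jitter"))
  write_tsv(out, file.path(dir, "participants.tsv"))
  write_volume(bundle$template$gm_prob, bundle$config$affine,
               file.path(dir, "gm_prob.nii.gz"))
  write_volume(array(as.numeric(bundle$template$wm_mask),
                     dim = bundle$config$grid_shape),
               bundle$config$affine, file.path(dir, "wm_mask.nii.gz"))
  write_volume(array(as.numeric(bundle$template$csf_mask),
                     dim = bundle$config$grid_shape),
               bundle$config$affine, file.path(dir, "csf_mask.nii.gz"))
  truth <- purrr::pmap(bundle$truth, function(region, group, delta, voxels, ...) {
    list(region = region, group = group, delta = delta,
         voxels = unname(voxels) - 1L)  # 0-based on disk
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}
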