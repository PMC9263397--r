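#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' discard 10 volumes, 0.01-0.08 Hz ideal band-pass, gray-matter threshold
#' 0.2 (strict), FDR q 0.05, 26-connectivity clusters with no extent
#' threshold, whole-mask post hoc contrasts, RBF SVM.  Any field can be
#' overridden directly or from a YAML file ([read_run_config()]).
#'
#' @param input_dir Directory holding the cohort (as written by
#'   [write_cohort()]); `NULL` to simulate in memory.
#' @param output_dir Directory for all stage outputs.
#' @param cohort Optional [cohort_config()] used when simulating.
#' @param n_discard,low_hz,high_hz,filter_method Preprocessing parameters.
#' @param mask_threshold Gray-matter probability threshold (strict `>`).
#' @param chunk_size GFC block size in mask voxels.
#' @param q FDR level for ANCOVA, post hoc and correlation corrections.
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param min_extent Minimum cluster extent in voxels.
#' @param posthoc_mask `"whole"` (default) or `"ancova"` — whether post hoc
#'   t maps are corrected over the whole mask or restricted to
#'   ANCOVA-surviving voxels.
#' @param svm Named list passed to [loocv_svm()] (`kernel`, `cost`, `gamma`,
#'   `scale`).
#' @param seed Master seed for all randomness.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, output_dir = tempfile("gfcmap-run-"),
                       cohort = cohort_config(seed = seed),
                       n_discard = 10L, low_hz = 0.01, high_hz = 0.08,
                       filter_method = "ideal", mask_threshold = 0.2,
                       chunk_size = 2048L, q = 0.05, connectivity = 26,
                       min_extent = 1L, posthoc_mask = c("whole", "ancova"),
                       svm = list(kernel = "radial", cost = 1, gamma = NULL,
                                  scale = TRUE),
                       seed = 1L) {
  posthoc_mask <- match.arg(posthoc_mask)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 cohort = cohort, n_discard = n_discard, low_hz = low_hz,
                 high_hz = high_hz, filter_method = filter_method,
                 mask_threshold = mask_threshold, chunk_size = chunk_size,
                 q = q, connectivity = connectivity, min_extent = min_extent,
                 posthoc_mask = posthoc_mask, svm = svm,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `cohort` block
#' mirrors [cohort_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  cohort_args <- y$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  if (!is.null(cohort_args$n_per_group))
    cohort_args$n_per_group <- as.integer(unlist(cohort_args$n_per_group))
  if (!is.null(cohort_args$grid_shape))
    cohort_args$grid_shape <- as.integer(unlist(cohort_args$grid_shape))
  cohort <- do.call(cohort_config, cohort_args)
  args <- y[setdiff(names(y), "cohort")]
  args$cohort <- cohort
  do.call(run_config, args)
}

#' Load a cohort written by [write_cohort()]
#'
#' Reads `participants.tsv`, per-subject images and motion traces, the
#' tissue volumes, and (if present) `truth.json`.
#'
#' @param dir Cohort directory.
#' @return A `cohort_bundle` (without a generator config).
#' @export
read_cohort <- function(dir) {
  subjects <- as_tibble(read.table(file.path(dir, "participants.tsv"),
                                   header = TRUE, sep = "\t"))
  images <- lapply(subjects$id, function(id)
    read_bold(file.path(dir, paste0(id, "_bold.nii.gz"))))
  motion <- lapply(subjects$id, function(id)
    read_motion(file.path(dir, paste0(id, "_rp.txt"))))
  gm <- read_volume(file.path(dir, "gm_prob.nii.gz"))
  wm <- read_volume(file.path(dir, "wm_mask.nii.gz"))
  csf <- read_volume(file.path(dir, "csf_mask.nii.gz"))
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (length(tr))
      truth <- tibble(region = tr$region, group = tr$group, delta = tr$delta,
                      voxels = lapply(tr$voxels, function(v)
                        matrix(as.integer(v), ncol = 3) + 1L))
  }
  template <- list(gm_prob = gm$data, wm_mask = wm$data > 0.5,
                   csf_mask = csf$data > 0.5)
  structure(list(subjects = subjects, images = images, motion = motion,
                 template = template, truth = truth,
                 config = list(affine = gm$affine)),
            class = "cohort_bundle")
}

#' Run the full pipeline
#'
#' Sequences simulation (or cohort loading), preprocessing with motion QC,
#' GFC mapping, three-group ANCOVA with FDR and clusters, post hoc
#' contrasts, cluster-mean feature extraction, clinical correlations, and
#' LOOCV SVM classification.  Subjects failing motion QC are excluded from
#' every group analysis and listed in the manifest.  All outputs are written
#' under `config$output_dir`; the returned manifest records parameters and
#' per-file checksums so a rerun with the same config and seed can be
#' verified byte-for-byte on the deterministic stages.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }
  manifest <- list(config = unclass(config)[setdiff(names(config), "cohort")],
                   stages = list())

  # stage 1: cohort
  if (is.null(config$input_dir)) {
    say("simulate: generating synthetic cohort (seed %d)", config$cohort$seed)
    bundle <- generate_cohort(config$cohort)
  } else {
    say("load: reading cohort from %s", config$input_dir)
    bundle <- read_cohort(config$input_dir)
  }
  subjects <- bundle$subjects
  n <- nrow(subjects)
  manifest$stages$cohort <- list(n_subjects = n,
                                 groups = as.list(table(subjects$group)))

  # stage 2: preprocessing + QC
  say("preprocess: discard %d, band [%g, %g] Hz (%s), Friston-24 + WM/CSF",
      config$n_discard, config$low_hz, config$high_hz, config$filter_method)
  prep <- vector("list", n)
  qc_rows <- vector("list", n)
  for (i in seq_len(n)) {
    prep[[i]] <- preprocess_bold(bundle$images[[i]], bundle$motion[[i]],
                                 template = bundle$template,
                                 n_discard = config$n_discard,
                                 low_hz = config$low_hz,
                                 high_hz = config$high_hz,
                                 filter_method = config$filter_method)
    qc_rows[[i]] <- tibble(id = subjects$id[i],
                           max_trans_mm = prep[[i]]$qc$max_trans_mm,
                           max_rot_deg = prep[[i]]$qc$max_rot_deg,
                           mean_fd = prep[[i]]$fd$mean_fd,
                           pass = prep[[i]]$qc$pass)
  }
  qc <- dplyr::bind_rows(qc_rows)
  write_tsv(qc, file.path(out, "qc_report.tsv"))
  excluded <- qc$id[!qc$pass]
  if (length(excluded))
    say("preprocess: excluding %d subject(s) failing motion QC: %s",
        length(excluded), paste(excluded, collapse = ", "))
  manifest$stages$preprocess <- list(params = prep[[1]]$params,
                                     excluded = as.list(excluded))

  # stage 3: GFC maps
  say("gfc: gray-matter mask at probability > %g", config$mask_threshold)
  mask <- make_gm_mask(bundle$template$gm_prob, config$mask_threshold,
                       affine = bundle$images[[1]]$affine)
  maps <- lapply(seq_len(n), function(i)
    gfc_map(prep[[i]]$bold, mask, chunk_size = config$chunk_size))
  map_files <- character(n)
  for (i in seq_len(n)) {
    map_files[i] <- file.path(out, paste0(subjects$id[i], "_gfc.nii.gz"))
    z <- maps[[i]]$z
    write_volume(ifelse(is.na(z), 0, z), bundle$images[[i]]$affine,
                 map_files[i])
  }
  gfc_summary <- purrr::map2_dfr(maps, subjects$id, function(m, id)
    dplyr::bind_cols(tibble(id = id), glance(m)))
  write_tsv(gfc_summary, file.path(out, "gfc_summary.tsv"))
  manifest$stages$gfc <- list(mask_voxels = mask$n_voxels,
                              n_maps = length(maps))

  # stage 4: group statistics (QC-passing subjects only)
  keep <- !subjects$id %in% excluded
  sub_k <- subjects[keep, , drop = FALSE]
  sub_k$mean_fd <- qc$mean_fd[keep]
  if (length(unique(sub_k$group)) < 3L)
    stop_input("fewer than 3 groups remain after QC exclusion")
  stack <- stack_gfc_maps(maps[keep])
  design <- group_design(sub_k)
  say("group-stats: ANCOVA over %d voxels, %d subjects, FDR q = %g",
      ncol(stack$Y), nrow(sub_k), config$q)
  fmap <- fit_voxel_ancova(stack, design)
  f_fdr <- fdr_bh(fmap$p, config$q)
  f_clusters <- label_clusters(fmap, q = config$q,
                               connectivity = config$connectivity,
                               min_extent = config$min_extent)
  pairs <- list(c("S1", "S0"), c("S1", "HC"), c("S0", "HC"))
  posthoc <- list()
  cluster_tables <- list(dplyr::mutate(f_clusters, contrast = "ANCOVA"))
  for (pr in pairs) {
    lbl <- paste(pr, collapse = "_vs_")
    tm <- posthoc_t(stack, sub_k, pr)
    restrict <- if (config$posthoc_mask == "ancova")
      fdr_bh(tm$p, config$q)$reject & f_fdr$reject else NULL
    cl <- label_clusters(tm, q = config$q,
                         connectivity = config$connectivity,
                         min_extent = config$min_extent, reject = restrict)
    posthoc[[lbl]] <- list(map = tm, clusters = cl)
    cluster_tables[[length(cluster_tables) + 1L]] <-
      dplyr::mutate(cl, contrast = lbl)
  }
  all_clusters <- dplyr::bind_rows(cluster_tables)
  write_cluster_table(dplyr::select(all_clusters, -dplyr::any_of("contrast")),
                      file.path(out, "clusters.tsv"))
  if (nrow(all_clusters))
    write_tsv(dplyr::select(all_clusters, "contrast", "cluster", "sign",
                            "n_voxels", "peak_x", "peak_y", "peak_z",
                            "peak_stat"),
              file.path(out, "clusters_by_contrast.tsv"))
  manifest$stages$group_stats <- list(
    n_fdr_voxels = f_fdr$n_rejected,
    n_clusters = nrow(f_clusters),
    posthoc = lapply(posthoc, function(x) nrow(x$clusters)))

  # stage 5: features + clinical statistics
  feat_regions <- if (nrow(f_clusters)) f_clusters else NULL
  say("clinical-stats: %s", if (is.null(feat_regions))
    "no surviving clusters; correlations skipped" else
      sprintf("extracting %d cluster-mean features", nrow(feat_regions)))
  correlations <- NULL
  features <- NULL
  if (!is.null(feat_regions)) {
    features <- purrr::map_dfc(seq_len(nrow(feat_regions)), function(ci)
      setNames(tibble(vapply(maps[keep], extract_cluster_mean_z,
                             numeric(1),
                             cluster_voxels = feat_regions$voxels[[ci]])),
               paste0("cluster_", feat_regions$cluster[ci])))
    features <- dplyr::bind_cols(tibble(id = sub_k$id), features)
    write_tsv(features, file.path(out, "region_features.tsv"))
    patients <- sub_k[sub_k$group %in% c("S1", "S0"), ]
    correlations <- dplyr::bind_rows(
      pearson_with_bh(features[sub_k$group %in% c("S1", "S0"), ],
                      patients, subset_label = "patients", q = config$q),
      pearson_with_bh(features[sub_k$group == "S1", ],
                      sub_k[sub_k$group == "S1", ],
                      subset_label = "S1", q = config$q))
    write_tsv(correlations, file.path(out, "correlations.tsv"))
  }
  clin <- characteristics_table(summarize_cohort(sub_k),
                                gender_counts_from(sub_k))
  write_tsv(clin, file.path(out, "characteristics.tsv"))

  # stage 6: classification
  classification <- NULL
  if (!is.null(features)) {
    say("classify: LOOCV SVM on cluster-mean features")
    svm_args <- config$svm
    cls <- function(sel, lab) {
      f <- features[sel, , drop = FALSE]
      f$label <- lab
      do.call(loocv_svm, c(list(features = f, positive = "S1"), svm_args))
    }
    res <- list()
    sel <- sub_k$group %in% c("S1", "S0")
    if (all(table(sub_k$group[sel]) >= 3))
      res$S1_vs_S0 <- cls(sel, sub_k$group[sel])
    sel <- sub_k$group %in% c("S1", "HC")
    if (all(table(sub_k$group[sel]) >= 3))
      res$S1_vs_HC <- cls(sel, sub_k$group[sel])
    classification <- res
    if (length(res)) {
      cls_tbl <- purrr::imap_dfr(res, function(fit, nm)
        dplyr::bind_cols(tibble(comparison = nm), glance(fit)))
      write_tsv(cls_tbl, file.path(out, "classification.tsv"))
      preds <- purrr::imap_dfr(res, function(fit, nm)
        dplyr::mutate(tidy(fit), comparison = nm, .before = 1))
      write_tsv(preds, file.path(out, "predictions.tsv"))
    }
  }
  manifest$stages$classification <-
    lapply(classification %||% list(), function(f) as.list(glance(f)))
  manifest$stages$correlations <- list(
    n_pairs = if (is.null(correlations)) 0L else nrow(correlations),
    n_significant = if (is.null(correlations)) 0L else
      sum(correlations$significant, na.rm = TRUE))

  # manifest with output checksums
  files <- list.files(out, full.names = TRUE)
  files <- files[!grepl("manifest|run\\.log", files)]  # timestamped, not content
  manifest$checksums <- as.list(setNames(unname(tools::md5sum(files)),
                                         basename(files)))
  manifest$log <- log_lines
  writeLines(log_lines, file.path(out, "run.log"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(c(manifest,
              list(results = list(fmap = fmap, f_clusters = f_clusters,
                                  posthoc = posthoc, features = features,
                                  correlations = correlations,
                                  classification = classification,
                                  qc = qc, mask = mask, subjects = sub_k))),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  subjects: %d (excluded: %d)\n",
              x$stages$cohort$n_subjects,
              length(x$stages$preprocess$excluded)))
  cat(sprintf("  mask voxels: %d; FDR discoveries: %d; clusters: %d\n",
              x$stages$gfc$mask_voxels, x$stages$group_stats$n_fdr_voxels,
              x$stages$group_stats$n_clusters))
  invisible(x)
}

# per-group mean/SD/n summaries of a subject table, in the shape
# characteristics_table() consumes
summarize_cohort <- function(subjects) {
  vars <- intersect(c("age", "education_years", "illness_duration_months",
                      "hrsd17", "anx_som", "weight_loss", "cognitive",
                      "retardation", "sleep"), names(subjects))
  purrr::map_dfr(vars, function(v)
    subjects |>
      dplyr::group_by(group = .data$group) |>
      dplyr::summarise(variable = v,
                       mean = mean(.data[[v]][!is.na(.data[[v]])]),
                       sd = sd(.data[[v]][!is.na(.data[[v]])]),
                       n = sum(!is.na(.data[[v]])), .groups = "drop") |>
      dplyr::filter(.data$n > 0))
}

gender_counts_from <- function(subjects) {
  subjects |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(male = sum(.data$gender == "male"),
                     female = sum(.data$gender == "female"),
                     .groups = "drop")
}
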