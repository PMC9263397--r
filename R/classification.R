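#' Leave-one-out SVM classification
#'
#' For each subject, trains a support-vector machine (libsvm via \pkg{e1071})
#' on the remaining n - 1 subjects and predicts the held-out subject.
#' Feature standardization (z-scoring) is computed on the training fold only
#' and applied to the held-out row — the leakage-free protocol.  Defaults
#' follow the library's: RBF kernel, cost 1, gamma = 1 / n_features; a
#' linear kernel is available.
#'
#' @param features Tibble: `id`, `label` (two classes), and one numeric
#'   column per feature.  The positive class is given by `positive`.
#' @param positive Label counted as positive for sensitivity (default: the
#'   first level encountered).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost SVM cost parameter.
#' @param gamma RBF kernel width; default `1 / n_features`.
#' @param scale Standardize features per training fold (default `TRUE`).
#' @return An object of class `loocv_fit`: list with `predictions` (tibble:
#'   `id`, `label`, `predicted`, `correct`), `counts` (TP/FN/TN/FP),
#'   `metrics` (from [classification_metrics()]), `positive`, `features`.
#' @export
loocv_svm <- function(features, positive = NULL, kernel = "radial",
                      cost = 1, gamma = NULL, scale = TRUE) {
  feat_cols <- setdiff(names(features), c("id", "label"))
  if (!length(feat_cols)) stop_input("no feature columns")
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  if (!all(is.finite(X))) stop_input("features must be finite")
  y <- factor(features$label)
  if (nlevels(y) != 2L) stop_input("exactly 2 classes required")
  if (any(table(y) < 3L)) stop_input("each class needs >= 3 subjects")
  positive <- positive %||% levels(y)[1]
  if (!positive %in% levels(y)) stop_input("positive class '%s' not found", positive)
  gamma <- gamma %||% (1 / ncol(X))
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) stop_input("a training fold lost a class")
    Xte <- X[i, , drop = FALSE]
    if (scale) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    fit <- e1071::svm(Xtr, ytr, kernel = kernel, cost = cost, gamma = gamma,
                      scale = FALSE)
    pred[i] <- as.character(predict(fit, Xte))
  }
  obs <- as.character(y)
  counts <- confusion_counts(obs, pred, positive)
  structure(list(
    predictions = tibble(id = features$id, label = obs, predicted = pred,
                         correct = obs == pred),
    counts = counts,
    metrics = classification_metrics(counts),
    positive = positive, features = feat_cols,
    config = list(kernel = kernel, cost = cost, gamma = gamma, scale = scale)
  ), class = "loocv_fit")
}

confusion_counts <- function(obs, pred, positive) {
  list(TP = sum(obs == positive & pred == positive),
       FN = sum(obs == positive & pred != positive),
       TN = sum(obs != positive & pred != positive),
       FP = sum(obs != positive & pred == positive))
}

#' @export
print.loocv_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<loocv_fit> features: %s; positive = %s\n",
                     "  accuracy %.2f%% (%d/%d), sensitivity %.2f%% (%d/%d), ",
                     "specificity %.2f%% (%d/%d)\n"),
              paste(x$features, collapse = ", "), x$positive,
              m$accuracy, x$counts$TP + x$counts$TN,
              with(x$counts, TP + FN + TN + FP),
              m$sensitivity, x$counts$TP, x$counts$TP + x$counts$FN,
              m$specificity, x$counts$TN, x$counts$TN + x$counts$FP))
  invisible(x)
}

#' @method tidy loocv_fit
#' @export
tidy.loocv_fit <- function(x, ...) x$predictions

#' @method glance loocv_fit
#' @export
glance.loocv_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(features = paste(x$features, collapse = "+"),
                          positive = x$positive),
                   as_tibble(x$counts), as_tibble(x$metrics))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`, `sensitivity = TP / (TP +
#' FN)`, `specificity = TN / (TN + FP)`, each reported as a percentage
#' rounded to 2 decimals.  Zero denominators yield `NA` with a warning
#' rather than a silent 0.
#'
#' @param counts List or one-row data frame with `TP`, `FN`, `TN`, `FP`
#'   (nonnegative integers).
#' @return Tibble with `accuracy`, `sensitivity`, `specificity` (percent,
#'   2 dp).
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; fn <- counts$FN; tn <- counts$TN; fp <- counts$FP
  if (any(c(tp, fn, tn, fp) < 0)) stop_input("counts must be nonnegative")
  pct <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    round(100 * num / den, 2)
  }
  tibble(accuracy = pct(tp + tn, tp + fn + tn + fp, "accuracy"),
         sensitivity = pct(tp, tp + fn, "sensitivity"),
         specificity = pct(tn, tn + fp, "specificity"))
}

#' Exhaustive feature-subset search under LOOCV
#'
#' Evaluates every nonempty feature subset up to `max_subset_size` with
#' [loocv_svm()] and ranks the results by accuracy, breaking ties toward
#' fewer features and then higher sensitivity.
#'
#' @inheritParams loocv_svm
#' @param max_subset_size Largest subset size to consider (default: all
#'   features).
#' @return Tibble: `subset` (feature names, `+`-separated), `n_features`,
#'   TP/FN/TN/FP, `accuracy`, `sensitivity`, `specificity`, ranked best
#'   first.
#' @export
feature_subset_search <- function(features, max_subset_size = NULL,
                                  positive = NULL, kernel = "radial",
                                  cost = 1, gamma = NULL, scale = TRUE) {
  feat_cols <- setdiff(names(features), c("id", "label"))
  if (!length(feat_cols)) stop_input("no feature columns")
  max_subset_size <- min(max_subset_size %||% length(feat_cols),
                         length(feat_cols))
  subsets <- unlist(lapply(seq_len(max_subset_size), function(k)
    utils::combn(feat_cols, k, simplify = FALSE)), recursive = FALSE)
  res <- purrr::map_dfr(subsets, function(s) {
    fit <- loocv_svm(features[, c("id", "label", s)], positive = positive,
                     kernel = kernel, cost = cost, gamma = gamma, scale = scale)
    dplyr::bind_cols(tibble(subset = paste(s, collapse = "+"),
                            n_features = length(s)),
                     as_tibble(fit$counts), fit$metrics)
  })
  dplyr::arrange(res, dplyr::desc(.data$accuracy), .data$n_features,
                 dplyr::desc(.data$sensitivity))
}
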