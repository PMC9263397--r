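#' One-way ANOVA from raw values
#'
#' Textbook between/within decomposition: df = (g - 1, N - g).
#'
#' @param values Numeric vector.
#' @param group_labels Vector of group labels, same length.
#' @return Tibble with `F`, `p`, `df1`, `df2`.
#' @export
oneway_anova <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop_input("need at least 2 groups")
  n <- tapply(values, g, length)
  if (any(n < 2L)) stop_input("every group needs n >= 2")
  means <- tapply(values, g, mean)
  grand <- mean(values)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  Fv <- if (ssb == 0) 0 else if (ssw == 0) Inf else (ssb / df1) / (ssw / df2)
  tibble(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE),
         df1 = df1, df2 = df2)
}

#' One-way ANOVA reconstructed from printed group summaries
#'
#' Recovers the F test from per-group mean, SD and n alone:
#' `SSb = sum n_g (m_g - m.)^2`, `SSw = sum (n_g - 1) SD_g^2`.  This is what
#' lets published summary tables be checked without the raw data.  If all
#' within-group SDs are 0 but the means differ, F is infinite and reported
#' as such.
#'
#' @param summaries Tibble with columns `mean`, `sd`, `n` (one row per
#'   group).
#' @return Tibble with `F`, `p`, `df1`, `df2`.
#' @export
anova_from_summary <- function(summaries) {
  m <- summaries$mean; s <- summaries$sd; n <- summaries$n
  if (any(is.na(m) | is.na(s) | is.na(n))) stop_input("summaries contain NA")
  g <- length(m)
  if (g < 2L) stop_input("need at least 2 groups")
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- g - 1L
  df2 <- N - g
  Fv <- if (ssb == 0) 0 else if (ssw == 0) Inf else (ssb / df1) / (ssw / df2)
  tibble(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE),
         df1 = df1, df2 = df2)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins,
#' df = (r - 1)(c - 1), no continuity correction (the convention for tables
#' larger than 2x2).
#'
#' @param counts Matrix of nonnegative counts, at least 2x2.
#' @return Tibble with `chisq`, `p`, `df`.
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_input("counts must be nonnegative")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop_input("need at least a 2x2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_input("table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(chisq = unname(res$statistic), p = res$p.value,
         df = unname(res$parameter))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with df = n1 + n2 - 2, computable either from raw samples or
#' from printed summaries (means, SDs, ns).
#'
#' @param x,y Numeric samples (each n >= 2); or `NULL` if summaries given.
#' @param summaries Optional tibble with columns `mean`, `sd`, `n` (2 rows).
#' @return Tibble with `t`, `p`, `df`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, summaries = NULL) {
  if (is.null(summaries)) {
    if (length(x) < 2L || length(y) < 2L) stop_input("each sample needs n >= 2")
    summaries <- tibble(mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)),
                        n = c(length(x), length(y)))
  }
  if (nrow(summaries) != 2L) stop_input("exactly 2 groups required")
  m <- summaries$mean; s <- summaries$sd; n <- summaries$n
  df <- sum(n) - 2
  sp2 <- sum((n - 1) * s^2) / df
  tv <- if (sp2 == 0) {
    if (m[1] == m[2]) 0 else Inf * sign(m[1] - m[2])
  } else (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  tibble(t = tv, p = 2 * pt(abs(tv), df, lower.tail = FALSE), df = df)
}

#' Reconstruct a cohort-characteristics statistics table from summaries
#'
#' Applies [anova_from_summary()] to every variable with three-group
#' summaries, [two_sample_t()] to patient-only variables (two groups), and
#' [chisq_independence()] to the gender counts — the full set of test
#' statistics a demographics table prints.
#'
#' @param summaries Tibble like [reference_group_summaries()].
#' @param gender_counts Tibble like `reference_gender_counts()` with columns
#'   `group`, `male`, `female`.
#' @return Tibble with `variable`, `statistic` (`"F"`, `"t"` or `"chisq"`),
#'   `value`, `p`.
#' @export
characteristics_table <- function(summaries = reference_group_summaries(),
                                  gender_counts = reference_gender_counts()) {
  rows <- summaries |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(df, key) {
      df <- df[!is.na(df$mean), , drop = FALSE]
      if (nrow(df) >= 3L) {
        r <- anova_from_summary(df)
        tibble(statistic = "F", value = r$F, p = r$p)
      } else if (nrow(df) == 2L) {
        r <- two_sample_t(summaries = df)
        tibble(statistic = "t", value = r$t, p = r$p)
      } else tibble(statistic = NA_character_, value = NA_real_, p = NA_real_)
    }) |>
    dplyr::ungroup()
  cs <- chisq_independence(as.matrix(gender_counts[, c("male", "female")]))
  dplyr::bind_rows(rows,
                   tibble(variable = "gender", statistic = "chisq",
                          value = cs$chisq, p = cs$p))
}

#' Pearson correlations with Benjamini-Hochberg correction
#'
#' Correlates each region's per-subject cluster-mean z values with each
#' clinical variable within a declared family (a subject subset, e.g. all
#' patients or one group), computing two-sided p from the t transform and
#' applying BH across all region x variable pairs in the family.  Pairs
#' where either variable has zero variance are skipped with a warning.
#'
#' @param features Tibble: one row per subject, `id` plus one column per
#'   region (cluster-mean z).
#' @param clinical Tibble: one row per subject, `id` plus clinical columns.
#' @param regions Character vector of region columns (default: all non-`id`
#'   feature columns).
#' @param variables Character vector of clinical columns to test.
#' @param subset_label Family label recorded in the output.
#' @param q BH level.
#' @return Tibble with `subset`, `region`, `variable`, `n`, `r`, `p`,
#'   `p_bh`, `significant`.
#' @export
pearson_with_bh <- function(features, clinical,
                            regions = setdiff(names(features), "id"),
                            variables = c("hrsd17", "anx_som", "weight_loss",
                                          "cognitive", "retardation", "sleep"),
                            subset_label = "all", q = 0.05) {
  df <- dplyr::inner_join(features, clinical, by = "id")
  grid <- tidyr::expand_grid(region = regions, variable = variables)
  res <- purrr::pmap_dfr(grid, function(region, variable) {
    x <- df[[region]]; y <- df[[variable]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4L) stop_input("pair %s x %s has n = %d (< 4)", region, variable, n)
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("skipping %s x %s: zero variance", region, variable))
      return(tibble(region = region, variable = variable, n = n,
                    r = NA_real_, p = NA_real_))
    }
    r <- cor(x, y)
    tv <- r * sqrt((n - 2) / (1 - r^2))
    tibble(region = region, variable = variable, n = n, r = r,
           p = 2 * pt(abs(tv), n - 2, lower.tail = FALSE))
  })
  adj <- fdr_bh(res$p, q)
  dplyr::mutate(res, subset = subset_label, p_bh = adj$p_adjusted,
                significant = adj$reject, .before = 1)
}
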