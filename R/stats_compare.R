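# Group-level comparison of per-cell features between two conditions,
# per-category significance summaries, and the box-plot IQR trimming rule
# (visualization only -- statistics are always computed on untrimmed data).

#' Two-sample t-tests per feature between two condition groups
#'
#' Independent two-sample Student's t-test (equal variance by default,
#' matching the convention of the common two-sample test; Welch available)
#' for every feature column of a tidy per-cell feature table. Missing
#' values are dropped per feature; features with fewer than 2 usable values
#' in either group are skipped with a warning. No trimming is ever applied
#' here: outlier removal is a visualization-only step.
#'
#' @param table data.frame with a `condition` column and numeric feature
#'   columns (any non-numeric columns are ignored).
#' @param group_a,group_b the two condition labels to compare.
#' @param var_equal use the pooled-variance Student test (default TRUE).
#' @return data.frame with one row per feature: `feature`, `t`, `p`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
compare_features <- function(table, group_a, group_b, var_equal = TRUE) {
  stopifnot("condition" %in% names(table))
  feats <- names(table)[vapply(table, is.numeric, TRUE)]
  feats <- setdiff(feats, c("condition", "cell", "cell_id"))
  out <- list()
  for (f in feats) {
    a <- table[[f]][table$condition == group_a]
    b <- table[[f]][table$condition == group_b]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("compare_features: feature '", f, "' skipped (fewer than 2 values in a group)")
      next
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        warning("compare_features: feature '", f, "' has zero within-group variance")
        tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
      }
    } else {
      ht <- stats::t.test(a, b, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    out[[f]] <- data.frame(feature = f, t = tt$statistic, p = tt$p.value,
                           mean_a = mean(a), mean_b = mean(b),
                           n_a = length(a), n_b = length(b))
  }
  if (length(out) == 0)
    return(data.frame(feature = character(), t = numeric(), p = numeric(),
                      mean_a = numeric(), mean_b = numeric(),
                      n_a = integer(), n_b = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of significantly different features per category
#'
#' For each feature category, the fraction of its features whose raw
#' two-sided p-value falls below `alpha` (default 1e-2; no multiple-testing
#' correction, matching a raw-p screening convention).
#'
#' @param comparisons data.frame from [compare_features()].
#' @param categories named character vector mapping feature name -> category.
#' @param alpha significance screen (default 1e-2).
#' @return data.frame with `category`, `n_features`, `n_significant`,
#'   `fraction`.
#' @export
category_significance <- function(comparisons, categories, alpha = 1e-2) {
  unmapped <- setdiff(comparisons$feature, names(categories))
  if (length(unmapped))
    stop("category_significance: unmapped feature(s): ",
         paste(unmapped, collapse = ", "))
  cat_ <- categories[comparisons$feature]
  sig <- comparisons$p < alpha
  agg <- stats::aggregate(list(n_significant = sig),
                          by = list(category = cat_), FUN = sum)
  tot <- stats::aggregate(list(n_features = sig),
                          by = list(category = cat_), FUN = length)
  res <- merge(tot, agg, by = "category")
  res$fraction <- res$n_significant / res$n_features
  res
}

#' Box-plot IQR outlier trimming (visualization only)
#'
#' Removes values outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with quartiles by
#' linear interpolation (the default `quantile` type 7 convention). This is
#' a single-pass rule intended solely for plotting; group statistics are
#' always computed on untrimmed data ([compare_features()] has no trimming
#' parameter by design).
#'
#' @param values numeric vector (>= 4 values; shorter inputs are returned
#'   unchanged with a warning).
#' @return the trimmed vector.
#' @export
iqr_trim <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) {
    warning("iqr_trim: fewer than 4 values; returned unchanged")
    return(values)
  }
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[2] + 1.5 * iqr
  values[is.finite(values) & values >= lo & values <= hi]
}
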