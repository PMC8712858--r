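#' Two-sample comparison (two-tailed Student's t-test)
#'
#' @param a,b numeric samples, each with n >= 2 and positive variance.
#' @param labels group labels for the output.
#' @return one-row data.frame (a ComparisonResult): group_a, group_b,
#'   test_name, statistic, p_value, adjusted_p (= p_value here),
#'   significant (adjusted_p < 0.05).
#' @export
compare_two <- function(a, b, labels = c("a", "b")) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate variance: both samples are constant")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  comparison_row(labels[1], labels[2], "t", unname(tt$statistic),
                 tt$p.value, tt$p.value)
}

#' Multi-group comparison with normality-based test selection
#'
#' Shapiro-Wilk (alpha = 0.05) on every group selects the path: if all
#' groups look normal, pairwise two-tailed t-tests (the ANOVA-with-
#' Bonferroni path); if any group is non-normal, or `force_nonparametric`,
#' Kruskal-Wallis with pairwise Wilcoxon rank-sum follow-ups. All pairwise
#' p-values are Bonferroni-adjusted with m = the number of pairwise
#' comparisons: adjusted_p = min(1, m * p).
#'
#' @param samples named list of >= 3 numeric groups, each n >= 3.
#' @param force_nonparametric force the Kruskal-Wallis path.
#' @return data.frame of pairwise ComparisonResult rows, with attributes
#'   `path` ("anova_bonferroni" or "kruskal_wallis") and `omnibus_p` (the
#'   overall one-way ANOVA or Kruskal-Wallis p-value).
#' @export
compare_many <- function(samples, force_nonparametric = FALSE) {
  if (length(samples) < 3L) {
    stop("fewer than 3 groups: use compare_two() for two-sample comparisons")
  }
  if (any(vapply(samples, length, integer(1)) < 3L)) {
    stop("every group needs n >= 3")
  }
  labs <- names(samples)
  if (is.null(labs)) labs <- paste0("group_", seq_along(samples))
  nonparametric <- isTRUE(force_nonparametric) ||
    any(vapply(samples, function(x) stats::shapiro.test(x)$p.value,
               numeric(1)) < 0.05)
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(labs, lengths(samples)), levels = labs)
  omnibus_p <- if (nonparametric) {
    stats::kruskal.test(values, groups)$p.value
  } else {
    summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1]
  }
  pairs <- utils::combn(seq_along(samples), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (nonparametric) {
      w <- suppressWarnings(stats::wilcox.test(samples[[i1]], samples[[i2]],
                                               alternative = "two.sided"))
      comparison_row(labs[i1], labs[i2], "kruskal_wallis",
                     unname(w$statistic), w$p.value,
                     bonferroni(w$p.value, m))
    } else {
      tt <- stats::t.test(samples[[i1]], samples[[i2]], var.equal = TRUE,
                          alternative = "two.sided")
      comparison_row(labs[i1], labs[i2], "anova_bonferroni",
                     unname(tt$statistic), tt$p.value,
                     bonferroni(tt$p.value, m))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "path") <- if (nonparametric) "kruskal_wallis" else
    "anova_bonferroni"
  attr(out, "omnibus_p") <- omnibus_p
  out
}

#' Bonferroni adjustment
#'
#' adjusted_p = min(1, m * p); monotone in p and capped at 1.
#'
#' @param p raw p-value(s).
#' @param m number of comparisons in the family.
#' @return adjusted p-value(s).
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

comparison_row <- function(ga, gb, test_name, statistic, p, adj) {
  data.frame(group_a = ga, group_b = gb, test_name = test_name,
             statistic = statistic, p_value = p, adjusted_p = adj,
             significant = adj < 0.05, stringsAsFactors = FALSE)
}

#' Group comparisons over a metrics table
#'
#' Applies [compare_two()] or [compare_many()] to one metric column of a
#' per-cell metrics table, split by a grouping column.
#'
#' @param metrics data.frame (e.g. from [analyze_raman_cube()] rows).
#' @param metric column name to compare.
#' @param by grouping column name (default "condition").
#' @param force_nonparametric passed to [compare_many()].
#' @return data.frame of ComparisonResult rows with a `metric` column.
#' @export
compare_metric <- function(metrics, metric, by = "condition",
                           force_nonparametric = FALSE) {
  stopifnot(metric %in% names(metrics), by %in% names(metrics))
  groups <- split(metrics[[metric]], metrics[[by]])
  out <- if (length(groups) == 2L) {
    compare_two(groups[[1]], groups[[2]], labels = names(groups))
  } else {
    compare_many(groups, force_nonparametric)
  }
  cbind(metric = metric, out, stringsAsFactors = FALSE)
}
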