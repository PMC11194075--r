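#' Significance star coding
#'
#' Maps a two-sided p-value to the label used in the figure annotations,
#' with strict inequalities: `"****"` if p < 0.0001, `"***"` if p < 0.001,
#' `"**"` if p < 0.01, `"*"` if p < 0.05, else `"ns"`. A p exactly at a cut
#' point receives the weaker label.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param cuts strictly decreasing cut points.
#' @return character label(s).
#' @export
star_label <- function(p, cuts = c(0.05, 0.01, 0.001, 0.0001)) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(diff(cuts) >= 0)) stop("cuts must be strictly decreasing")
  labs <- c("ns", "*", "**", "***", "****")
  vapply(p, function(pi) labs[1 + sum(pi < cuts)], character(1))
}

new_group_comparison <- function(test, statistic, p, n_a, n_b, summary_a,
                                 summary_b, branch, note = NULL) {
  structure(list(test = test, statistic = statistic,
                 p_two_sided = p, n_a = n_a, n_b = n_b,
                 summary_a = summary_a, summary_b = summary_b,
                 label = star_label(p), branch = branch, note = note),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  sumname <- if (x$test == "mann_whitney") "median" else "mean"
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g [%s]\n",
              x$test, x$statistic, x$p_two_sided, x$label))
  cat(sprintf("  group a: n = %d, %s = %.4g | group b: n = %d, %s = %.4g\n",
              x$n_a, sumname, x$summary_a, x$n_b, sumname, x$summary_b))
  cat(sprintf("  p-value branch: %s\n", x$branch))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' The per-cell comparison test. U is computed by rank summation with
#' midranks for ties. The two-sided p-value is exact — by full enumeration
#' of all `choose(n_a + n_b, n_a)` group assignments — when the combined
#' sample size is at most 16 and the pooled data are tie-free; otherwise a
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. Group summaries are medians.
#'
#' @param a,b numeric samples (per-cell values).
#' @param method `"auto"` (the rule above), `"exact"`, or `"normal"`.
#' @param exact_max_n largest combined sample size for the exact branch.
#' @return a `GroupComparison` with `statistic` = U of group `a`.
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal"),
                         exact_max_n = 16L) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  u_stat <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  ties <- anyDuplicated(pooled) > 0
  use_exact <- switch(method,
                      exact = TRUE,
                      normal = FALSE,
                      auto = n <= exact_max_n && !ties)
  if (use_exact) {
    dev <- abs(u_stat - mu)
    combs <- utils::combn(n, n_a)
    u_all <- colSums(matrix(r[combs], nrow = n_a)) - n_a * (n_a + 1) / 2
    p <- mean(abs(u_all - mu) >= dev - 1e-9)
    branch <- "exact enumeration"
  } else {
    tie_tab <- table(pooled)
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
      branch <- "normal approximation (degenerate: all values tied)"
    } else {
      z <- max(abs(u_stat - mu) - 0.5, 0) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
      branch <- "normal approximation, tie-corrected, continuity-corrected"
    }
  }
  new_group_comparison("mann_whitney", u_stat, p, n_a, n_b,
                       median(a), median(b), branch)
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' The per-tumor comparison test: Student's t with pooled variance and
#' `n_a + n_b - 2` degrees of freedom, two-sided. Group summaries are means.
#' If the pooled variance is zero, p is 1 when the means are equal and 0
#' (with a warning) when they differ.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return a `GroupComparison`.
#' @export
unpaired_t <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2 || n_b < 2) stop("both samples must have n >= 2")
  ma <- mean(a); mb <- mean(b)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * stats::var(a) + (n_b - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    if (ma == mb) {
      return(new_group_comparison("t_test", 0, 1, n_a, n_b, ma, mb,
                                  "degenerate: zero pooled variance"))
    }
    warning("zero pooled variance with unequal means; p = 0 by convention")
    return(new_group_comparison("t_test", Inf * sign(ma - mb), 0, n_a, n_b,
                                ma, mb, "degenerate: zero pooled variance"))
  }
  t_stat <- (ma - mb) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  p <- 2 * pt(-abs(t_stat), df)
  new_group_comparison("t_test", t_stat, p, n_a, n_b, ma, mb,
                       sprintf("Student t, df = %d", df))
}

#' Aggregate per-cell values to per-unit means
#'
#' For two-level ("xenograft") designs: each unit's value is the arithmetic
#' mean of the chosen per-cell metric over the cells of that unit; the
#' downstream comparison then runs [unpaired_t()] on unit means. Units
#' contributing zero non-missing cells are excluded with a warning.
#'
#' @param cells data.frame of per-cell phenotypes carrying a unit column.
#' @param metric name of the per-cell metric column.
#' @param unit name of the unit id column.
#' @return data.frame `unit, n_cells, mean_value`.
#' @export
per_tumor_aggregate <- function(cells, metric, unit = "unit") {
  if (!metric %in% names(cells)) stop("no such metric column: ", metric)
  if (!unit %in% names(cells)) stop("no such unit column: ", unit)
  v <- cells[[metric]]
  keep <- !is.na(v)
  dropped_units <- setdiff(unique(cells[[unit]]),
                           unique(cells[[unit]][keep]))
  if (length(dropped_units))
    warning("unit(s) with zero usable cells excluded: ",
            paste(dropped_units, collapse = ", "))
  agg <- aggregate(v[keep], by = list(unit = cells[[unit]][keep]),
                   FUN = mean)
  n <- aggregate(v[keep], by = list(unit = cells[[unit]][keep]),
                 FUN = length)
  data.frame(unit = agg$unit, n_cells = n$x, mean_value = agg$x)
}

#' Median, mean and n of a distribution
#'
#' The summary-line values drawn on per-cell scatter plots (median for
#' rank-based comparisons, mean for t-based ones).
#'
#' @param values non-empty numeric vector.
#' @return list `median, mean, n`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty sample")
  list(median = median(values), mean = mean(values), n = length(values))
}

#' Two-group comparison of a per-cell metric
#'
#' Convenience wrapper running [mann_whitney()] (cell level) or
#' [unpaired_t()] (after [per_tumor_aggregate()] at unit level) on a
#' phenotype table with a `condition` column.
#'
#' @param phenotypes per-cell phenotype data.frame with a `condition`
#'   column (two levels) and, for `by = "unit"`, a `unit` column.
#' @param metric per-cell metric column name.
#' @param test `"mwu"` or `"ttest"`.
#' @param by `"cell"` or `"unit"`.
#' @return a `GroupComparison`.
#' @export
compare_groups <- function(phenotypes, metric,
                           test = c("mwu", "ttest"),
                           by = c("cell", "unit")) {
  test <- match.arg(test); by <- match.arg(by)
  conds <- unique(phenotypes$condition)
  if (length(conds) != 2) stop("exactly two conditions are required")
  if (by == "unit") {
    va <- vb <- NULL
    for (ci in 1:2) {
      sub <- phenotypes[phenotypes$condition == conds[ci], , drop = FALSE]
      agg <- per_tumor_aggregate(sub, metric)
      if (ci == 1) va <- agg$mean_value else vb <- agg$mean_value
    }
  } else {
    va <- phenotypes[[metric]][phenotypes$condition == conds[1]]
    vb <- phenotypes[[metric]][phenotypes$condition == conds[2]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  }
  if (test == "mwu") mann_whitney(va, vb) else unpaired_t(va, vb)
}
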