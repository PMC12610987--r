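## Clinical table handling: bronchodilator-responsiveness labeling and the
## normality-routed group-comparison decision tree.

#' Label bronchodilator responsiveness
#'
#' A subject is BDR-positive iff the post-bronchodilator change in FEV1 or
#' in FVC exceeds 10 % of the predicted value (strict `>` by default; set
#' `strict = FALSE` for a `>=` comparator). Missing deltas are ignored as
#' long as at least one is present.
#'
#' @param deltaFev1,deltaFvc Post-bronchodilator changes in percent of
#'   predicted; vectorized, `NA` allowed.
#' @param threshold Positivity threshold in percent predicted (default 10).
#' @param strict Use strict `>` (default) rather than `>=`.
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
#' @examples
#' labelBDR(12, 3)      # positive
#' labelBDR(10, 10)     # negative: strict inequality
labelBDR <- function(deltaFev1, deltaFvc = NA_real_, threshold = 10,
                     strict = TRUE) {
  n <- max(length(deltaFev1), length(deltaFvc))
  deltaFev1 <- rep_len(as.numeric(deltaFev1), n)
  deltaFvc <- rep_len(as.numeric(deltaFvc), n)
  if (any(is.na(deltaFev1) & is.na(deltaFvc)))
    stop("labeling error: at least one of the FEV1/FVC deltas is required")
  over <- function(x) !is.na(x) & (if (strict) x > threshold
                                   else x >= threshold)
  ifelse(over(deltaFev1) | over(deltaFvc), "positive", "negative")
}

#' Compare a variable between groups with automatic test routing
#'
#' Implements the comparison decision tree: continuous variables are tested
#' for normality per group (Shapiro-Wilk at `normalityAlpha`); if every
#' group is compatible with normality, Welch's t-test (two groups) or
#' one-way ANOVA (more) is used, otherwise the Mann-Whitney U test or
#' Kruskal-Wallis. Categorical variables use Pearson's chi-square, or
#' Fisher's exact test when any expected cell count is below 5. Missing
#' values are excluded pairwise; no multiple-testing correction is applied
#' (raw p-values are reported).
#'
#' @param table Data frame with the variable and grouping columns.
#' @param variable Name of the column to compare.
#' @param group Name of the grouping column.
#' @param normalityAlpha Shapiro-Wilk significance level gating the
#'   parametric route (default 0.05).
#' @return One-row data frame: `variable`, `groups`, `n_used`, `test_used`
#'   (`welch`, `anova`, `mannwhitney`, `kruskal`, `chi2` or `fisher`),
#'   `statistic`, `p_value`.
#' @export
compareGroups <- function(table, variable, group, normalityAlpha = 0.05) {
  stopifnot(variable %in% names(table), group %in% names(table))
  x <- table[[variable]]
  g <- as.factor(table[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop("at least two groups are required")

  row <- function(test, statistic, p) data.frame(
    variable = variable, groups = paste(levels(g), collapse = "|"),
    n_used = length(x), test_used = test,
    statistic = unname(statistic), p_value = unname(p),
    stringsAsFactors = FALSE)

  if (is.numeric(x)) {
    if (length(unique(x)) < 2L)
      stop("test error: '", variable, "' is degenerate (constant)")
    sizes <- table(g)
    if (any(sizes < 3L))
      stop("each group needs at least 3 observations for '", variable, "'")
    normal <- all(vapply(levels(g), function(lv) {
      xi <- x[g == lv]
      if (length(unique(xi)) < 2L) return(FALSE)
      stats::shapiro.test(xi)$p.value >= normalityAlpha
    }, logical(1)))
    if (nlevels(g) == 2L) {
      if (normal) {
        tt <- stats::t.test(x ~ g, var.equal = FALSE)
        row("welch", tt$statistic, tt$p.value)
      } else {
        wt <- stats::wilcox.test(x ~ g, exact = FALSE)
        row("mannwhitney", wt$statistic, wt$p.value)
      }
    } else {
      if (normal) {
        fit <- stats::aov(x ~ g)
        s <- summary(fit)[[1]]
        row("anova", s[["F value"]][1], s[["Pr(>F)"]][1])
      } else {
        kt <- stats::kruskal.test(x, g)
        row("kruskal", kt$statistic, kt$p.value)
      }
    }
  } else {
    tab <- table(as.factor(x), g)
    if (length(unique(as.factor(x))) < 2L)
      stop("test error: '", variable, "' is degenerate (constant)")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      row("fisher", NA_real_, ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      row("chi2", ct$statistic, ct$p.value)
    }
  }
}
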