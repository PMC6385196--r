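# Descriptive-comparison layer: group contrasts between IDH and non-IDH
# patients, pre/post paired contrasts, and phase-trend tests of HRV
# parameters. "As appropriate" test choices are operationalized as pure
# functions of the data: chi-square vs Fisher by the expected-count >= 5
# rule, t vs Mann-Whitney (and paired t vs Wilcoxon) by a Shapiro-Wilk
# normality check at alpha = 0.05 per group.

.normal_enough <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) return(FALSE)
  if (length(unique(x)) < 3L) return(FALSE)
  shapiro.test(x)$p.value >= alpha
}

#' Compare a categorical variable between groups
#'
#' Pearson chi-square without continuity correction when every expected
#' cell count is at least 5, Fisher's exact test otherwise; the rule is
#' applied automatically and the chosen test reported.
#'
#' @param counts contingency table of nonnegative integer counts
#'   (matrix, typically 2x2 with groups in columns).
#' @return list: `test` (`"chi-squared"` or `"fisher"`), `p`,
#'   `statistic` (chi-square statistic or `NA` for Fisher).
#' @examples
#' # drug-use contrast: 34/43 users vs 15/28
#' compare_categorical(matrix(c(34, 9, 15, 13), nrow = 2))
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has an empty margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
    list(test = "chi-squared", p = ct$p.value,
         statistic = unname(ct$statistic))
  } else {
    ft <- fisher.test(counts)
    list(test = "fisher", p = ft$p.value, statistic = NA_real_)
  }
}

#' Compare a continuous variable between two groups
#'
#' Student's t-test when a Shapiro-Wilk check (alpha = 0.05) passes in
#' both groups, Mann-Whitney U (Wilcoxon rank-sum) otherwise.
#'
#' @param x,y numeric samples, each of length at least 2.
#' @param normality_alpha level of the per-group normality check.
#' @param method `"auto"` (normality-driven choice, the default), or force
#'   `"t"` / `"mann-whitney"`.
#' @return list: `test`, `p`, `statistic`, plus per-group `summary`
#'   strings (mean +/- sd, or median (IQR) for the nonparametric branch).
#' @export
compare_continuous <- function(x, y, normality_alpha = 0.05,
                               method = c("auto", "t", "mann-whitney")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    warning("both groups are constant and equal; p = 1")
    return(list(test = "degenerate", p = 1, statistic = 0,
                summary = c(.summ_norm(x), .summ_norm(y))))
  }
  normal <- if (method == "auto")
    .normal_enough(x, normality_alpha) && .normal_enough(y, normality_alpha)
  else method == "t"
  if (normal) {
    tt <- t.test(x, y, var.equal = TRUE)
    list(test = "t-test", p = tt$p.value, statistic = unname(tt$statistic),
         summary = c(.summ_norm(x), .summ_norm(y)))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y))
    list(test = "mann-whitney", p = wt$p.value,
         statistic = unname(wt$statistic),
         summary = c(.summ_mediqr(x), .summ_mediqr(y)))
  }
}

.summ_norm <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
.summ_mediqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.2f (%.2f–%.2f)", q[2], q[1], q[3])
}

#' Paired pre/post comparison
#'
#' Paired t-test when the differences pass a Shapiro-Wilk normality check,
#' Wilcoxon signed-rank otherwise.
#'
#' @param pre,post paired numeric vectors of equal length (n >= 2).
#' @param normality_alpha level of the normality check on differences.
#' @param method `"auto"` (default), or force `"t"` / `"wilcoxon"`.
#' @return list: `test`, `p`, `statistic`.
#' @export
paired_comparison <- function(pre, post, normality_alpha = 0.05,
                              method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(test = "degenerate", p = 1, statistic = 0))
  }
  normal <- if (method == "auto") .normal_enough(d, normality_alpha) else
    method == "t"
  if (normal) {
    tt <- t.test(post, pre, paired = TRUE)
    list(test = "paired t-test", p = tt$p.value,
         statistic = unname(tt$statistic))
  } else {
    wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
    list(test = "wilcoxon signed-rank", p = wt$p.value,
         statistic = unname(wt$statistic))
  }
}

#' Test for HRV changes across dialysis phases
#'
#' Friedman test (default; robust for the skewed spectral powers) or
#' one-way repeated-measures ANOVA across the early/middle/late phase
#' values of one HRV parameter. Pairwise phase contrasts can be obtained
#' with [paired_comparison()].
#'
#' @param values numeric matrix, one row per subject and one column per
#'   phase (complete cases, n >= 3 subjects).
#' @param method `"friedman"` (default) or `"anova"` (repeated measures).
#' @return list: `test`, `p`, `statistic`.
#' @export
phase_trend_test <- function(values, method = c("friedman", "anova")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3, ncol(values) >= 2, !anyNA(values))
  if (all(apply(values, 1, function(r) length(unique(r)) == 1L))) {
    warning("all subjects are constant across phases; p = 1")
    return(list(test = method, p = 1, statistic = 0))
  }
  if (method == "friedman") {
    ft <- friedman.test(values)
    list(test = "friedman", p = ft$p.value, statistic = unname(ft$statistic))
  } else {
    n <- nrow(values)
    k <- ncol(values)
    df <- data.frame(value = as.vector(values),
                     phase = factor(rep(seq_len(k), each = n)),
                     subject = factor(rep(seq_len(n), k)))
    fit <- aov(value ~ phase + Error(subject / phase), data = df)
    tab <- summary(fit)[["Error: subject:phase"]][[1]]
    list(test = "rm-anova", p = tab[["Pr(>F)"]][1],
         statistic = tab[["F value"]][1])
  }
}

#' Group-comparison table (baseline-characteristics style)
#'
#' Builds a table of per-variable group contrasts: binary/categorical
#' variables via [compare_categorical()], continuous ones via
#' [compare_continuous()], with the display style (mean +/- sd vs
#' median (IQR)) following the test branch chosen.
#'
#' @param data data frame.
#' @param group name of a binary grouping column.
#' @param vars character vector of columns to compare; variables with at
#'   most 2 distinct values are treated as categorical.
#' @return data frame: `variable`, `group0`, `group1`, `test`, `p`.
#' @export
group_comparison_table <- function(data, group, vars) {
  g <- as.integer(as.logical(data[[group]]))
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (length(unique(x)) <= 2L) {
      tab <- table(factor(x, levels = sort(unique(x))), g)
      res <- compare_categorical(as.matrix(tab))
      npos <- tapply(x == max(x), g, sum)
      ntot <- tapply(x, g, length)
      summ <- sprintf("%d (%.1f%%)", npos, 100 * npos / ntot)
    } else {
      res <- compare_continuous(x[g == 0], x[g == 1])
      summ <- res$summary
    }
    data.frame(variable = v, group0 = summ[1], group1 = summ[2],
               test = res$test, p = res$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
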