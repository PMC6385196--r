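# ROC analysis of linear-predictor risk scores and DeLong's paired test
# for the difference of two correlated AUCs.

#' Area under the ROC curve (Mann-Whitney estimate)
#'
#' `AUC = (#concordant + 0.5 * #tied) / (n1 * n0)` over all
#' positive-negative pairs, computed via midranks so ties are handled
#' exactly.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' One operating point per distinct threshold plus the `(0,0)` and `(1,1)`
#' endpoints; the trapezoidal area under the returned curve equals
#' [roc_auc()] to within floating-point error (midranks and trapezoids
#' agree exactly in exact arithmetic).
#'
#' @inheritParams roc_auc
#' @return object of class `"roc_curve"`: data frame with `threshold`,
#'   `fpr` (1 - specificity), `tpr` (sensitivity); attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  df <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                   tpr = c(0, tpr))
  if (df$fpr[nrow(df)] != 1 || df$tpr[nrow(df)] != 1)
    df <- rbind(df, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(df$fpr) * (head(df$tpr, -1) + df$tpr[-1]) / 2)
  structure(df, auc = auc, class = c("roc_curve", "data.frame"))
}

#' @export
plot.roc_curve <- function(x, add = FALSE, ...) {
  if (add) {
    lines(x$fpr, x$tpr, ...)
  } else {
    plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - Specificity", ylab = "Sensitivity", ...)
    abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

# Midrank placement values: V10[i] = P-hat(score of positive i exceeds a
# random negative), V01[j] likewise for negatives.
.placements <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  n1 <- length(x)
  n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's paired test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores measured on the same subjects.
#' Per-subject placement values give structural components whose empirical
#' covariances yield the variance of the AUC difference;
#' `z = (AUC_a - AUC_b) / sqrt(var)` is referred to a two-sided standard
#' normal.
#'
#' @param scores_a,scores_b risk scores of the two models on the same
#'   subjects.
#' @param labels shared binary outcome labels.
#' @return object of class `"delong_test"`: `auc_a`, `auc_b`, `var_diff`,
#'   `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present")
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) > 1e-12)
      stop("degenerate pairing: zero variance with unequal AUCs")
    z <- 0
    p <- 1
    var_diff <- 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p = p, n1 = n1, n0 = n0),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat("DeLong's paired test for two correlated AUCs\n")
  cat(sprintf("AUC (model A): %.3f   AUC (model B): %.3f\n",
              x$auc_a, x$auc_b))
  cat(sprintf("z = %.3f, two-sided p = %.4g (n1 = %d, n0 = %d)\n",
              x$z, x$p, x$n1, x$n0))
  invisible(x)
}
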