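# Variable screening, collinearity diagnostics and the AUC-ranked search
# over HRV-augmented count models.

#' Univariate screening of count-model candidates
#'
#' Fits one intercept-plus-covariate NB2 model per candidate and selects
#' those with a two-sided Wald p below the threshold. Clinically mandated
#' variables can be force-included regardless of p (the study kept prior
#' coronary artery disease and congestive heart failure in the
#' multivariate model despite univariate p of 0.225 and 0.846).
#'
#' @param data data frame with the outcome and candidate columns.
#' @param candidates character vector of candidate column names.
#' @param outcome count outcome column name (default `"idh_count"`).
#' @param threshold selection threshold on the univariate p (default 0.10).
#' @param force character vector of columns always selected.
#' @return data frame (class `"univariate_screen"`) with one row per
#'   candidate: `variable`, `exp_b`, `lwr`, `upr`, `p`, `selected`,
#'   `forced`, `screenable`. Candidates whose univariate fit fails are
#'   flagged `screenable = FALSE`, never silently dropped.
#' @export
univariate_screen <- function(data, candidates, outcome = "idh_count",
                              threshold = 0.10, force = character()) {
  stopifnot(outcome %in% names(data))
  miss <- setdiff(c(candidates, force), names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  candidates <- union(candidates, force)
  rows <- lapply(candidates, function(v) {
    fit <- tryCatch(
      idh_nb(stats::reformulate(v, response = outcome), data = data),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(variable = v, exp_b = NA, lwr = NA, upr = NA,
                        p = NA, selected = v %in% force, forced = v %in% force,
                        screenable = FALSE))
    ec <- exp_coef(fit)[v, ]
    data.frame(variable = v, exp_b = ec$exp_b, lwr = ec$lwr, upr = ec$upr,
               p = ec$p,
               selected = (is.finite(ec$p) && ec$p < threshold) || v %in% force,
               forced = v %in% force, screenable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("univariate_screen", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of column `j` on all other columns (with intercept). Values
#' above 10 flag multicollinearity in the model-search stage; perfect
#' collinearity is reported as `Inf`.
#'
#' @param X numeric matrix or data frame of model covariates (no
#'   intercept column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) return(setNames(rep(1, p), colnames(X)))
  if (nrow(X) <= p + 1L)
    stop("need more rows (", nrow(X), ") than columns + 1 (", p + 1L, ")")
  out <- vapply(seq_len(p), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Search HRV-augmented count models ranked by discrimination
#'
#' Fits the clinical "basic" model and every augmentation of it with up to
#' `max_add` delta-HRV columns, excludes candidates with multicollinearity
#' (any VIF above `vif_bound`, or any pairwise correlation involving an
#' added column above `cor_bound` in absolute value), and ranks survivors
#' by the AUC of their linear predictor against the binary outcome
#' "at least one IDH event".
#'
#' @param data data frame with outcome and covariates.
#' @param basic character vector: the basic (clinical) model columns.
#' @param delta character vector: candidate delta-HRV columns.
#' @param outcome count outcome column name.
#' @param max_add maximum number of delta columns added (default 4).
#' @param vif_bound VIF exclusion bound (default 10).
#' @param cor_bound pairwise |correlation| exclusion bound for pairs
#'   involving an added column (default 0.8).
#' @param top number of augmented models reported (default 5).
#' @return object of class `"model_search"`: `table` (all candidates with
#'   `terms`, `aic`, `bic`, `auc`, `max_vif`, `excluded`, `reason`, and
#'   rank for survivors), `basic_fit`, `best_fit`, `top_fits`, `labels`.
#' @export
model_search <- function(data, basic, delta, outcome = "idh_count",
                         max_add = 4, vif_bound = 10, cor_bound = 0.8,
                         top = 5) {
  stopifnot(all(c(basic, delta, outcome) %in% names(data)))
  y <- data[[outcome]]
  labels <- as.integer(y >= 1)
  basic_fit <- idh_nb(stats::reformulate(basic, response = outcome), data)
  basic_auc <- roc_auc(basic_fit$linear_predictor, labels)

  subsets <- list(character())
  for (m in seq_len(min(max_add, length(delta))))
    subsets <- c(subsets, combn(delta, m, simplify = FALSE))

  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    add <- subsets[[i]]
    cols <- c(basic, add)
    label <- if (length(add)) paste(add, collapse = "+") else "(basic)"
    Xc <- as.matrix(data[cols])
    v <- tryCatch(vif(Xc), error = function(e) rep(Inf, length(cols)))
    max_vif <- max(v)
    reason <- ""
    excluded <- FALSE
    if (length(add)) {
      if (max_vif > vif_bound) {
        excluded <- TRUE
        reason <- sprintf("VIF %.1f > %g", max_vif, vif_bound)
      } else {
        cm <- abs(cor(Xc))
        diag(cm) <- 0
        # only pairs involving an added column can exclude a candidate
        cm_add <- cm[add, , drop = FALSE]
        if (any(cm_add > cor_bound)) {
          excluded <- TRUE
          reason <- sprintf("|r| %.2f > %g", max(cm_add), cor_bound)
        }
      }
    }
    if (excluded) {
      rows[[i]] <- data.frame(terms = label, aic = NA, bic = NA, auc = NA,
                              max_vif = max_vif, excluded = TRUE,
                              reason = reason)
      next
    }
    fit <- tryCatch(idh_nb(stats::reformulate(cols, response = outcome),
                           data),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(terms = label, aic = NA, bic = NA, auc = NA,
                              max_vif = max_vif, excluded = TRUE,
                              reason = paste("fit failed:",
                                             conditionMessage(fit)))
      next
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(terms = label, aic = fit$aic, bic = fit$bic,
                            auc = roc_auc(fit$linear_predictor, labels),
                            max_vif = max_vif, excluded = FALSE,
                            reason = "")
  }
  tab <- do.call(rbind, rows)
  tab$rank <- NA_integer_
  ok <- which(!tab$excluded)
  tab$rank[ok] <- rank(-tab$auc[ok], ties.method = "first")
  tab <- tab[order(tab$excluded, tab$rank), ]
  rownames(tab) <- NULL

  surv_aug <- which(!tab$excluded & tab$terms != "(basic)")
  if (!length(surv_aug) && length(delta))
    warning("no augmented model survived the collinearity screen; ",
            "only the basic model is reported")
  ord <- order(tab$rank)
  keep_terms <- head(tab$terms[!tab$excluded & tab$terms != "(basic)"], top)
  all_terms <- vapply(seq_along(subsets), function(i)
    if (length(subsets[[i]])) paste(subsets[[i]], collapse = "+") else
      "(basic)", character(1))
  top_fits <- fits[match(keep_terms, all_terms)]
  names(top_fits) <- keep_terms
  best_fit <- if (length(top_fits)) top_fits[[1]] else basic_fit

  structure(list(table = tab, basic_fit = basic_fit, basic_auc = basic_auc,
                 best_fit = best_fit, top_fits = top_fits,
                 labels = labels),
            class = "model_search")
}

#' @export
print.model_search <- function(x, n = 6, ...) {
  cat("Count-model search ranked by linear-predictor AUC\n")
  cat(sprintf("Basic model AUC: %.3f\n", x$basic_auc))
  shown <- head(x$table[!x$table$excluded, c("rank", "terms", "auc",
                                             "aic", "bic", "max_vif")], n)
  print(shown, row.names = FALSE, digits = 4)
  nex <- sum(x$table$excluded)
  if (nex) cat(nex, "candidate(s) excluded for collinearity or fit failure\n")
  invisible(x)
}
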