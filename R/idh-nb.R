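# Negative-binomial (NB2) regression of monthly IDH counts.
#
# The model: count_i ~ NegBin(mu_i, alpha) with log link
# log mu_i = x_i' beta and variance mu_i + alpha mu_i^2. beta and alpha
# are estimated jointly by maximum likelihood (alpha on the log scale),
# with Wald covariance from the observed information at the optimum. No
# exposure offset is used: every patient contributes the same 12 sessions
# per month, so a log-exposure term is constant and absorbed by the
# intercept.

# NB2 log-likelihood and gradient in theta = c(beta, log(alpha))
.nb2_nll <- function(theta, y, X) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  alpha <- exp(theta[p + 1L])
  eta <- drop(X %*% beta)
  if (any(eta > 500)) return(1e10)
  mu <- exp(eta)
  r <- 1 / alpha
  -sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
         y * log(alpha * mu) - (y + r) * log1p(alpha * mu))
}

.nb2_grad <- function(theta, y, X) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  la <- theta[p + 1L]
  alpha <- exp(la)
  eta <- drop(X %*% beta)
  if (any(eta > 500)) return(rep(0, p + 1L))
  mu <- exp(eta)
  r <- 1 / alpha
  w <- (y - mu) / (1 + alpha * mu)
  g_beta <- drop(crossprod(X, w))
  dl_dalpha <- sum(-r^2 * (digamma(y + r) - digamma(r)) + y / alpha +
                     r^2 * log1p(alpha * mu) - (y + r) * mu / (1 + alpha * mu))
  -c(g_beta, alpha * dl_dalpha)
}

#' Fit a negative-binomial model of IDH frequency
#'
#' Fits the NB2 count regression `count ~ NegBin(exp(X beta), alpha)` by
#' joint maximum likelihood over the regression coefficients and the
#' dispersion. The per-patient linear predictor `eta = X beta-hat` is kept
#' on the object for downstream use as a continuous risk score in ROC
#' analysis.
#'
#' @param formula model formula; the response is a nonnegative integer
#'   count (monthly IDH events).
#' @param data data frame containing the variables.
#' @param ... passed to [idh_nb_fit()].
#' @return an object of class `"idh_nb"`; see [idh_nb_fit()] for its
#'   components. Supports `print`, `summary`, `coef`, `vcov`, `logLik`,
#'   `AIC`/`BIC`, `predict`, `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' fit <- idh_nb(idh_count ~ dm + age10 + ufr, data = coh)
#' summary(fit)
#' @export
idh_nb <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- idh_nb_fit(y, X, ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @rdname idh_nb
#' @param y nonnegative integer count vector.
#' @param X design matrix (including an intercept column if wanted).
#' @param alpha_init initial dispersion (default: method-of-moments from a
#'   Poisson start, floored at 0.01).
#' @param tol gradient-norm convergence tolerance.
#' @param maxit maximum optimizer iterations.
#' @export
idh_nb_fit <- function(y, X, alpha_init = NULL, tol = 1e-4, maxit = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (any(y < 0) || any(y != round(y)))
    stop("response must be a nonnegative integer count")
  if (all(y == 0)) stop("all counts are zero; the NB mean is degenerate")
  if (n <= p) stop("need more observations (", n, ") than parameters (",
                   p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }

  pois <- suppressWarnings(glm.fit(X, y, family = poisson()))
  beta <- pois$coefficients
  mu <- pmax(pois$fitted.values, 1e-10)
  if (is.null(alpha_init)) {
    # moment estimate from Poisson-fit residuals
    a <- sum((y - mu)^2 - mu) / sum(mu^2)
    alpha_init <- min(max(a, 1e-6), 1e3)
  }
  la <- log(alpha_init)
  la_range <- c(-25, 10)

  # Alternate: IRLS (Fisher scoring) for beta given alpha, 1-D profile
  # maximization for log(alpha) given beta. Both steps increase the
  # likelihood; the alternation is stable at the Poisson boundary.
  irls_beta <- function(beta, alpha) {
    for (it in 1:50) {
      eta <- drop(X %*% beta)
      mu <- exp(pmin(eta, 500))
      w <- mu / (1 + alpha * mu)
      score <- drop(crossprod(X, (y - mu) / (1 + alpha * mu)))
      XtWX <- crossprod(X * sqrt(w))
      step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
      if (is.null(step)) {
        # quasi-separated indicators drive their weights to zero; a tiny
        # ridge keeps the scoring step defined while the likelihood
        # flattens toward its boundary optimum
        ridge <- diag(1e-8 * max(diag(XtWX), 1), ncol(X))
        step <- tryCatch(solve(XtWX + ridge, score), error = function(e)
          stop("NB fit failed: singular weighted information"))
      }
      # step-halving to guarantee the likelihood never decreases
      nll0 <- .nb2_nll(c(beta, log(alpha)), y, X)
      h <- 1
      repeat {
        cand <- beta + h * step
        if (.nb2_nll(c(cand, log(alpha)), y, X) <= nll0 + 1e-12 || h < 1e-6)
          break
        h <- h / 2
      }
      beta_new <- beta + h * step
      if (max(abs(beta_new - beta)) < 1e-10) return(beta_new)
      beta <- beta_new
    }
    beta
  }
  nll <- .nb2_nll(c(beta, la), y, X)
  for (outer in seq_len(maxit)) {
    beta <- irls_beta(beta, exp(la))
    op <- optimize(function(l) .nb2_nll(c(beta, l), y, X),
                   interval = la_range, tol = 1e-9)
    la <- op$minimum
    nll_new <- op$objective
    if (abs(nll - nll_new) < 1e-10 && outer > 1) break
    nll <- nll_new
  }
  par <- c(beta, la)
  grad <- .nb2_grad(par, y, X)
  at_bound <- la <= la_range[1] + 1e-3 || la >= la_range[2] - 1e-3
  # at the Poisson boundary the dispersion gradient is one-sided
  gnorm <- if (at_bound) sqrt(sum(grad[seq_len(p)]^2)) else
    sqrt(sum(grad^2))
  if (!is.finite(nll) || gnorm > max(tol, tol * sqrt(n)))
    stop("NB fit did not converge after ", maxit,
         " outer iterations (gradient norm ", signif(gnorm, 3), ")")

  names(beta) <- colnames(X)
  alpha <- exp(la)
  H <- optimHess(par, .nb2_nll, .nb2_grad, y = y, X = X)
  # near-singular information (quasi-separated indicators, boundary
  # dispersion) gets a minimal ridge: the flat directions then carry very
  # large, finite variances instead of aborting the fit
  safe_inv <- function(M) {
    tryCatch(solve(M), error = function(e) {
      lam <- 1e-10 * max(abs(diag(M)), 1)
      solve(M + diag(lam, nrow(M)))
    })
  }
  vc_full <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc_full) || any(!is.finite(diag(vc_full))) ||
      any(diag(vc_full)[seq_len(p)] < 0)) {
    # dispersion at/near the Poisson boundary: invert the beta block only
    vc_beta <- safe_inv(H[seq_len(p), seq_len(p), drop = FALSE])
    vc_alpha <- NA_real_
  } else {
    vc_beta <- vc_full[seq_len(p), seq_len(p), drop = FALSE]
    vc_alpha <- vc_full[p + 1L, p + 1L]
  }
  vc_beta <- (vc_beta + t(vc_beta)) / 2
  dimnames(vc_beta) <- list(names(beta), names(beta))

  ll <- -nll
  k <- p + 1L  # beta terms plus the dispersion
  eta <- drop(X %*% beta)
  structure(list(coefficients = beta,
                 alpha = alpha,
                 vcov = vc_beta,
                 vcov_log_alpha = vc_alpha,
                 logLik = ll,
                 n = n, k = k,
                 aic = -2 * ll + 2 * k,
                 bic = -2 * ll + k * log(n),
                 linear_predictor = eta,
                 fitted = exp(eta),
                 y = y, X = X,
                 iterations = outer,
                 converged = TRUE,
                 call = match.call()),
            class = "idh_nb")
}

#' @export
print.idh_nb <- function(x, digits = 4, ...) {
  cat("Negative-binomial (NB2) model of monthly IDH counts\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Dispersion alpha: %.*g   logLik: %.*g   AIC: %.*g   BIC: %.*g\n",
              digits, x$alpha, digits, x$logLik, digits, x$aic,
              digits, x$bic))
  invisible(x)
}

#' @export
coef.idh_nb <- function(object, ...) object$coefficients

#' @export
vcov.idh_nb <- function(object, ...) object$vcov

#' @export
logLik.idh_nb <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.idh_nb <- function(object, ...) object$fitted

#' @export
summary.idh_nb <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  p <- 2 * pnorm(-abs(z))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = p)
  structure(list(coefficients = tab,
                 exp_coef = exp_coef(object, level = level),
                 alpha = object$alpha,
                 logLik = object$logLik, aic = object$aic,
                 bic = object$bic, n = object$n),
            class = "summary.idh_nb")
}

#' @export
print.summary.idh_nb <- function(x, ...) {
  cat("Negative-binomial (NB2) model of monthly IDH counts\n\n")
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nDispersion alpha: %.4g (n = %d)\n", x$alpha, x$n))
  cat(sprintf("logLik %.3f, AIC %.2f, BIC %.2f\n", x$logLik, x$aic, x$bic))
  invisible(x)
}

#' Exponentiated coefficients (rate ratios) with Wald intervals
#'
#' `Exp(B) = exp(beta-hat)` per unit of each covariate's reporting scale,
#' with `exp(beta-hat +/- z * SE)` confidence limits and two-sided Wald
#' p-values.
#'
#' @param fit an `idh_nb` fit.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `exp_b`, `lwr`, `upr`, `z`, `p`; rows
#'   with a non-finite standard error have `NA` limits.
#' @export
exp_coef <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "idh_nb"))
  se <- sqrt(diag(fit$vcov))
  zq <- qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  ok <- is.finite(se)
  out <- data.frame(exp_b = exp(b),
                    lwr = ifelse(ok, exp(b - zq * se), NA_real_),
                    upr = ifelse(ok, exp(b + zq * se), NA_real_),
                    z = ifelse(ok, b / se, NA_real_),
                    p = ifelse(ok, 2 * pnorm(-abs(b / se)), NA_real_))
  rownames(out) <- names(b)
  out
}

#' @export
predict.idh_nb <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictor
  } else {
    if (is.matrix(newdata)) {
      X <- newdata
    } else if (!is.null(object$terms)) {
      X <- stats::model.matrix(stats::delete.response(object$terms),
                               newdata)
    } else {
      X <- as.matrix(newdata)
    }
    want <- colnames(object$X)
    missing <- setdiff(want, colnames(X))
    extra <- setdiff(colnames(X), want)
    if (length(missing) || length(extra))
      stop("column mismatch; missing: [",
           paste(missing, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]")
    eta <- drop(X[, want, drop = FALSE] %*% object$coefficients)
  }
  if (type == "link") eta else exp(eta)
}

#' @export
residuals.idh_nb <- function(object,
                             type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "response") return(r)
  r / sqrt(object$fitted + object$alpha * object$fitted^2)
}

#' @export
simulate.idh_nb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, rnbinom(object$n,
                                               size = 1 / object$alpha,
                                               mu = object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.idh_nb <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "Fitted mean monthly IDH count",
       ylab = "Observed count",
       main = "NB2 fit: observed vs fitted", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Per-patient linear-predictor risk score
#'
#' Convenience wrapper around `predict(fit, newdata, type = "link")`; the
#' linear predictor of the count model is the continuous risk score used
#' for ROC/AUC analysis of IDH occurrence.
#'
#' @param fit an `idh_nb` fit.
#' @param newdata optional data frame or design matrix.
#' @return numeric vector of risk scores.
#' @export
linear_predictor <- function(fit, newdata = NULL) {
  predict(fit, newdata = newdata, type = "link")
}
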