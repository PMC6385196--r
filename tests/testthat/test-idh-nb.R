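test_that("intercept-only MLE is the log mean", {
  fit <- idh_nb_fit(rep(3L, 50), matrix(1, 50, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(coef(fit)), log(3), tolerance = 1e-8)
  expect_equal(unname(fitted(fit)[1]), 3, tolerance = 1e-7)
})

test_that("the NB2 fit agrees with an independent ML implementation", {
  skip_if_not_installed("MASS")
  coh <- suppressWarnings(generate_cohort(cohort_config(n_patients = 500,
                                                        seed = 11)))
  form <- idh_count ~ dm + cad + chf + age10 + ufr + ipth100 +
    arb_acei + ccb + bblocker
  fit <- idh_nb(form, data = coh)
  ref <- MASS::glm.nb(form, data = coh)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(fit$alpha, 1 / ref$theta, tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-9)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-8)
  expect_equal(fit$bic, BIC(ref), tolerance = 1e-8)
  expect_equal(sqrt(diag(vcov(fit))), sqrt(diag(vcov(ref))),
               tolerance = 0.05)
})

test_that("AIC and BIC follow from logLik, k and n by direct arithmetic", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_patients = 120,
                                                        seed = 2)))
  fit <- idh_nb(idh_count ~ dm + ufr, data = coh)
  k <- length(coef(fit)) + 1  # dispersion counts as a parameter
  expect_equal(fit$aic, -2 * fit$logLik + 2 * k)
  expect_equal(fit$bic, -2 * fit$logLik + k * log(fit$n))
  expect_equal(AIC(fit), fit$aic)
  expect_equal(BIC(fit), fit$bic)
})

test_that("the likelihood at the optimum dominates the truth", {
  cfg <- cohort_config(n_patients = 300, covariates = cov3,
                       true_beta = beta3, true_dispersion = 0.8, seed = 44)
  coh <- suppressWarnings(generate_cohort(cfg))
  fit <- idh_nb(idh_count ~ dm + age10 + ufr, data = coh)
  nll_truth <- hrvidh:::.nb2_nll(c(beta3, log(0.8)), coh$idh_count, fit$X)
  expect_gte(fit$logLik, -nll_truth)
})

test_that("Poisson-generated data drive the dispersion to zero", {
  cfg <- cohort_config(n_patients = 2000, covariates = cov3,
                       true_beta = beta3, true_dispersion = 1e-9, seed = 3)
  coh <- suppressWarnings(generate_cohort(cfg))
  fit <- idh_nb(idh_count ~ dm + age10 + ufr, data = coh)
  ref <- glm(idh_count ~ dm + age10 + ufr, data = coh, family = poisson())
  expect_lt(max(abs(coef(fit) - coef(ref))), 1e-3)
  expect_lt(fit$alpha, 1e-4)
})

test_that("degenerate inputs raise informative errors", {
  X <- cbind(`(Intercept)` = 1, a = rnorm(20))
  expect_error(idh_nb_fit(rep(0L, 20), X), "zero")
  expect_error(idh_nb_fit(c(rep(1L, 19), -1L), X), "nonnegative")
  Xr <- cbind(X, b = X[, "a"])
  expect_error(idh_nb_fit(rpois(20, 2), Xr), "b")
  expect_error(idh_nb_fit(rpois(3, 2), cbind(1, rnorm(3), rnorm(3), rnorm(3))),
               "more observations")
})

test_that("exponentiated coefficients follow the Wald formulas", {
  fake <- structure(list(coefficients = c(x = 0),
                         vcov = matrix(0.01, dimnames = list("x", "x"))),
                    class = "idh_nb")
  ec <- exp_coef(fake)
  expect_equal(ec$exp_b, 1)
  expect_equal(ec$lwr, exp(-1.959964 * 0.1), tolerance = 1e-6)
  expect_equal(ec$upr, exp(1.959964 * 0.1), tolerance = 1e-6)
  expect_equal(round(ec$lwr, 2), 0.82)
  expect_equal(round(ec$upr, 2), 1.22)

  coh <- suppressWarnings(generate_cohort(cohort_config(n_patients = 200,
                                                        seed = 6)))
  fit <- idh_nb(idh_count ~ dm + ufr, data = coh)
  ec <- exp_coef(fit)
  expect_true(all(ec$lwr <= ec$exp_b & ec$exp_b <= ec$upr))
  # the printed DM interval (1.16-4.22) around 2.22 implies SE ~ 0.329
  expect_equal((log(4.22) - log(1.16)) / (2 * qnorm(0.975)), 0.3294,
               tolerance = 1e-3)
})

test_that("the linear predictor is a faithful matrix product", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_patients = 150,
                                                        seed = 9)))
  fit <- idh_nb(idh_count ~ dm + age10 + ufr, data = coh)
  eta_rowwise <- apply(fit$X, 1, function(r) sum(r * coef(fit)))
  expect_equal(unname(fit$linear_predictor), unname(eta_rowwise),
               tolerance = 1e-12)
  expect_equal(linear_predictor(fit), predict(fit, type = "link"))

  # doubling a positive-coefficient covariate strictly increases eta
  stopifnot(coef(fit)[["ufr"]] > 0)
  nd <- coh
  nd$ufr <- nd$ufr * 2
  expect_true(all(predict(fit, nd) > fit$linear_predictor |
                    coh$ufr <= 0))

  bad <- coh
  names(bad)[names(bad) == "ufr"] <- "ufr_kg"
  expect_error(predict(fit, bad[, c("dm", "age10", "ufr_kg")]), "ufr")

  Xbad <- fit$X[, 1:2]
  expect_error(predict(fit, Xbad), "missing")
})

test_that("simulate and residuals round-trip the fitted model", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_patients = 400,
                                                        seed = 13)))
  fit <- idh_nb(idh_count ~ dm + ufr + age10, data = coh)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(400, 3))
  expect_true(all(sims >= 0))
  r <- residuals(fit)
  expect_equal(residuals(fit, "response"), coh$idh_count - fitted(fit))
  # Pearson residuals should have roughly unit variance under NB2
  expect_gt(var(r), 0.6)
  expect_lt(var(r), 1.6)
})
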