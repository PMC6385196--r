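make_screen_cohort <- function(n = 150, seed = 1) {
  set.seed(seed)
  coh <- suppressWarnings(generate_cohort(cohort_config(
    n_patients = n, covariates = cov3, true_beta = beta3,
    true_dispersion = 0.8, seed = seed)))
  coh$noise <- rnorm(n)
  coh$strong <- log(coh$idh_count + 1) + rnorm(n, 0, 0.1)
  coh
}

test_that("univariate screening selects by p < 0.10 and honors the force list", {
  coh <- make_screen_cohort(300, seed = 4)
  sc <- univariate_screen(coh, candidates = c("ufr", "noise", "strong"),
                          force = c("dm", "age10"))
  expect_s3_class(sc, "univariate_screen")
  expect_true(all(c("dm", "age10") %in% sc$variable[sc$selected]))
  expect_true(all(sc$forced[sc$variable %in% c("dm", "age10")]))
  expect_true(sc$selected[sc$variable == "strong"])  # power sanity
  expect_true(sc$p[sc$variable == "ufr"] < 0.10)
})

test_that("a pure-noise column is selected at roughly the nominal 10% rate", {
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    coh <- suppressWarnings(generate_cohort(cohort_config(
      n_patients = 150, covariates = cov3, true_beta = beta3,
      true_dispersion = 0.8, seed = 1000 + r)))
    coh$noise <- rnorm(150)
    fit <- idh_nb(idh_count ~ noise, data = coh)
    hits <- hits + (exp_coef(fit)["noise", "p"] < 0.10)
  }
  rate <- hits / reps
  # binomial(200, 0.10) 3-sigma band
  expect_gt(rate, 0.10 - 3 * sqrt(0.1 * 0.9 / reps))
  expect_lt(rate, 0.10 + 3 * sqrt(0.1 * 0.9 / reps))
})

test_that("unscreenable candidates are flagged, not dropped", {
  coh <- make_screen_cohort(100, seed = 7)
  coh$allsame <- 1  # constant column: rank-deficient with the intercept
  sc <- univariate_screen(coh, candidates = c("ufr", "allsame"))
  expect_false(sc$screenable[sc$variable == "allsame"])
  expect_equal(nrow(sc), 2)
})

test_that("VIF matches its definition on constructed designs", {
  set.seed(10)
  n <- 200
  # columns orthogonal to each other and to the intercept -> VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  colnames(Q) <- c("a", "b", "c")
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)

  # exact linear dependence -> infinite VIF
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  X <- cbind(X, x3 = X[, 1] + X[, 2])
  expect_true(any(is.infinite(vif(X))))

  # brute-force R^2 oracle on a correlated pair
  z <- rnorm(n)
  pair <- cbind(u = z + rnorm(n, 0, 0.5), v = z + rnorm(n, 0, 0.5))
  r2 <- summary(lm(pair[, 1] ~ pair[, 2]))$r.squared
  expect_equal(unname(vif(pair))[1], 1 / (1 - r2), tolerance = 1e-10)
})

test_that("VIF agrees with the car implementation on a fitted design", {
  skip_if_not_installed("car")
  coh <- make_screen_cohort(200, seed = 3)
  X <- as.matrix(coh[, c("dm", "age10", "ufr", "noise")])
  ref <- car::vif(lm(idh_count ~ dm + age10 + ufr + noise, data = coh))
  expect_equal(vif(X), ref[colnames(X)], tolerance = 1e-8)
})

test_that("model search returns only the basic model when no deltas offered", {
  coh <- make_screen_cohort(150, seed = 5)
  ms <- model_search(coh, basic = c("dm", "age10", "ufr"),
                     delta = character())
  expect_equal(nrow(ms$table), 1)
  expect_equal(ms$table$terms, "(basic)")
  expect_equal(ms$basic_auc,
               roc_auc(ms$basic_fit$linear_predictor, coh$idh_count >= 1))
})

test_that("duplicated columns are excluded by the collinearity screen", {
  coh <- make_screen_cohort(150, seed = 6)
  coh$d_tp <- rnorm(150)
  coh$d_tp_copy <- coh$d_tp
  ms <- model_search(coh, basic = c("dm", "age10", "ufr"),
                     delta = c("d_tp", "d_tp_copy"), max_add = 2)
  tab <- ms$table
  dup <- tab[grepl("d_tp\\+d_tp_copy", tab$terms), ]
  expect_true(all(dup$excluded))
  expect_false(tab$excluded[tab$terms == "d_tp"])
  # excluded candidates are never ranked
  expect_true(all(is.na(tab$rank[tab$excluded])))
  ranked <- tab[!tab$excluded, ]
  expect_true(all(diff(ranked$auc[order(ranked$rank)]) <= 1e-12))
})

test_that("an informative delta column rises to the top of the search", {
  set.seed(77)
  coh <- make_screen_cohort(250, seed = 77)
  # construct a delta covariate that truly enters the rate
  coh$d_hf <- rnorm(250, 0, 2)
  mu <- exp(beta3[["(Intercept)"]] + beta3[["dm"]] * coh$dm +
              beta3[["age10"]] * coh$age10 + beta3[["ufr"]] * coh$ufr +
              log(0.6) * coh$d_hf)
  coh$idh_count <- rnbinom(250, size = 1 / 0.8, mu = mu)
  coh$d_noise <- rnorm(250)
  ms <- model_search(coh, basic = c("dm", "age10", "ufr"),
                     delta = c("d_hf", "d_noise"), max_add = 2)
  best <- ms$table[which.min(ms$table$rank), ]
  expect_match(best$terms, "d_hf")
  expect_gt(best$auc, ms$basic_auc)
})
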