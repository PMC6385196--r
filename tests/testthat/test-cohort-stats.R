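test_that("printed drug-use contrasts reproduce to three decimals", {
  # ARB/ACEI use: 34 of 43 non-IDH vs 15 of 28 IDH patients
  arb <- compare_categorical(matrix(c(34, 9, 15, 13), nrow = 2))
  expect_equal(arb$test, "chi-squared")
  expect_equal(round(arb$p, 3), 0.023)
  # CCB use: 29 of 43 vs 12 of 28
  ccb <- compare_categorical(matrix(c(29, 14, 12, 16), nrow = 2))
  expect_equal(round(ccb$p, 3), 0.040)
})

test_that("the expected-count rule switches between chi-square and Fisher", {
  big <- matrix(c(30, 30, 30, 30), nrow = 2)
  expect_equal(compare_categorical(big)$test, "chi-squared")
  expect_equal(compare_categorical(big)$p, 1)
  small <- matrix(c(8, 1, 2, 6), nrow = 2)
  res <- compare_categorical(small)
  expect_equal(res$test, "fisher")
  expect_equal(res$p, fisher.test(small)$p.value)
  expect_error(compare_categorical(matrix(c(0, 0, 3, 4), nrow = 2)),
               "margin")
  expect_error(compare_categorical(matrix(c(1.5, 2, 3, 4), nrow = 2)),
               "integer")
})

test_that("identical continuous samples give p = 1", {
  set.seed(1)
  x <- rnorm(30)
  res <- compare_continuous(x, x)
  expect_equal(res$p, 1)
})

test_that("a large location shift is detected by both branches", {
  set.seed(2)
  x <- rnorm(50)
  y <- x + 5
  expect_lt(compare_continuous(x, y, method = "t")$p, 1e-6)
  expect_lt(compare_continuous(x, y, method = "mann-whitney")$p, 1e-6)
})

test_that("Mann-Whitney agrees with exhaustive rank enumeration", {
  x <- c(1, 2, 3)
  y <- c(4, 5, 6)
  res <- compare_continuous(x, y, method = "mann-whitney")
  # enumerate all C(6,3) assignments of ranks to group x
  combs <- combn(6, 3)
  stat <- apply(combs, 2, function(idx) sum(idx) - 3 * 4 / 2)  # U of group x
  obs <- sum(rank(c(x, y))[1:3]) - 3 * 4 / 2
  p_exact <- mean(stat <= obs) + mean(stat >= 9 - obs)  # two-sided, U' = n1*n0 - U
  expect_equal(res$p, p_exact)
})

test_that("paired comparisons detect shifts and respect degeneracy", {
  set.seed(3)
  pre <- rnorm(40)
  expect_warning(res0 <- paired_comparison(pre, pre), "zero")
  expect_equal(res0$p, 1)
  shift <- pre + 3 + rnorm(40, 0, 0.1)
  expect_lt(paired_comparison(pre, shift, method = "t")$p, 1e-6)
  expect_lt(paired_comparison(pre, shift, method = "wilcoxon")$p, 1e-6)
})

test_that("Wilcoxon signed-rank agrees with exhaustive sign flips", {
  pre <- c(0, 0, 0, 0)
  post <- c(1, -2, 3, -4)
  res <- paired_comparison(pre, post, method = "wilcoxon")
  d <- post - pre
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  flips <- expand.grid(rep(list(c(0, 1)), 4))
  wplus <- as.matrix(flips) %*% r
  ew <- sum(r) / 2
  p_exact <- mean(abs(wplus - ew) >= abs(obs - ew))
  expect_equal(res$p, p_exact)
})

test_that("phase trend tests behave across constant and trending data", {
  const <- matrix(5, nrow = 6, ncol = 3)
  expect_warning(res <- phase_trend_test(const), "constant")
  expect_equal(res$p, 1)

  # strictly increasing triples: Friedman statistic is maximal (2n for k=3)
  set.seed(4)
  inc <- t(replicate(10, sort(rnorm(3))))
  res <- phase_trend_test(inc)
  expect_equal(res$statistic, 20)
  expect_equal(res$statistic,
               unname(friedman.test(inc)$statistic))
  expect_lt(res$p, 0.001)

  # repeated-measures ANOVA branch on the same data
  res2 <- phase_trend_test(inc, method = "anova")
  expect_lt(res2$p, 0.01)
})

test_that("a rise-then-fall HF pattern is detected with high power at n = 43", {
  set.seed(5)
  reps <- 100
  hits <- 0
  for (r in seq_len(reps)) {
    n <- 43
    base <- rlnorm(n, log(300), 0.6)
    vals <- cbind(early = base * rlnorm(n, 0, 0.25),
                  middle = base * 1.8 * rlnorm(n, 0, 0.25),
                  late = base * 1.2 * rlnorm(n, 0, 0.25))
    hits <- hits + (phase_trend_test(vals)$p < 0.05)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("the group-comparison table mixes categorical and continuous rows", {
  set.seed(6)
  df <- data.frame(grp = rep(c(0, 1), each = 30),
                   drug = rbinom(60, 1, 0.5),
                   age = rnorm(60, 55, 10))
  tab <- group_comparison_table(df, "grp", c("drug", "age"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_match(tab$group0[tab$variable == "drug"], "%")
})
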