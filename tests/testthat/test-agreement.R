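# Independent oracle: ICC(2,1) from a two-way ANOVA fitted with stats::aov
# on long-format data, plus the textbook mean-square combination.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ subj + rater, data = long)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("identical columns give ICC exactly 1", {
  x <- c(1.2, 0.9, 1.4, 1.1, 1.3)
  r <- icc_2_1(x, x)
  expect_equal(r$estimate, 1)
  expect_equal(r$ci_lower, 1)
})

test_that("a constant offset between methods matches the ANOVA oracle", {
  m <- cbind(1:4, 2:5)
  r <- icc_2_1(m)
  expect_equal(r$estimate, icc_oracle(m), tolerance = 1e-10)
  # absolute agreement penalises the offset: estimate below 1
  expect_lt(r$estimate, 1)
})

test_that("ICC matches the brute-force oracle on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    base <- rnorm(n, sd = runif(1, 0.5, 2))
    m <- cbind(base + rnorm(n, sd = 0.3), base + rnorm(n, sd = 0.3) + rnorm(1, 0, 0.2))
    r <- icc_2_1(m)
    expect_equal(r$estimate, icc_oracle(m), tolerance = 1e-10)
    # column swap leaves the absolute-agreement estimate unchanged
    expect_equal(icc_2_1(m[, 2:1])$estimate, r$estimate, tolerance = 1e-12)
    expect_lte(r$estimate, 1)
    expect_lte(r$ci_lower, r$estimate + 1e-12)
    expect_gte(r$ci_upper, r$estimate - 1e-12)
  }
})

test_that("ICC is invariant to adding a common constant and flags degeneracy", {
  set.seed(5)
  m <- cbind(rnorm(10), rnorm(10))
  expect_equal(icc_2_1(m + 100)$estimate, icc_2_1(m)$estimate, tolerance = 1e-8)
  expect_error(icc_2_1(cbind(rep(1, 5), rep(1, 5))), "degenerate")
  expect_error(icc_2_1(cbind(1:2, 1:2)), "at least 3")
})

test_that("correlation suite reproduces closed-form cases", {
  r1 <- correlation_suite(1:6, c(2, 3, 5, 8, 9, 14))
  expect_equal(r1$spearman_rho, 1)
  r2 <- correlation_suite(c(1, 2, 1.5), c(2, 1, 1.5))
  expect_equal(r2$pearson_r, -1)
  set.seed(33)
  a <- rnorm(20); b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(20)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlation_suite(a, b)$pearson_r, direct, tolerance = 1e-12)
  flat <- correlation_suite(rep(1, 5), rnorm(5))
  expect_true(flat$undefined)
  expect_true(is.na(flat$pearson_r))
})

test_that("Bland-Altman statistics match hand-computed values", {
  x <- c(1, 2, 3)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)

  a <- c(0.9, 1.1, 1.2); b <- a - c(-0.1, 0.1, 0.1)
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_diff, 1 / 30, tolerance = 1e-10)
  expect_equal(ba$sd_diff, sd(c(-0.1, 0.1, 0.1)), tolerance = 1e-12)
  expect_equal(ba$loa_lower, 1 / 30 - 1.96 * sd(c(-0.1, 0.1, 0.1)), tolerance = 1e-10)
  expect_equal(ba$loa_upper, 1 / 30 + 1.96 * sd(c(-0.1, 0.1, 0.1)), tolerance = 1e-10)
  # antisymmetry under argument swap
  expect_equal(bland_altman(b, a)$mean_diff, -ba$mean_diff)
})

test_that("absolute differences reproduce the worked table values", {
  expect_equal(absolute_difference(1.156, 1.152), 0.004)
  expect_equal(absolute_difference(1.096, 1.079), 0.017)
  expect_equal(absolute_difference(0.42, 0.42), 0)
  expect_error(absolute_difference(NA, 1), "finite")
})

test_that("agreement categories follow the printed bins, gaps resolved downward", {
  expect_equal(classify_agreement(0.730), "substantial")
  expect_equal(classify_agreement(0.987), "very_good")
  expect_equal(classify_agreement(0.30), "none")
  expect_equal(classify_agreement(0.305), "none")
  expect_equal(classify_agreement(0.505), "fair")
  expect_equal(classify_agreement(0.705), "moderate")
  expect_equal(classify_agreement(0.905), "substantial")
  expect_equal(classify_agreement(0.91), "very_good")
  expect_equal(classify_agreement(-0.4), "none")
  expect_error(classify_agreement(1.2), "\\[-1, 1\\]")
})

test_that("the bundled agreement summary is internally consistent", {
  set.seed(8)
  a <- rnorm(15, 1.1, 0.1); b <- a + rnorm(15, 0.01, 0.02)
  ag <- agreement_summary(a, b)
  expect_equal(ag$ad_of_means, abs(mean(a) - mean(b)))
  expect_lte(ag$icc_lower, ag$icc)
  expect_gte(ag$icc_upper, ag$icc)
  expect_lte(ag$bland_altman$loa_lower, ag$bland_altman$mean_diff)
  expect_equal(ag$category, classify_agreement(ag$icc))
  fit <- lm(b ~ a)
  expect_equal(ag$regression$slope, unname(coef(fit)[2]))
})
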