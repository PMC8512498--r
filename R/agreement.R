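#' Single-measure absolute-agreement intraclass correlation, ICC(2,1)
#'
#' Two-way ANOVA decomposition with subjects as rows and the two methods as
#' columns: with `MSR` (between-subject), `MSC` (between-method) and `MSE`
#' (residual) mean squares and k = 2 methods,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The 95 percent confidence interval follows the F-based procedure of
#' McGraw and Wong for the absolute-agreement single-measure coefficient
#' (ICC(A,1)); the p value is from the F test of between-subject variance
#' against residual (`F = MSR/MSE` on n-1 and (n-1)(k-1) df), the test
#' conventionally reported alongside this coefficient.  The estimate may be
#' negative.
#'
#' @param a1,a2 Paired per-subject values from the two methods, equal
#'   length >= 3; alternatively `a1` may be an n x 2 matrix.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `p_value`, `n`,
#'   and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(a1, a2 = NULL, conf_level = 0.95) {
  m <- if (is.null(a2)) as.matrix(a1) else cbind(a1, a2)
  if (ncol(m) != 2) stop("expected two method columns")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- 2
  if (n < 3) stop("need at least 3 complete subject pairs")
  if (!all(is.finite(m))) stop("non-finite values")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  sst <- sum((m - grand)^2)
  if (sst < 1e-24) stop("degenerate matrix: zero total variance")
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse <= 1e-24 && msc <= 1e-24) {
    # identical columns: perfect agreement, no sampling uncertainty to model
    ci <- c(1, 1); p <- 0
  } else {
    r <- est
    a <- (k * r) / (n * (1 - r)); b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
    fstat <- msr / mse
    p <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(estimate = est, ci_lower = ci[1], ci_upper = ci[2], p_value = p,
       n = n, msr = msr, msc = msc, mse = mse)
}

#' Pearson and Spearman correlation between the two methods
#'
#' Standard product-moment and rank correlations with two-tailed p values;
#' Spearman uses average ranks for ties (asymptotic p).  Zero variance in
#' either column yields NA estimates with `undefined = TRUE` rather than 0.
#'
#' @param a1,a2 Paired per-subject values, length >= 3.
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `undefined`.
#' @export
correlation_suite <- function(a1, a2) {
  ok <- stats::complete.cases(a1, a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a1) == 0 || stats::sd(a2) == 0) {
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                undefined = TRUE))
  }
  pe <- stats::cor.test(a1, a2, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(a1, a2, method = "spearman",
                                         exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       undefined = FALSE)
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as method 1 minus method 2; limits of agreement
#' are `mean_diff +/- multiplier * sd_diff` with the conventional 1.96
#' multiplier.
#'
#' @param a1,a2 Paired values (length >= 2).
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @return List with `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper` and a
#'   `points` data frame of per-subject (mean, difference) pairs for
#'   plotting.
#' @export
bland_altman <- function(a1, a2, loa_multiplier = 1.96) {
  ok <- stats::complete.cases(a1, a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) < 2) stop("need at least 2 complete pairs")
  d <- a1 - a2
  md <- mean(d); sdd <- stats::sd(d)
  list(mean_diff = md, sd_diff = sdd,
       loa_lower = md - loa_multiplier * sdd,
       loa_upper = md + loa_multiplier * sdd,
       points = data.frame(mean = (a1 + a2) / 2, diff = d))
}

#' Absolute difference between two method means
#' @param mean_a1,mean_a2 Finite scalars (s).
#' @return `|mean_a1 - mean_a2|`.
#' @export
absolute_difference <- function(mean_a1, mean_a2) {
  if (!is.finite(mean_a1) || !is.finite(mean_a2)) stop("inputs must be finite")
  abs(mean_a1 - mean_a2)
}

#' Categorical agreement label for a correlation-type coefficient
#'
#' Bins as conventionally printed: <= 0.30 none, 0.31-0.50 fair, 0.51-0.70
#' moderate, 0.71-0.90 substantial, >= 0.91 very good.  Values falling in
#' the gaps between printed bin edges (e.g. 0.305) are resolved downward.
#'
#' @param coefficient Value in [-1, 1].
#' @return One of `"none"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"very_good"`.
#' @export
classify_agreement <- function(coefficient) {
  if (!is.finite(coefficient) || coefficient < -1 || coefficient > 1) {
    stop("coefficient must lie in [-1, 1]")
  }
  if (coefficient < 0.31) "none"
  else if (coefficient < 0.51) "fair"
  else if (coefficient < 0.71) "moderate"
  else if (coefficient < 0.91) "substantial"
  else "very_good"
}

#' Full between-method agreement summary for one parameter/statistic cell
#'
#' Bundles the correlation suite, ICC(2,1) with CI and p, the categorical
#' label of the ICC, the absolute difference of means, Bland-Altman
#' statistics and the ordinary least-squares regression of method 2 on
#' method 1.
#'
#' @param a1,a2 Paired per-subject values (length >= 3).
#' @return Object of class `agreement_result` (a list).
#' @export
agreement_summary <- function(a1, a2) {
  ok <- stats::complete.cases(a1, a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  corr <- correlation_suite(a1, a2)
  icc <- tryCatch(icc_2_1(a1, a2), error = function(e) NULL)
  ba <- bland_altman(a1, a2)
  fit <- stats::lm(a2 ~ a1)
  structure(list(
    n = length(a1),
    pearson_r = corr$pearson_r, pearson_p = corr$pearson_p,
    spearman_rho = corr$spearman_rho, spearman_p = corr$spearman_p,
    icc = if (is.null(icc)) NA_real_ else icc$estimate,
    icc_lower = if (is.null(icc)) NA_real_ else icc$ci_lower,
    icc_upper = if (is.null(icc)) NA_real_ else icc$ci_upper,
    icc_p = if (is.null(icc)) NA_real_ else icc$p_value,
    category = if (is.null(icc) || !is.finite(icc$estimate)) NA_character_
               else classify_agreement(max(-1, min(1, icc$estimate))),
    ad_of_means = absolute_difference(mean(a1), mean(a2)),
    mean_a1 = mean(a1), sd_a1 = stats::sd(a1),
    mean_a2 = mean(a2), sd_a2 = stats::sd(a2),
    bland_altman = ba[c("mean_diff", "sd_diff", "loa_lower", "loa_upper")],
    regression = list(intercept = unname(stats::coef(fit)[1]),
                      slope = unname(stats::coef(fit)[2]))),
    class = "agreement_result")
}
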