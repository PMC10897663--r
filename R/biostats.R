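#' Normality-routed paired comparison
#'
#' Implements the study's testing rule: a Shapiro-Wilk test on the paired
#' differences routes to a two-sided paired t test when the differences are
#' compatible with normality (p > `alpha`) and to a two-sided Wilcoxon
#' signed-rank test otherwise (zeros dropped; exact null distribution for
#' up to 25 non-zero untied differences, normal approximation with
#' continuity correction beyond). Identical vectors are a degenerate case
#' reported with p = 1; zero-variance differences with a non-zero mean are
#' an error (no test is defined).
#'
#' @param a,b Paired sample vectors of equal length (>= 3).
#' @param alpha Significance level used only for the normality routing.
#' @param test `"auto"` (the default Shapiro-Wilk routing) or a forced
#'   `"paired_t"` / `"wilcoxon"` choice.
#' @return An object of class `paired_comparison` with fields `n`,
#'   `mean_sd_a`, `mean_sd_b`, `test_used` (`"paired_t"` or `"wilcoxon"`),
#'   `statistic`, `p_value`, `normality_p`, `degenerate`.
#' @examples
#' paired_compare(c(1, 2, 3), c(2, 3, 5))
#' @export
paired_compare <- function(a, b, alpha = 0.05,
                           test = c("auto", "paired_t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("at least 3 pairs required")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite")
  d <- b - a
  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  if (stats::sd(d) < 1e-12 * max(1, mean(abs(c(a, b))))) {
    if (abs(mean(d)) > 1e-12 * max(1, mean(abs(c(a, b)))))
      stop("degenerate comparison: constant non-zero differences")
    return(structure(
      list(n = length(a), mean_sd_a = msd(a), mean_sd_b = msd(b),
           test_used = "paired_t", statistic = 0, p_value = 1,
           normality_p = NA_real_, degenerate = TRUE),
      class = "paired_comparison"))
  }
  sw <- stats::shapiro.test(d)
  use_t <- switch(test, auto = sw$p.value > alpha, paired_t = TRUE,
                  wilcoxon = FALSE)
  if (use_t) {
    tt <- stats::t.test(b, a, paired = TRUE)
    test_used <- "paired_t"; statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    nz <- sum(d != 0)
    wt <- suppressWarnings(
      stats::wilcox.test(b, a, paired = TRUE, exact = nz <= 25,
                         correct = TRUE))
    test_used <- "wilcoxon"; statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(
    list(n = length(a), mean_sd_a = msd(a), mean_sd_b = msd(b),
         test_used = test_used, statistic = statistic, p_value = p,
         normality_p = sw$p.value, degenerate = FALSE),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> n = %d: %.2f +/- %.2f vs %.2f +/- %.2f\n",
    x$n, x$mean_sd_a["mean"], x$mean_sd_a["sd"], x$mean_sd_b["mean"],
    x$mean_sd_b["sd"]))
  cat(sprintf("  %s: statistic = %.3f, p = %.4g%s\n", x$test_used,
              x$statistic, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way model, single rater, absolute agreement (McGraw-Wong A,1):
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)` with mean
#' squares from the two-way ANOVA decomposition of an n-subjects by
#' k-raters rating matrix; the 95% confidence interval follows the
#' F-distribution construction with Satterthwaite degrees of freedom.
#'
#' @param ratings n x k numeric matrix, no missing cells, n >= 2, k >= 2.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc_result` with fields `icc`, `ci95`,
#'   `MSR`, `MSC`, `MSE`, `n`, `k`.
#' @examples
#' icc_a1(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (any(!is.finite(m))) stop("ratings must be complete and finite")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (stats::sd(as.vector(m)) == 0)
    stop("degenerate ratings: constant matrix, ICC undefined (0/0)")
  g <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  MSR <- k * sum((rm_ - g)^2) / (n - 1)
  MSC <- n * sum((cm_ - g)^2) / (k - 1)
  resid <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf_level
  if (MSE <= .Machine$double.eps * max(MSR, MSC, 1)) {
    ci <- c(icc, icc) # perfect within-cell fit: no residual uncertainty
  } else {
    Fj <- MSC / MSE
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * Fj + b)^2 /
      (a^2 * Fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    F1 <- stats::qf(1 - alpha / 2, n - 1, v)
    F2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - F1 * MSE) /
      (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (F2 * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = icc, ci95 = ci, MSR = MSR, MSC = MSC, MSE = MSE,
         n = n, k = k, conf_level = conf_level),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> ICC(A,1) = %.3f (%g%% CI %.3f-%.3f; n = %d, k = %d)\n",
    x$icc, 100 * x$conf_level, x$ci95[1], x$ci95[2], x$n, x$k))
  invisible(x)
}

#' Sample size for a two-sided paired t test
#'
#' Smallest number of pairs `n` such that the power of the two-sided paired
#' t test (degrees of freedom `n - 1`, noncentrality `d * sqrt(n)`, critical
#' value from the central t) reaches the requested power for a standardized
#' effect size `d` (mean paired difference over the SD of differences).
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Two-sided significance level.
#' @param power Required power.
#' @param n_max Iteration cap.
#' @return Integer sample size (>= 2).
#' @examples
#' sample_size_paired_t(d = 1.3, alpha = 0.05, power = 0.95)
#' @export
sample_size_paired_t <- function(d, alpha = 0.05, power = 0.95,
                                 n_max = 1e6) {
  if (!is.finite(d) || d <= 0) stop("effect size d must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  for (n in 2:n_max) {
    df <- n - 1
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n)
    pw <- 1 - stats::pt(tcrit, df, ncp = ncp) +
      stats::pt(-tcrit, df, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("requested power unattainable within iteration cap")
}
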