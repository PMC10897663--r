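test_that("paired comparison handles degenerate and hand-computed cases", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  same <- paired_compare(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_error(paired_compare(a, a + 2), "constant non-zero")
  # differences (1, 1, 2): t = 4, df = 2, two-sided p = 0.0572; the t
  # branch is forced because Shapiro-Wilk rejects n = 3 with tied values
  pc <- paired_compare(c(1, 2, 3), c(2, 3, 5), test = "paired_t")
  expect_equal(pc$test_used, "paired_t")
  expect_equal(pc$statistic, 4, tolerance = 1e-10)
  expect_equal(pc$p_value, 0.05719096, tolerance = 1e-6)
  # closed-form df = 2 tail: p = 1 - t / sqrt(2 + t^2)
  expect_equal(pc$p_value, 1 - 4 / sqrt(2 + 16), tolerance = 1e-10)
})

test_that("normality routing follows the Shapiro-Wilk decision", {
  set.seed(31)
  for (rep in 1:20) {
    a <- rnorm(12)
    b <- a + if (rep %% 2) rnorm(12) else rexp(12)^3
    pc <- paired_compare(a, b)
    expect_identical(pc$test_used == "paired_t", pc$normality_p > 0.05)
  }
})

test_that("paired comparison keeps its nominal type-I error", {
  set.seed(99)
  rejections <- vapply(1:2000, function(i) {
    x <- rnorm(15); y <- x + rnorm(15)
    paired_compare(x, y)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("ICC(A,1) matches hand and aov-based ANOVA decompositions", {
  perfect <- icc_a1(cbind(1:4, 1:4))
  expect_equal(perfect$icc, 1)
  # constant offset of 1: MSR = 10/3, MSC = 2, MSE = 0 -> 10/13
  off <- icc_a1(cbind(1:4, 2:5))
  expect_equal(off$MSR, 10 / 3, tolerance = 1e-12)
  expect_equal(off$MSC, 2, tolerance = 1e-12)
  expect_equal(off$MSE, 0, tolerance = 1e-12)
  expect_equal(off$icc, 10 / 13, tolerance = 1e-12)
  expect_error(icc_a1(matrix(3, 4, 2)), "constant")
  # random matrices against the independent aov oracle
  set.seed(8)
  for (i in 1:25) {
    m <- matrix(rnorm(10, 10, 3), 5, 2)
    r <- icc_a1(m)
    expect_equal(r$icc, icc_aov_oracle(m), tolerance = 1e-10)
    expect_lte(r$ci95[1], r$icc)
    expect_gte(r$ci95[2], r$icc)
  }
})

test_that("ICC confidence interval covers the true reliability", {
  # true ICC 0.95: subject SD 2, error SD 2 * sqrt(0.05 / 0.95)
  set.seed(21)
  sigma_e <- 2 * sqrt(0.05 / 0.95)
  true_icc <- 4 / (4 + sigma_e^2)
  cover <- vapply(1:300, function(i) {
    subj <- rnorm(24, 36, 2)
    m <- cbind(subj + rnorm(24, 0, sigma_e), subj + rnorm(24, 0, sigma_e))
    ci <- icc_a1(m)$ci95
    ci[1] <= true_icc && true_icc <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.9)
})

test_that("paired-t sample size reproduces the noncentral-t oracle", {
  # independent continuous solver, rounded up
  oracle_n <- function(d, alpha = 0.05, power = 0.95) {
    ceiling(stats::power.t.test(delta = d, sd = 1, sig.level = alpha,
                                power = power, type = "paired")$n)
  }
  for (d in c(0.5, 0.8, 1.0, 1.3, 2.0)) {
    expect_equal(sample_size_paired_t(d), oracle_n(d))
  }
  # monotonicity: smaller effects need more pairs; more power needs more
  expect_gt(sample_size_paired_t(0.5), sample_size_paired_t(1.0))
  expect_gte(sample_size_paired_t(1, power = 0.99),
             sample_size_paired_t(1, power = 0.8))
  expect_gte(sample_size_paired_t(1, alpha = 0.01),
             sample_size_paired_t(1, alpha = 0.05))
  # a non-empty effect-size interval yields the study's n = 10
  ds <- seq(1.05, 1.60, by = 0.01)
  ns <- vapply(ds, sample_size_paired_t, numeric(1))
  expect_true(any(ns == 10))
  expect_error(sample_size_paired_t(-1), "positive")
})
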