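# Test-retest statistics: Bland-Altman closed form, paired t, Pearson r,
# degenerate handling, and the assembled report.

test_that("Bland-Altman limits reproduce the closed form exactly", {
  same <- repeat_pair(c(1, 2, 3), c(1, 2, 3))
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))

  # worked example: differences (0.1, -0.1, 0.3, -0.3)
  pair <- repeat_pair(c(0.8, 0.7, 0.9, 0.6), c(0.7, 0.8, 0.6, 0.9))
  ba <- bland_altman(pair)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(0.2 / 3), tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.2582, tolerance = 1e-4)
  expect_equal(ba$loa_upper, 0.5061, tolerance = 1e-4)
  expect_equal(ba$loa_lower, -0.5061, tolerance = 1e-4)
  # multiplier is exactly 1.96
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * ba$sd_diff,
               tolerance = 1e-12)

  # closed-form oracle on random vectors, sample (n-1) SD
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    bb <- bland_altman(repeat_pair(a, b))
    d <- a - b
    mu <- sum(d) / n
    s <- sqrt(sum((d - mu)^2) / (n - 1))
    expect_equal(bb$bias, mu, tolerance = 1e-12)
    expect_equal(bb$loa_upper, mu + 1.96 * s, tolerance = 1e-12)
    expect_equal(bb$loa_lower, mu - 1.96 * s, tolerance = 1e-12)
  }
  expect_error(repeat_pair(1, 2), "length")
})

test_that("paired t matches the textbook formula and flags degeneracy", {
  # differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, df 2, p = 0.0742
  pt1 <- paired_t(repeat_pair(c(2, 4, 6), c(1, 2, 3)))
  expect_equal(pt1$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(pt1$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(pt1$df, 2)
  expect_equal(pt1$p_value, 2 * stats::pt(-abs(pt1$statistic), 2),
               tolerance = 1e-12)
  expect_equal(pt1$p_value, 0.0742, tolerance = 1e-3)  # printed precision
  # direction sanity: constant offset with tiny noise is highly significant
  set.seed(15)
  base <- runif(12)
  off <- paired_t(repeat_pair(base + 0.5 + rnorm(12, 0, 1e-4), base))
  expect_gt(abs(off$statistic), 100)
  expect_lt(off$p_value, 1e-6)
  # identical vectors are degenerate, flagged, p = 1
  deg <- paired_t(repeat_pair(base, base))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # brute-force oracle on random vectors
  for (i in 1:10) {
    n <- sample(4:25, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    tref <- mean(d) / (sd(d) / sqrt(n))
    got <- paired_t(repeat_pair(a, b))
    expect_equal(got$statistic, tref, tolerance = 1e-9)
    expect_equal(got$p_value, 2 * stats::pt(-abs(tref), n - 1),
                 tolerance = 1e-9)
  }
})

test_that("Pearson r matches the product-moment formula", {
  m1 <- c(1, 2, 3, 4)
  expect_equal(pearson_r(repeat_pair(m1, 2 * m1 + 1))$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(repeat_pair(m1, -m1))$r, -1, tolerance = 1e-12)
  expect_equal(pearson_r(repeat_pair(m1, c(1, 2, 4, 3)))$r, 0.8,
               tolerance = 1e-12)
  expect_error(pearson_r(repeat_pair(m1, rep(2, 4))), "constant")
  expect_error(pearson_r(repeat_pair(c(1, 2), c(3, 4))), "n >= 3")
  set.seed(16)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    rref <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    got <- pearson_r(repeat_pair(a, b))
    expect_equal(got$r, rref, tolerance = 1e-9)
    tr <- rref * sqrt((n - 2) / (1 - rref^2))
    expect_equal(got$p_value, 2 * stats::pt(-abs(tr), n - 2),
                 tolerance = 1e-9)
  }
})

test_that("the assembled report carries all components and degeneracy flags", {
  set.seed(17)
  a <- runif(19, 0.6, 1)
  b <- a + rnorm(19, 0, 0.03)
  rep <- repeat_report(repeat_pair(a, b, "av_ratio"))
  expect_equal(rep$n, 19)
  expect_equal(rep$mean1, mean(a))
  expect_equal(rep$sd2, sd(b))
  expect_equal(rep$alpha, 0.05)
  expect_s3_class(rep$bland_altman, "bland_altman")
  # identical vectors: r flagged undefined, not forced to 1
  same <- repeat_report(repeat_pair(a, a))
  expect_true(is.na(same$pearson$r))
  expect_true(same$paired_t$degenerate)
})

test_that("simulated 19-eye repeats recover low bias and high correlation", {
  # measurement noise sd 0.03 around per-eye truths in [0.6, 1]; the spec
  # for this Monte-Carlo: over 100 seeds, 95% of runs have |bias| < 0.02
  # and r > 0.8
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    truth <- runif(19, 0.6, 1)
    m1 <- truth + rnorm(19, 0, 0.03)
    m2 <- truth + rnorm(19, 0, 0.03)
    rep <- repeat_report(repeat_pair(m1, m2))
    if (abs(rep$bland_altman$bias) < 0.02 && rep$pearson$r > 0.8) ok <- ok + 1
  }
  expect_gte(ok, 95)
})
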