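test_that("Welch summaries reproduce the closed-form albumin comparison", {
  # 66.8 +/- 2.6 vs 58.9 +/- 3.4 ng/ml, n = 5 per group
  res <- welch_from_summary(66.8, 2.6, 5, 58.9, 3.4, 5)
  expect_equal(res$t_statistic, 4.1271, tolerance = 1e-4)
  expect_equal(res$df, 7.4864, tolerance = 1e-4)
  expect_lt(res$p_two_sided, 0.01)
  expect_equal(res$mean_difference, 7.9)
})

test_that("degenerate and boundary Welch cases are defined", {
  same <- welch_from_summary(5, 1.2, 4, 5, 1.2, 4)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)
  # both SDs zero with equal means
  z <- welch_from_summary(3, 0, 4, 3, 0, 4)
  expect_equal(z$p_two_sided, 1)
  # both SDs zero with unequal means is undefined
  expect_error(welch_from_summary(0, 0, 4, 1, 0, 4), "undefined")
  expect_error(welch_from_samples(c(0, 0, 0, 0), c(1, 1, 1, 1)), "undefined")
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
  # equal sds and n: df reduces to n1 + n2 - 2 exactly
  eq <- welch_from_summary(4, 2, 7, 6, 2, 7)
  expect_equal(eq$df, 12)
})

test_that("sample-based Welch agrees with summaries and with stats::t.test", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1), 0, runif(1, 0.5, 2))
    b <- rnorm(sample(3:15, 1), runif(1, -1, 1), runif(1, 0.5, 2))
    mine <- welch_from_samples(a, b)
    viasum <- welch_from_summary(mean(a), sd(a), length(a),
                                 mean(b), sd(b), length(b))
    expect_equal(mine$t_statistic, viasum$t_statistic, tolerance = 1e-12)
    expect_equal(mine$p_two_sided, viasum$p_two_sided, tolerance = 1e-12)
    ref <- t.test(a, b)  # independent Welch implementation
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-9)
    # swapping groups flips t, preserves p
    sw <- welch_from_samples(b, a)
    expect_equal(sw$t_statistic, -mine$t_statistic, tolerance = 1e-12)
    expect_equal(sw$p_two_sided, mine$p_two_sided, tolerance = 1e-12)
  }
})

test_that("the null rejection rate is near nominal", {
  set.seed(31)
  rej <- 0
  for (i in 1:500) {
    if (welch_from_samples(rnorm(11), rnorm(11))$p_two_sided < 0.05)
      rej <- rej + 1
  }
  expect_gt(rej / 500, 0.025)
  expect_lt(rej / 500, 0.075)
})

test_that("sample size calculation matches the noncentral-t oracle", {
  # d = 0.3, alpha 0.05, power 0.8 -> 176 per group; the normal
  # approximation 2 (z_0.975 + z_0.84)^2 / d^2 ~ 175 brackets it
  n <- sample_size_two_sample_t(0.3, 0.05, 0.8)
  expect_equal(n, 176L)
  napprox <- 2 * ((qnorm(0.975) + qnorm(0.8)) / 0.3)^2
  expect_lt(abs(n - napprox), 3)
  # independent oracle from stats
  expect_equal(n, as.integer(ceiling(power.t.test(delta = 0.3, sd = 1,
                                                  power = 0.8)$n)))
  # attained power at n meets the target, at n - 1 it does not
  expect_gte(t_test_power(0.3, n), 0.8)
  expect_lt(t_test_power(0.3, n - 1), 0.8)
})

test_that("sample size behaves at large effects and boundary power", {
  expect_lte(sample_size_two_sample_t(2, 0.05, 0.8), 7)
  # monotone non-increasing in d
  ds <- c(0.2, 0.3, 0.5, 0.8, 1.2, 2)
  ns <- vapply(ds, sample_size_two_sample_t, integer(1))
  expect_true(all(diff(ns) <= 0))
  # as power drops toward alpha the required n drops to the minimum
  expect_equal(sample_size_two_sample_t(1, 0.05, 0.051), 2L)
  expect_error(sample_size_two_sample_t(0), "> 0")
  expect_error(sample_size_two_sample_t(-1), "> 0")
})

test_that("Welch direction agrees with a permutation test and t tables", {
  set.seed(77)
  a <- rnorm(8, 1); b <- rnorm(8, 0)
  mine <- welch_from_samples(a, b)
  # brute-force permutation of group labels
  pool <- c(a, b)
  perm_t <- replicate(400, {
    idx <- sample(16, 8)
    welch_from_samples(pool[idx], pool[-idx])$t_statistic
  })
  expect_equal(sign(mine$t_statistic), sign(mean(a) - mean(b)))
  expect_gt(mine$t_statistic, quantile(perm_t, 0.9))
  # published t quantiles: P(T_df > q) at df 5, 10, 30
  expect_equal(2 * pt(2.571, 5, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_equal(2 * pt(2.228, 10, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_equal(2 * pt(2.042, 30, lower.tail = FALSE), 0.05, tolerance = 1e-3)
})

test_that("per-probe Welch testing supports optional Holm adjustment", {
  set.seed(9)
  ga <- list("4 kDa" = rnorm(11, 90, 5), "150 kDa" = rnorm(11, 50, 5))
  gb <- list("150 kDa" = rnorm(11, 45, 5), "4 kDa" = rnorm(11, 88, 5))
  raw <- welch_by_probe(ga, gb)
  expect_equal(raw$p_adjusted, raw$p_two_sided)
  holm <- welch_by_probe(ga, gb, adjust = "holm")
  expect_equal(holm$p_adjusted, p.adjust(holm$p_two_sided, "holm"))
  expect_error(welch_by_probe(ga, gb["4 kDa"]), "same probes")
})
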