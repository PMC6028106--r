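test_that("unpaired t: conventions, published call, formula agreement", {
  same <- c(1, 2, 3)
  res <- unpaired_t(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(unpaired_t(c(2, 2), c(2, 2))$p, 1)  # constant-equal rule

  # per-animal total densities, adult vs aged: strongly significant
  t1 <- load_table1()
  dens <- t1$n_included / t1$volume_um3
  ht <- unpaired_t(dens[t1$group == "adult"], dens[t1$group == "aged"])
  expect_lt(ht$p, 0.001)

  # agreement with the closed-form pooled statistic
  set.seed(99)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.3)
    got <- unpaired_t(a, b)
    want <- oracle_pooled_t(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
  # Welch variant reduces df below the pooled value for unequal spread
  w <- unpaired_t(rnorm(10), rnorm(10, sd = 5), variant = "welch")
  expect_lt(w$df, 18)
})

test_that("type-I error of the pooled t at alpha = 0.05 is calibrated", {
  set.seed(2024)
  n_rep <- 10000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    if (unpaired_t(rnorm(3), rnorm(3))$p < 0.05) rej <- rej + 1L
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej / n_rep - 0.05), 3 * se)
})

test_that("KS test: degenerate cases, oracle D, null uniformity", {
  x <- c(1, 2, 3, 4)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)  # disjoint supports

  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(sample(5:50, 1)); b <- rnorm(sample(5:50, 1), 0.5)
    expect_equal(ks_two_sample(a, b)$D, oracle_ks_D(a, b),
                 tolerance = 1e-9)
  }

  # null calibration: P(p < alpha) tracks alpha (the two-sample D is
  # discrete at n = 100, so exact uniformity is unattainable; rejection
  # rates are checked at 3 binomial SE instead)
  set.seed(17)
  ps <- replicate(2000, ks_two_sample(rnorm(100), rnorm(100))$p)
  for (alpha in c(0.05, 0.2, 0.5)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lt(abs(mean(ps < alpha) - alpha), 3 * se + 0.02)
  }
})

test_that("linear fit: exact lines, noisy slope recovery, errors", {
  x <- 1:10
  fit <- linear_fit(x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(linear_fit(x, 5 - 3 * x)$r, -1, tolerance = 1e-12)

  set.seed(200)
  xr <- runif(200); yr <- xr + rnorm(200, 0, 0.3)
  f2 <- linear_fit(xr, yr)
  se <- summary(lm(yr ~ xr))$coefficients[2, 2]
  expect_lt(abs(f2$slope - 1), 3 * se)
  expect_equal(f2$r_squared, f2$r^2, tolerance = 1e-12)

  expect_error(linear_fit(rep(1, 5), rnorm(5)), "constant")
  expect_error(linear_fit(1:2, 1:2), "n >= 3")
})

test_that("slope comparison: exact zero, power, null uniformity", {
  x <- runif(50); y <- 2 * x + rnorm(50, 0, 0.1)
  dup <- compare_slopes(x, y, x, y)
  expect_equal(dup$estimate, 0, tolerance = 1e-12)

  set.seed(44)
  x1 <- runif(100); x2 <- runif(100)
  strong <- compare_slopes(x1, 1 * x1 + rnorm(100, 0, 0.05),
                           x2, 2 * x2 + rnorm(100, 0, 0.05))
  expect_lt(strong$p, 1e-6)

  ps <- replicate(400, {
    xa <- runif(30); xb <- runif(30)
    compare_slopes(xa, xa + rnorm(30, 0, 0.3),
                   xb, xb + rnorm(30, 0, 0.3))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)

  expect_error(compare_slopes(rep(1, 5), rnorm(5), runif(5), rnorm(5)),
               "constant")
})

test_that("percent change reproduces the published arithmetic", {
  expect_equal(round(percent_change(0.103, 0.083), 1), 19.4)
  expect_equal(round(percent_change(0.123, 0.078), 1), 36.6)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(2, 3), -50)
  # vs_larger uses the bigger magnitude as denominator
  expect_equal(percent_change(2, 3, "vs_larger"), -100 / 3,
               tolerance = 1e-12)
  expect_error(percent_change(0, 1), "denominator")
})

test_that("group summaries carry mean +/- sem with sample SD", {
  gs <- group_summary(c(1.400, 1.419, 1.402), "adult")
  expect_equal(gs$mean, mean(c(1.400, 1.419, 1.402)))
  expect_equal(gs$sem, sd(c(1.400, 1.419, 1.402)) / sqrt(3))
  expect_equal(gs$n, 3)
  expect_error(group_summary(numeric(0)), "at least one")
})
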