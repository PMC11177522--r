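test_that("mixed ANOVA matches the aov Error-stratum oracle", {
  set.seed(61)
  for (r in 1:5) {
    n_per <- sample(3:5, 1)
    k <- sample(3:4, 1)
    values <- matrix(rnorm(2 * n_per * k), 2 * n_per, k)
    group <- rep(c("a", "b"), each = n_per)
    got <- mixed_anova(values, group)
    want <- aov_mixed_oracle(values, group)
    expect_equal(got$F[got$effect == "group"], unname(want$F_group),
                 tolerance = 1e-10)
    expect_equal(got$F[got$effect == "task"], unname(want$F_task),
                 tolerance = 1e-10)
    expect_equal(got$F[got$effect == "group:task"], unname(want$F_int),
                 tolerance = 1e-10)
  }
})

test_that("mixed ANOVA handles degenerate and symmetric designs", {
  vals <- matrix(1, 6, 3)
  expect_warning(tab <- mixed_anova(vals, rep(c("a", "b"), each = 3)), "variance")
  expect_true(is.nan(tab$F[1]))

  # identical task profiles in both groups -> group effect ~ 0
  set.seed(62)
  prof <- rnorm(3)
  vals2 <- matrix(rep(prof, each = 8), 8, 3) + rnorm(24, sd = 0.1)
  vals2[5:8, ] <- vals2[1:4, ]               # mirror the two groups exactly
  tab2 <- mixed_anova(vals2, rep(c("a", "b"), each = 4))
  expect_equal(tab2$F[tab2$effect == "group"], 0, tolerance = 1e-10)
  expect_equal(tab2$p[tab2$effect == "group"], 1, tolerance = 1e-10)

  expect_error(mixed_anova(matrix(c(1, NA, 2, 3), 2, 2), c("a", "b")),
               "incomplete")
  expect_error(mixed_anova(matrix(rnorm(6), 3, 2), c("a", "a", "b")),
               "2 subjects")
})

test_that("one-way repeated-measures ANOVA matches aov and is shift-invariant", {
  set.seed(63)
  vals <- matrix(rnorm(5 * 4), 5, 4)
  got <- one_way_rm_anova(vals)
  expect_equal(got$F, unname(aov_rm_oracle(vals)), tolerance = 1e-10)
  shifted <- one_way_rm_anova(vals + 17.3)
  expect_equal(got$F, shifted$F, tolerance = 1e-9)
  scaled <- one_way_rm_anova(vals * 5)
  expect_equal(got$F, scaled$F, tolerance = 1e-9)
  expect_warning(one_way_rm_anova(matrix(2, 4, 3)), "variance")
})

test_that("independent t-test reproduces the pooled-variance closed form", {
  got <- t_independent(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, -3.674, tolerance = 1e-3)
  expect_equal(got$df, 4)
  expect_equal(got$p, 0.0214, tolerance = 1e-2)

  same <- t_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # antisymmetry
  ab <- t_independent(c(1, 2, 3, 4), c(2, 3, 5, 9))
  ba <- t_independent(c(2, 3, 5, 9), c(1, 2, 3, 4))
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)

  expect_equal(t_independent(c(2, 2), c(2, 2))$p, 1)
  expect_error(t_independent(c(1, 1), c(2, 2)), "degenerate")
})

test_that("paired t-test equals a one-sample t on the differences", {
  set.seed(64)
  x <- rnorm(12); y <- rnorm(12)
  got <- t_paired(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$df, 11)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 11), tolerance = 1e-12)

  expect_equal(t_paired(x, x)$t, 0)
  expect_equal(t_paired(x, x)$p, 1)
  expect_error(t_paired(c(2, 3, 4), c(1, 2, 3)), "degenerate")
})

test_that("t-tests hold their nominal type-I error under the null", {
  set.seed(65)
  n_rep <- 2000
  rej_ind <- rej_par <- 0L
  for (r in seq_len(n_rep)) {
    a <- rnorm(10); b <- rnorm(12)
    if (t_independent(a, b)$p < 0.05) rej_ind <- rej_ind + 1L
    x <- rnorm(10); y <- rnorm(10)
    if (t_paired(x, y)$p < 0.05) rej_par <- rej_par + 1L
  }
  expect_lt(abs(rej_ind / n_rep - 0.05), 0.02)
  expect_lt(abs(rej_par / n_rep - 0.05), 0.02)
})
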