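test_that("paired t reproduces the closed form and effect size", {
  x <- c(5.1, 4.8, 6.2, 5.9, 5.3, 6.1)
  y <- c(4.6, 4.9, 5.5, 5.1, 5.0, 5.2)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 5)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 5))
  expect_equal(res$effect_size, mean(d) / sd(d))
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(1:2, 2:3), "length")
})

test_that("two-sample t uses pooled variance and Cohen's d", {
  a <- c(10, 12, 9, 14, 11)
  b <- c(8, 7, 9, 6)
  res <- two_sample_t(a, b)
  sp2 <- (4 * var(a) + 3 * var(b)) / 7
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 7)
  expect_equal(res$effect_size, (mean(a) - mean(b)) / sqrt(sp2))
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("chi-squared on the demographic gender table gives 0.067 / 0.967", {
  tab <- matrix(c(23, 17, 24, 15, 11, 14), nrow = 3)
  res <- chi_squared_test(tab)
  expect_equal(round(res$statistic, 3), 0.067)
  expect_equal(round(res$p, 3), 0.967)
  expect_equal(res$df, 2)
  # hand expected-count formula on a 2x2
  t2 <- matrix(c(10, 20, 30, 40), 2)
  e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
  expect_equal(chi_squared_test(t2)$statistic, sum((t2 - e)^2 / e))
  expect_error(chi_squared_test(matrix(c(1, -1, 2, 3), 2)), "nonnegative")
  expect_error(chi_squared_test(matrix(c(0, 0, 2, 3), 2)), "marginal")
})

test_that("one-way ANOVA agrees with lm/anova", {
  g <- withr::with_seed(1, list(rnorm(8, 0), rnorm(9, 0.5), rnorm(7, 1)))
  res <- one_way_anova(g)
  dat <- data.frame(v = unlist(g),
                    f = factor(rep(1:3, lengths(g))))
  ref <- anova(lm(v ~ f, dat))
  expect_equal(res$statistic, ref$`F value`[1])
  expect_equal(res$p, ref$`Pr(>F)`[1])
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 21)
})

test_that("mixed ANOVA matches a hand split-plot decomposition", {
  ng <- 3; n <- 5; k <- 4
  dat <- withr::with_seed(2, {
    d <- expand.grid(participant = 1:(ng * n), class = 1:k)
    d$group <- (d$participant - 1) %/% n + 1
    d$value <- rnorm(nrow(d)) + 0.4 * d$class + 0.3 * d$group +
      0.2 * d$class * (d$group == 2)
    d
  })
  res <- mixed_anova(dat)

  y <- dat$value
  grand <- mean(y)
  m_subj <- tapply(y, dat$participant, mean)
  m_grp <- tapply(y, dat$group, mean)
  m_cls <- tapply(y, dat$class, mean)
  m_gc <- tapply(y, list(dat$group, dat$class), mean)
  ss_total <- sum((y - grand)^2)
  ss_bsubj <- k * sum((m_subj - grand)^2)
  ss_group <- n * k * sum((m_grp - grand)^2)
  ss_serr <- ss_bsubj - ss_group
  ss_class <- ng * n * sum((m_cls - grand)^2)
  ss_int <- n * sum((m_gc - outer(m_grp - grand, m_cls - grand, "+") -
                       grand)^2)
  ss_werr <- ss_total - ss_bsubj - ss_class - ss_int
  f_group <- (ss_group / (ng - 1)) / (ss_serr / (ng * (n - 1)))
  f_class <- (ss_class / (k - 1)) / (ss_werr / (ng * (n - 1) * (k - 1)))
  f_int <- (ss_int / ((ng - 1) * (k - 1))) /
    (ss_werr / (ng * (n - 1) * (k - 1)))
  expect_equal(res$statistic, c(f_group, f_class, f_int))
  expect_equal(res$df1, c(ng - 1, k - 1, (ng - 1) * (k - 1)))
  expect_equal(res$df2, c(ng * (n - 1), ng * (n - 1) * (k - 1),
                          ng * (n - 1) * (k - 1)))
  expect_equal(res$p[1], pf(f_group, 2, 12, lower.tail = FALSE))

  # Greenhouse-Geisser shifts only the within-factor p values upward
  res_gg <- mixed_anova(dat, gg = TRUE)
  expect_equal(res_gg$p[1], res$p[1])
  expect_gte(res_gg$p[2], res$p[2])
  expect_true(res_gg$gg_epsilon[2] <= 1 &&
                res_gg$gg_epsilon[2] >= 1 / (k - 1))

  expect_error(mixed_anova(dat[-1, ]), "unbalanced")
  expect_error(mixed_anova(transform(dat, group = 1)), "2 groups")
})

test_that("Dunn's z matches the tie-corrected formula", {
  values <- c(1, 2, 2, 3, 2, 4, 5, 6, 6, 7)
  group <- rep(c("a", "b", "c"), c(4, 3, 3))
  res <- dunn_posthoc(values, group, adjust = "none")
  rk <- rank(values)
  N <- 10
  ties <- table(values)
  varr <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z_ab <- (mean(rk[1:4]) - mean(rk[5:7])) / sqrt(varr * (1 / 4 + 1 / 3))
  expect_equal(res$z[res$group1 == "a" & res$group2 == "b"], z_ab)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)))
  expect_equal(res$p_adjusted, res$p)
  res_b <- dunn_posthoc(values, group, adjust = "bonferroni")
  expect_equal(res_b$p_adjusted, pmin(1, res_b$p * 3))
  expect_equal(nrow(res), 3)
  expect_error(dunn_posthoc(rep(1, 6), rep(c("a", "b"), 3)), "identical")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_correct(c(0.01, 0.2, 0.5)), c(0.03, 0.6, 1))
  expect_equal(bonferroni_correct(0.04, m = 10), 0.4)
  expect_error(bonferroni_correct(c(0.1, 0.2), m = 1), "family size")
})

test_that("TANOVA separates distinct topographies and is seed-stable", {
  tmpl <- orthogonal_pair(8)
  withr::with_seed(4, {
    a <- tmpl[rep(1, 8), ] * runif(8, 2, 4) + matrix(rnorm(64, sd = 0.02),
                                                     8, 8)
    b <- tmpl[rep(2, 8), ] * runif(8, 2, 4) + matrix(rnorm(64, sd = 0.02),
                                                     8, 8)
  })
  res <- tanova(a, b, n_perm = 200, seed = 7)
  expect_lt(res$p, 0.02)
  expect_gte(res$p, 1 / 201)
  expect_identical(tanova(a, b, n_perm = 200, seed = 7)$p, res$p)
  # same-population groups: p should not be extreme
  withr::with_seed(5, {
    c1 <- tmpl[rep(1, 10), ] + matrix(rnorm(80, sd = 0.5), 10, 8)
    c2 <- tmpl[rep(1, 10), ] + matrix(rnorm(80, sd = 0.5), 10, 8)
  })
  expect_gt(tanova(c1, c2, n_perm = 200, seed = 8)$p, 0.05)
  expect_error(tanova(a[1:2, ], b, n_perm = 10), "nrow")
})

test_that("linear fit matches lm and recovers a known line", {
  x <- withr::with_seed(6, rnorm(20))
  y <- 2 * x + 1 + withr::with_seed(7, rnorm(20, sd = 0.3))
  res <- linear_fit(x, y)
  ref <- summary(lm(y ~ x))
  expect_equal(res$slope, unname(coef(ref)[2, 1]))
  expect_equal(res$intercept, unname(coef(ref)[1, 1]))
  expect_equal(res$r_squared, ref$r.squared)
  expect_equal(res$p, coef(ref)[2, 4])
  expect_equal(res$slope, 2, tolerance = 0.15)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "constant x")
})
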