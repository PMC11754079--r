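test_that("pooled-variance t-test matches the hand-evaluated formula", {
  tt <- t_test_unpaired(c(1, 2, 3), c(4, 5, 6))
  # oracle by hand: pooled sd = 1, se = sqrt(2/3), t = -3/se
  expect_equal(abs(tt$statistic_value), 3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(tt$df, 4)

  same <- t_test_unpaired(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic_value, 0)
  expect_equal(same$p_value, 1)

  a <- rnorm(6); b <- rnorm(7)
  expect_equal(t_test_unpaired(a, b)$statistic_value,
               -t_test_unpaired(b, a)$statistic_value)
  expect_equal(t_test_unpaired(a, b)$p_value, t_test_unpaired(b, a)$p_value)
})

test_that("Mann-Whitney exact p equals full enumeration for all n1+n2 <= 8", {
  set.seed(21)
  for (n1 in 1:4) for (n2 in n1:(8 - n1)) {
    for (rep in 1:3) {
      x <- sample(seq_len(50), n1)   # tie-free integer draws
      y <- sample(setdiff(seq_len(50), x), n2)
      mw <- mann_whitney(x, y)
      expect_true(mw$exact)
      expect_equal(mw$p_value, mw_enumeration_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }

  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic_value, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$U1 + mw$U2, 9)  # U1 + U2 = n1 * n2

  tied <- mann_whitney(1, 1)
  expect_equal(tied$statistic_value, 0.5)
  expect_equal(tied$p_value, 1)
})

test_that("Kruskal-Wallis ties to Mann-Whitney and handles degeneracy", {
  expect_equal(kruskal_wallis(list(rep(3, 5), rep(3, 4)))$statistic_value, 0)

  set.seed(22)
  a <- rnorm(11); b <- rnorm(11)  # n > 20 pooled: MW takes the normal branch
  mw <- mann_whitney(a, b)
  kw <- kruskal_wallis(list(a, b))
  expect_false(mw$exact)
  expect_equal(kw$statistic_value, mw$z^2, tolerance = 1e-9)
})

test_that("Dunn's post hoc flags shifted groups and respects adjustment order", {
  g_same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  d0 <- dunn_posthoc(g_same)
  expect_equal(d0$p_adjusted, 1)

  set.seed(23)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 10)
  d <- dunn_posthoc(g)
  hit <- grepl("c", d$contrast)
  expect_true(all(d$p_adjusted[hit] < 0.05))
  expect_true(all(d$p_adjusted >= d$p_raw - 1e-15))
  # adjusted p is monotone nondecreasing in raw p
  o <- order(d$p_raw)
  expect_true(all(diff(d$p_adjusted[o]) >= -1e-15))
})

test_that("Holm-Sidak step-down reproduces the hand-worked example", {
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(c(0.01, 0.04, 0.03)),
               c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.97^2),
               tolerance = 1e-12)
  expect_equal(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
})

test_that("two-way ANOVA uses Type III SS, collapses to t^2, and is shift-invariant", {
  set.seed(24)
  v <- rnorm(24); g <- rep(c("a", "b"), each = 12)
  an1 <- anova_two_way(v, g, rep("x", 24))
  tt <- t_test_unpaired(v[g == "a"], v[g == "b"])
  expect_equal(an1$statistic_value, tt$statistic_value^2, tolerance = 1e-9)

  fb <- rep(rep(c("p", "q"), each = 6), 2)
  an2 <- anova_two_way(v, g, fb)
  an3 <- anova_two_way(v + 100, g, fb)
  expect_equal(an2$effects$F, an3$effects$F, tolerance = 1e-8)
  expect_named(an2$posthoc, c("contrast", "t", "p_raw", "p_adjusted"))

  expect_error(anova_two_way(v[1:18], g[1:18], c(rep("p", 12), rep("q", 6))),
               "empty design cell")
})

test_that("repeated-measures ANOVA partitions within-subject variance", {
  set.seed(25)
  n_sub <- 8
  d <- data.frame(id = rep(sprintf("s%d", 1:n_sub), each = 2),
                  g = rep(rep(c("WT", "KO"), each = n_sub / 2), each = 2),
                  phase = rep(c("dark", "light"), n_sub))
  d$y <- rnorm(nrow(d)) + ifelse(d$g == "WT" & d$phase == "dark", 4, 0)
  an <- anova_two_way(d$y, d$g, d$phase, subject = d$id)
  expect_equal(an$test_name, "two-way RM ANOVA")
  expect_lt(an$p_value, 0.05)  # strong injected interaction
  expect_equal(nrow(an$effects), 3)

  # incomplete subject dropped with a warning
  d2 <- d[-1, ]
  expect_warning(anova_two_way(d2$y, d2$g, d2$phase, subject = d2$id),
                 "incomplete subject")
})

test_that("normality gating selects the nonparametric branch for skewed data", {
  set.seed(26)
  expect_true(ks_normality(rnorm(60))$pass)
  expect_false(ks_normality(rexp(60))$pass)
  expect_warning(res <- ks_normality(rep(1, 10)), "constant")
  expect_false(res$pass)

  sel1 <- select_test(list(rnorm(30), rnorm(30)))
  expect_equal(sel1$branch, "parametric")
  sel2 <- select_test(list(rnorm(30), rexp(30)^2))
  expect_equal(sel2$branch, "nonparametric")
  expect_equal(nrow(sel2$log), 2)

  # calibration: null rejection rate near the 5% gate level
  set.seed(27)
  rej <- mean(replicate(400, !ks_normality(rnorm(50))$pass))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  pow <- mean(replicate(200, !ks_normality(rexp(50))$pass))
  expect_gt(pow, 0.9)
})

test_that("ROUT flags gross outliers but almost never clean data", {
  ro <- rout_outliers(c(1, 2, 3, 100))
  expect_equal(ro$flagged, 100)
  expect_equal(ro$kept, c(1, 2, 3))

  # affine equivariance of the flagging decision
  set.seed(28)
  x <- c(rnorm(20), 15)
  expect_equal(rout_outliers(x)$flag_mask, rout_outliers(3 * x - 7)$flag_mask)

  expect_warning(ro2 <- rout_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(ro2$kept, c(1, 2, 3))

  set.seed(29)
  false_flag <- mean(replicate(500, any(rout_outliers(rnorm(50))$flag_mask)))
  expect_lte(false_flag, 0.01)
})
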