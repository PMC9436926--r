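# Statistical kernels: analytic behaviour, oracles, and error signalling.

test_that("t_tail_p handles symmetry, tails, and the normal limit", {
  expect_equal(t_tail_p(0, 30), 1.0)
  expect_equal(t_tail_p(2, 1e6), 2 * pnorm(-2), tolerance = 1e-4)
  # strictly decreasing in |statistic|
  p <- t_tail_p(seq(0, 5, by = 0.25), 17)
  expect_true(all(diff(p) < 0))
  # one-sided is half the two-sided tail for positive statistics
  expect_equal(t_tail_p(1.7, 12, two_sided = FALSE),
               t_tail_p(1.7, 12) / 2)
  expect_error(t_tail_p(Inf, 10), class = "bftrans_error_invalid_argument")
  expect_error(t_tail_p(1, 0.5), class = "bftrans_error_invalid_argument")
})

test_that("pearson_r_test matches cor.test and the identity case", {
  set.seed(1)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  mine <- pearson_r_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(mine$estimate, unname(ref$estimate))
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
  ident <- pearson_r_test(x, x)
  expect_equal(ident$estimate, 1)
  expect_equal(ident$p, 0)
  expect_error(pearson_r_test(rep(1, 5), rnorm(5)),
               class = "bftrans_error_constant_input")
  expect_error(pearson_r_test(1:4, 1:5),
               class = "bftrans_error_invalid_argument")
})

test_that("pearson p-values agree with a permutation oracle", {
  set.seed(7)
  for (i in 1:6) {
    n <- sample(8:14, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    p_perm <- oracle_perm_p(x, y, n_perm = 20000)
    p_t <- pearson_r_test(x, y)$p
    mc_se <- sqrt(p_perm * (1 - p_perm) / 20000)
    expect_lt(abs(p_t - p_perm), max(3 * mc_se, 0.02))
  }
})

test_that("ols_fit reproduces the normal-equations oracle and lm anatomy", {
  set.seed(2)
  for (i in 1:5) {
    X <- cbind(rnorm(20), rnorm(20), rnorm(20))
    y <- 1 + X %*% c(0.5, -1, 0.2) + rnorm(20)
    fit <- ols_fit(as.vector(y), data.frame(a = X[, 1], b = X[, 2],
                                            c = X[, 3]))
    beta_oracle <- oracle_ols(as.vector(y), cbind(1, X))
    expect_equal(fit$coefficients$estimate, unname(beta_oracle),
                 tolerance = 1e-8)
  }
  # exact fit: R^2 = 1 (lm warns about the perfect fit)
  x <- rnorm(15)
  fit <- suppressWarnings(ols_fit(2 + 3 * x, data.frame(x = x)))
  expect_equal(fit$r_squared, 1)
  # single binary predictor equals the pooled two-sample t
  g <- rep(0:1, c(8, 12)); y <- rnorm(20) + 0.8 * g
  fit <- ols_fit(y, data.frame(g = g))
  tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(fit$coefficients$statistic[2], unname(tt$statistic))
  # listwise deletion is reported
  y[3] <- NA
  expect_equal(ols_fit(y, data.frame(g = g))$n_used, 19)
  # collinearity names the offending column
  expect_error(ols_fit(y, data.frame(g = g, g2 = 2 * g)),
               regexp = "g2", class = "bftrans_error_collinearity")
})

test_that("interaction_model detects planted slope differences", {
  set.seed(3)
  # identical slopes, no noise: interaction exactly 0
  x <- rnorm(40); g <- rep(0:1, 20)
  y <- 1 + 0.7 * x
  tr <- interaction_model(y + rnorm(40, 0, 1e-8), x, g)
  expect_lt(abs(tr$estimate), 1e-6)
  # planted slope -0.5 vs 0 at n = 85, noise sd matched to the effect
  hits <- 0
  for (i in 1:200) {
    g <- rep(c(0, 1), c(29, 56))
    x <- rnorm(85)
    y <- ifelse(g == 0, -0.5 * x, 0) + rnorm(85, 0, 0.5)
    if (interaction_model(y, x, g)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.8)
  expect_error(interaction_model(y, x, rep(1, 85)),
               class = "bftrans_error_invalid_argument")
})

test_that("levene_test matches car and is calibrated", {
  v <- c(rnorm(20, sd = 1), rnorm(20, sd = 1))
  g <- rep(c("a", "b"), each = 20)
  mine <- levene_test(v, g)
  ref <- car::leveneTest(v, factor(g), center = median)
  expect_equal(mine$statistic, ref$`F value`[1])
  expect_equal(mine$p, ref$`Pr(>F)`[1])
  # identical values up to permutation: F = 0
  expect_equal(levene_test(c(1, 2, 3, 3, 2, 1), rep(c("a", "b"), each = 3))$statistic, 0)
  # type-I calibration and power
  set.seed(4)
  null_rej <- mean(replicate(600, {
    levene_test(rnorm(80), rep(c("a", "b"), 40))$p < 0.05
  }))
  expect_gt(null_rej, 0.025)
  expect_lt(null_rej, 0.075)
  power <- mean(replicate(300, {
    levene_test(c(rnorm(40, sd = 1), rnorm(40, sd = 2)),
                rep(c("a", "b"), each = 40))$p < 0.05
  }))
  expect_gt(power, 0.8)
  expect_error(levene_test(rnorm(5), c("a", rep("b", 4))),
               class = "bftrans_error_invalid_argument")
})

test_that("bh_fdr performs the step-up adjustment and controls FDR", {
  expect_equal(bh_fdr(0.37)$q, 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  # q >= p, order preserved, permutation invariant
  set.seed(5)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj$q >= adj$p_raw))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm])$q, adj$q[perm])
  expect_equal(adj$p_bonf_threshold, 0.05 / 50)
  expect_error(bh_fdr(c(0.1, 1.2)), class = "bftrans_error_invalid_argument")
  # null simulation: share of q < 0.10 discoveries stays near zero
  fdr_hits <- replicate(200, sum(bh_fdr(runif(500))$q < 0.10))
  expect_lte(mean(fdr_hits > 0), 0.15)
})

test_that("bonferroni thresholds match the analysis families", {
  expect_lt(bonferroni_threshold(3), 0.017)
  expect_equal(bonferroni_threshold(8), 6.25e-3)
  expect_equal(signif(bonferroni_threshold(12), 3), 4.17e-3)
})

test_that("t_from_summary reproduces t.test in both variants", {
  set.seed(6)
  a <- rnorm(30, 1); b <- rnorm(20)
  for (ve in c(TRUE, FALSE)) {
    mine <- t_from_summary(mean(a), sd(a), 30, mean(b), sd(b), 20,
                           var_equal = ve)
    ref <- t.test(a, b, var.equal = ve)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value)
  }
})
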