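# Sphericity, epsilon, split-plot ANOVA (vs independent oracles), post hocs.

test_that("Mauchly: k = 2 degenerates to W = 1; structured covariances behave", {
  set.seed(81)
  m2 <- mauchly_test(matrix(rnorm(24), 12, 2))
  expect_equal(m2$W, 1)
  expect_false(m2$applicable)
  # one dominant contrast variance drives W toward 0
  base <- matrix(rnorm(120, sd = 0.05), 30, 4)
  dom <- base + outer(rnorm(30, sd = 3), c(1, -1, 0, 0))
  expect_lt(mauchly_test(dom)$W, 0.05)
})

test_that("Mauchly type-I rate is near alpha under compound symmetry", {
  set.seed(82)
  reps <- 200
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    subj_eff <- rnorm(16)
    Y <- outer(subj_eff, rep(1, 4)) + matrix(rnorm(64), 16, 4)
    rej[r] <- mauchly_test(Y)$p.value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("Greenhouse-Geisser epsilon hits its analytic anchors and oracle", {
  # spherical: independent equal-variance contrasts => epsilon ~ 1
  set.seed(83)
  Y <- matrix(rnorm(4000), 1000, 4)
  expect_gt(gg_epsilon(Y), 0.98)
  # rank-1 contrast covariance: analytic lower bound 1/(k-1)
  r1 <- outer(rnorm(50), c(1, 2, 3, 4)) + 1e-8 * matrix(rnorm(200), 50, 4)
  expect_equal(gg_epsilon(r1), 1 / 3, tolerance = 1e-3)
  # random covariance vs a brute-force eigenvalue evaluation
  Y4 <- matrix(rnorm(200), 50, 4) %*% matrix(runif(16, -1, 1), 4, 4)
  Cq <- qr.Q(qr(stats::contr.helmert(4)))
  lam <- eigen(stats::cov(Y4 %*% Cq), symmetric = TRUE)$values
  expect_equal(gg_epsilon(Y4), sum(lam)^2 / (3 * sum(lam^2)),
               tolerance = 1e-10)
})

test_that("split-plot ANOVA matches the brute-force SS oracle on 50 random tables", {
  set.seed(84)
  for (r in 1:50) {
    tb <- random_table(G = sample(2:4, 1), n = sample(3:6, 1),
                       k = sample(2:4, 1))
    fit <- split_plot_anova(long_from_wide(tb$Y, tb$g))
    orc <- oracle_split_plot(tb$Y, tb$g)
    expect_equal(fit$table$F[fit$table$effect == "group"], orc$F_group,
                 tolerance = 1e-8)
    expect_equal(fit$table$F[fit$table$effect == "condition"], orc$F_cond,
                 tolerance = 1e-8)
    expect_equal(fit$table$F[fit$table$effect == "group:condition"],
                 orc$F_int, tolerance = 1e-8)
  }
})

test_that("split-plot ANOVA agrees with car::Anova on an unbalanced design", {
  skip_if_not_installed("car")
  set.seed(85)
  n <- c(6, 5, 7); k <- 3
  N <- sum(n)
  Y <- matrix(rnorm(N * k), N, k,
              dimnames = list(sprintf("S%02d", 1:N), paste0("c", 1:k)))
  g <- factor(rep(c("A", "B", "C"), n))
  Y[g == "B", 2] <- Y[g == "B", 2] + 1
  fit <- split_plot_anova(long_from_wide(Y, g))
  mlm <- stats::lm(Y ~ gg, data = data.frame(gg = g),
                   contrasts = list(gg = "contr.sum"))
  av <- suppressWarnings(  # car notes HF eps > 1, which it clamps itself
    summary(car::Anova(mlm, idata = data.frame(condition = factor(colnames(Y))),
                       idesign = ~condition, type = 3),
            multivariate = FALSE))
  ref <- av$univariate.tests
  expect_equal(fit$table$F, unname(ref[c("gg", "condition", "gg:condition"),
                                       "F value"]), tolerance = 1e-10)
  expect_equal(fit$epsilon,
               unname(av$pval.adjustments["condition", "GG eps"]),
               tolerance = 1e-10)
  expect_equal(fit$mauchly$W,
               unname(av$sphericity.tests["condition", "Test statistic"]),
               tolerance = 1e-10)
})

test_that("degenerate and invalid ANOVA inputs are caught", {
  # all responses equal -> F = 0 for every effect
  dat <- expand.grid(subject = sprintf("S%d", 1:8),
                     condition = c("EO", "EC"))
  dat$group <- rep(c("A", "B"), 4)[match(dat$subject,
                                         sprintf("S%d", 1:8))]
  dat$value <- 5
  fit <- split_plot_anova(dat)
  # zero variance everywhere: every effect F collapses to 0
  expect_lt(max(fit$table$SS), 1e-9)
  expect_true(all(fit$table$F == 0))
  expect_true(all(fit$table$p == 1))
  # missing cells are refused
  expect_error(split_plot_anova(dat[-1, ]),
               class = "liftpost_error_incomplete_design")
})

test_that("epsilon correction is conservative in the rejection region", {
  set.seed(86)
  for (r in 1:20) {
    tb <- random_table(G = 2, n = 5, k = 4)
    # inject a condition effect so some tests land in the tail
    tb$Y[, 2] <- tb$Y[, 2] + r / 10
    fit <- split_plot_anova(long_from_wide(tb$Y, tb$g))
    w <- fit$table$effect != "group" & fit$table$p <= 0.2
    expect_true(all(fit$table$p_gg[w] >= fit$table$p[w] - 1e-12))
    expect_gte(fit$epsilon, 1 / 3)
    expect_lte(fit$epsilon, 1)
  }
})

test_that("split-plot type-I error for the group effect is calibrated", {
  set.seed(87)
  reps <- 500
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    tb <- random_table(G = 3, n = 5, k = 2)
    fit <- split_plot_anova(long_from_wide(tb$Y, tb$g))
    rej[r] <- fit$table$p[fit$table$effect == "group"] < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Bonferroni adjustment and post hocs follow min(1, m p)", {
  expect_equal(bonferroni_adjust(0.03, 1), 0.03)
  expect_equal(bonferroni_adjust(0.02, 3), 0.06)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  set.seed(88)
  v <- c(rnorm(10), rnorm(10, 3), rnorm(10))
  g <- rep(c("A", "B", "C"), each = 10)
  ph <- bonferroni_posthoc(v, g)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_bonf, pmin(1, 3 * ph$p))
})

test_that("permutation test: null calibration, separation floor, determinism", {
  set.seed(89)
  ps <- replicate(200, {
    permutation_group_test(rnorm(18), rep(c("A", "B", "C"), 6),
                           n_perm = 199)$p.value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  sep <- permutation_group_test(c(rnorm(8), rnorm(8, 50)),
                                rep(c("A", "B"), each = 8), n_perm = 999,
                                seed = 1)
  expect_equal(sep$p.value, 1 / 1000)
  v2 <- rnorm(20)
  p1 <- permutation_group_test(v2, rep(c("A", "B"), 10),
                               n_perm = 199, seed = 7)$p.value
  p2 <- permutation_group_test(v2, rep(c("A", "B"), 10),
                               n_perm = 199, seed = 7)$p.value
  expect_equal(p1, p2)
})
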