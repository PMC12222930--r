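test_that("DerSimonian-Laird estimate matches the moment formula", {
  y <- c(0.1, 0.3, 0.5); vi <- rep(0.01, 3)
  expect_equal(cochran_q(y, vi), 8, tolerance = 1e-12)
  expect_equal(estimate_tau2_dl(y, vi), 0.03, tolerance = 1e-12)
  expect_identical(estimate_tau2_dl(rep(0.2, 4), rep(0.02, 4)), 0)
  expect_error(estimate_tau2_dl(0.1, 0.01), "at least 2")
  expect_error(estimate_tau2_dl(c(0.1, 0.2), c(0.01, 0)), "> 0")
})

test_that("REML estimate agrees with the grid oracle and with metafor", {
  expect_identical(estimate_tau2_reml(rep(0.2, 5), rep(0.01, 5)), 0)
  # strong separation forces tau2 far above the sampling variances
  expect_gt(estimate_tau2_reml(c(0, 10), c(0.01, 0.01)), 1)
  set.seed(21)
  for (i in 1:10) {
    s <- sim_effects(sample(5:25, 1), mu = 0.2, tau2 = runif(1, 0, 0.05))
    t2 <- estimate_tau2_reml(s$y, s$vi)
    expect_lt(abs(t2 - reml_grid_tau2(s$y, s$vi)), 1e-5)
    mf <- metafor::rma(s$y, s$vi, method = "REML",
                       control = list(tol = 1e-10))
    expect_lt(abs(t2 - mf$tau2), 1e-5)
  }
})

test_that("pooling reproduces the closed-form inverse-variance summary", {
  # equal variances, tau2 = 0: plain mean with se = sqrt(v/k)
  p0 <- pool(rep(0.2, 6), rep(0.012, 6))
  expect_equal(p0$mu, 0.2, tolerance = 1e-12)
  expect_equal(p0$tau2, 0)
  expect_equal(p0$se_mu, sqrt(0.012 / 6), tolerance = 1e-12)
  # worked micro-example at the DL tau2
  p1 <- pool(c(0.1, 0.3, 0.5), rep(0.01, 3), method = "DL")
  expect_equal(p1$tau2, 0.03, tolerance = 1e-12)
  expect_equal(p1$mu, 0.3, tolerance = 1e-12)
  expect_equal(p1$se_mu, sqrt(0.04 / 3), tolerance = 1e-12)
  expect_equal(p1$percent_mu, 100 * (exp(0.3) - 1), tolerance = 1e-12)
  expect_equal(p1$ci_low, 0.3 - 1.96 * sqrt(0.04 / 3), tolerance = 1e-12)
  # single study: the study itself, no test
  ps <- pool(0.4, 0.02)
  expect_equal(ps$mu, 0.4)
  expect_equal(ps$se_mu, sqrt(0.02))
  expect_true(is.na(ps$p))
  expect_error(pool(numeric(0), numeric(0)), "at least 1")
  expect_error(pool(c(0.1, 0.2), c(0.01, 0)), "> 0")
})

test_that("pooled mean stays inside the effects and respects invariance", {
  set.seed(22)
  for (i in 1:20) {
    s <- sim_effects(sample(3:15, 1), 0.1, 0.03)
    p <- pool(s$y, s$vi)
    expect_gte(p$mu, min(s$y)); expect_lte(p$mu, max(s$y))
    expect_gte(p$tau2, 0)
    expect_true(p$ci_low <= p$mu && p$mu <= p$ci_high)
    # permutation invariance (up to optimizer tolerance on tau2)
    o <- sample(length(s$y))
    expect_lt(abs(pool(s$y[o], s$vi[o])$p - p$p), 1e-7)
    # a study equal to mu leaves mu unchanged (weights held fixed)
    p2 <- pool(c(s$y, p$mu), c(s$vi, 0.01), tau2 = p$tau2)
    expect_equal(p2$mu, p$mu, tolerance = 1e-10)
  }
})

test_that("bootstrap interval is deterministic and sane", {
  set.seed(23)
  s <- sim_effects(15, 0.2, 0.02)
  b1 <- bootstrap_ci(s$y, s$vi, B = 1000, seed = 5)
  b2 <- bootstrap_ci(s$y, s$vi, B = 1000, seed = 5)
  expect_identical(b1, b2)
  expect_false(b1$degenerate)
  expect_lt(b1$ci_low, b1$ci_high)
  expect_error(bootstrap_ci(s$y, s$vi, B = 500, seed = 1), ">= 1000")
  expect_warning(bd <- bootstrap_ci(rep(0.3, 5), rep(0.01, 5), B = 1000,
                                    seed = 1), "degenerate")
  expect_equal(bd$ci_low, bd$ci_high)
  expect_true(bd$degenerate)
})

test_that("large homogeneous samples give BC intervals near the Wald width", {
  set.seed(24)
  s <- sim_effects(200, 0.15, 0)
  p <- pool(s$y, s$vi)
  b <- bootstrap_ci(s$y, s$vi, B = 1000, seed = 9)
  wald_width <- p$ci_high - p$ci_low
  expect_lt(abs((b$ci_high - b$ci_low) - wald_width) / wald_width, 0.2)
})

test_that("duration subgrouping splits at the boundary and tests the gap", {
  y <- c(0.35, 0.25, 0.31, 0.12, 0.08); vi <- rep(0.01, 5)
  dur <- c(2, 5.0, 4, 5.01, 8)   # 5.0 is short, 5.01 long
  sg <- subgroup_by_duration(y, vi, dur)
  expect_equal(sg$short$k, 3L)
  expect_equal(sg$long$k, 2L)
  expect_true(sg$contrast_available)
  expect_equal(sg$diff_z,
               (sg$short$mu - sg$long$mu) /
                 sqrt(sg$short$se_mu^2 + sg$long$se_mu^2))
  # identical subgroups: zero contrast, p = 1
  sg0 <- subgroup_by_duration(c(0.2, 0.2, 0.2, 0.2), rep(0.01, 4),
                              c(2, 3, 7, 9))
  expect_equal(sg0$diff_z, 0)
  expect_equal(sg0$diff_p, 1)
  # an empty subgroup disables the contrast
  sg1 <- subgroup_by_duration(y, vi, rep(2, 5))
  expect_null(sg1$long)
  expect_false(sg1$contrast_available)
  expect_true(is.na(sg1$diff_p))
  expect_error(subgroup_by_duration(y, vi, c(2, 3, 4, 0, 5)), "> 0")
})
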