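test_that("meta-regression recovers an exact linear relationship", {
  x <- c(1, 2, 3, 4, 5)
  f <- fit_meta_regression(1 + 2 * x, rep(1e-8, 5), x)
  expect_equal(f$beta0, 1, tolerance = 1e-4)
  expect_equal(f$beta1, 2, tolerance = 1e-4)
  expect_lt(f$tau2_resid, 1e-6)
  expect_lt(f$p1, 1e-10)
  # identifiability boundary: two distinct x values suffice at k = 3
  expect_s3_class(fit_meta_regression(c(0.1, 0.2, 0.3), rep(0.01, 3),
                                      c(1, 1, 2)), "meta_reg_result")
  expect_error(fit_meta_regression(c(0.1, 0.2, 0.3), rep(0.01, 3),
                                   rep(1, 3)), "constant moderator")
  expect_error(fit_meta_regression(c(0.1, 0.2, 0.3), rep(0.01, 3),
                                   c(-1, 1, 2), transform = "log"),
               "positive")
})

test_that("meta-regression agrees with metafor on a seeded dataset", {
  set.seed(51)
  k <- 30
  x <- runif(k, 0.05, 1.5)
  y <- 0.2 - 0.5 * log(x) + rnorm(k, 0, 0.2)
  v <- runif(k, 0.005, 0.02)
  f <- fit_meta_regression(y, v, x, transform = "log", method = "REML")
  mf <- metafor::rma(y, v, mods = ~ log(x), method = "REML",
                     control = list(tol = 1e-10))
  expect_equal(f$beta0, unname(mf$beta[1]), tolerance = 1e-6)
  expect_equal(f$beta1, unname(mf$beta[2]), tolerance = 1e-6)
  expect_equal(f$se1, mf$se[2], tolerance = 1e-6)
  expect_equal(f$tau2_resid, mf$tau2, tolerance = 1e-5)
  expect_equal(f$QM, mf$QM, tolerance = 1e-4)
  fml <- fit_meta_regression(y, v, x, transform = "log", method = "ML")
  expect_equal(fml$aic,
               stats::AIC(metafor::rma(y, v, mods = ~ log(x),
                                       method = "ML")),
               tolerance = 1e-5)
})

test_that("meta-regression structural identities hold", {
  set.seed(52)
  s <- sim_effects(25, 0.1, 0.02)
  x <- runif(25, -5, 20)
  f <- fit_meta_regression(s$y, s$vi, x)
  # single-moderator omnibus statistic is the squared slope z
  expect_equal(f$QM, f$z1^2, tolerance = 1e-10)
  # centering shifts only the intercept: exact at a common tau2 ...
  fc0 <- fit_meta_regression(s$y, s$vi, x - mean(x),
                             tau2 = f$tau2_resid)
  expect_equal(fc0$beta1, f$beta1, tolerance = 1e-10)
  expect_equal(fc0$z1, f$z1, tolerance = 1e-10)
  expect_equal(fc0$QM, f$QM, tolerance = 1e-10)
  # ... and to optimizer precision when tau2 is re-estimated
  fc <- fit_meta_regression(s$y, s$vi, x - mean(x))
  expect_lt(abs(fc$beta1 - f$beta1), 1e-6)
  expect_lt(abs(fc$tau2_resid - f$tau2_resid), 1e-7)
  # with no moderator the model reduces exactly to pooling
  f0 <- fit_meta_regression(s$y, s$vi, x = NULL, method = "REML")
  p0 <- pool(s$y, s$vi, method = "REML")
  expect_equal(f0$beta0, p0$mu, tolerance = 1e-10)
  expect_equal(f0$se0, p0$se_mu, tolerance = 1e-10)
  expect_equal(f0$tau2_resid, p0$tau2, tolerance = 1e-10)
  # residual heterogeneity cannot exceed the moderator-free ML fit
  fml <- fit_meta_regression(s$y, s$vi, x, method = "ML")
  f0ml <- fit_meta_regression(s$y, s$vi, x = NULL, method = "ML")
  expect_lte(fml$tau2_resid, f0ml$tau2_resid + 1e-8)
})

test_that("moderator selection ranks by ML AIC with declared tie-breaks", {
  set.seed(53)
  s <- sim_effects(20, 0.2, 0.02)
  x <- runif(20, 0.1, 2)
  single <- select_moderator(s$y, s$vi,
                             list(only = list(x = x, transform = "log")))
  expect_equal(single$best_name, "only")
  # byte-identical candidates: the first wins
  tie <- select_moderator(s$y, s$vi,
                          list(a = list(x = x, transform = "linear"),
                               b = list(x = x, transform = "linear")))
  expect_equal(tie$best_name, "a")
  # failing candidates are reported, not fatal, unless all fail
  mixed <- select_moderator(s$y, s$vi,
                            list(bad = list(x = rep(1, 20),
                                            transform = "linear"),
                                 good = list(x = x, transform = "log")))
  expect_equal(mixed$best_name, "good")
  expect_true(any(!is.na(mixed$ranking$error)))
  expect_error(select_moderator(s$y, s$vi,
                                list(bad = list(x = rep(1, 20),
                                                transform = "linear"))),
               "all candidate")
  # the reported best is refit with REML but keeps the comparable ML AIC
  expect_equal(single$best$method, "REML")
  expect_equal(single$best$aic, single$ranking$aic[1])
})

test_that("a true ln(AI) signal is found and labeled in the gradient report", {
  sim <- simulate_dataset(simulation_config(
    k_sites = 40, treatment = "drought", true_beta0 = -0.2,
    true_beta1 = -1, moderator = "aridity_index",
    moderator_transform = "log", seed = 61))
  es <- compute_effect_sizes(sim$studyset)
  rep <- sensitivity_gradient_report(es)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$moderator, "^AI")
  expect_equal(rep$label, "significant")
  expect_lt(rep$p, 0.05)
})

test_that("degenerate strata are reported as not estimable, never dropped", {
  df <- make_valid_records()[1:2, ]
  es <- compute_effect_sizes(study_set(df))
  rep <- sensitivity_gradient_report(es)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$label, "not_estimable")
  expect_equal(rep$k, 2L)
  expect_true(is.na(rep$slope))
})
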