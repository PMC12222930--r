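test_that("log response ratio and its variance match hand arithmetic", {
  expect_identical(compute_log_rr(100, 100), 0)
  expect_equal(compute_log_rr(200, 100), log(2), tolerance = 1e-15)
  expect_error(compute_log_rr(100, 0), "must be > 0")
  expect_error(compute_log_rr(-1, 100), "must be > 0")

  # 10^2/(5*100^2) + 20^2/(4*200^2) = 0.002 + 0.0025
  expect_equal(compute_variance(100, 10, 5, 200, 20, 4), 0.0045,
               tolerance = 1e-15)
  expect_identical(compute_variance(100, 0, 5, 200, 0, 4), 0)
  # symmetric arms reduce to 2 s^2 / (n m^2)
  expect_equal(compute_variance(80, 6, 4, 80, 6, 4), 2 * 36 / (4 * 80^2),
               tolerance = 1e-15)
  expect_error(compute_variance(100, 10, 1, 200, 20, 4), ">= 2")
})

test_that("variance is invariant to common rescaling of both arms", {
  set.seed(31)
  for (i in 1:50) {
    m <- runif(2, 10, 500); s <- runif(2, 0, 50); n <- sample(2:8, 2, TRUE)
    c0 <- runif(1, 0.01, 100)
    expect_equal(compute_variance(m[1], s[1], n[1], m[2], s[2], n[2]),
                 compute_variance(c0 * m[1], c0 * s[1], n[1],
                                  c0 * m[2], c0 * s[2], n[2]),
                 tolerance = 1e-9)
  }
})

test_that("percent transform is exact and invertible", {
  expect_identical(to_percent(0), 0)
  expect_equal(to_percent(log(2)), 100, tolerance = 1e-12)
  expect_equal(to_percent(-log(2)), -50, tolerance = 1e-12)
  set.seed(7)
  rr <- runif(200, -3, 3)
  expect_equal(from_percent(to_percent(rr)), rr, tolerance = 1e-12)
  # antisymmetry: swapping arms negates rr and maps percent accordingly
  p <- to_percent(rr)
  expect_equal(to_percent(-rr), 100 * (1 / (1 + p / 100) - 1),
               tolerance = 1e-9)
  expect_error(to_percent(Inf), "finite")
})

test_that("sensitivity standardises by the treatment's driver unit", {
  expect_equal(to_sensitivity(30, "warming", 2), 15)
  expect_equal(to_sensitivity(-10, "nitrogen", 5), -2)
  # drought: per 10 mm of change, sign of percent preserved
  expect_equal(to_sensitivity(-45, "drought", -150), -3)
  expect_equal(to_sensitivity(24, "increased_precipitation", 80), 3)
  expect_error(to_sensitivity(10, "warming", 0), "non-zero")
  expect_error(to_sensitivity(10, "warming_nitrogen", 2), "combination")
  # homogeneity of degree -1 in the driver magnitude
  set.seed(8)
  for (i in 1:50) {
    pc <- runif(1, -60, 120); d <- runif(1, 0.1, 200)
    tr <- sample(SINGLE_DRIVER_TREATMENTS, 1)
    if (tr == "drought") d <- -d
    expect_equal(to_sensitivity(pc, tr, 2 * d),
                 to_sensitivity(pc, tr, d) / 2, tolerance = 1e-12)
  }
})

test_that("timepoint aggregation averages means and SDs", {
  expect_equal(aggregate_timepoints(10, 2), c(mean = 10, sd = 2))
  expect_equal(aggregate_timepoints(c(10, 20, 30), c(2, 4, 6)),
               c(mean = 20, sd = 4))
  expect_error(aggregate_timepoints(numeric(0), numeric(0)), "no timepoints")
  expect_error(aggregate_timepoints(c(1, 2), c(1, -1)), ">= 0")

  df <- make_valid_records()
  dup <- df[c(1, 1, 2, 3), ]
  dup$mean_treat[2] <- 140; dup$sd_treat[2] <- 16
  ss <- aggregate_studyset(study_set(dup))
  expect_equal(nrow(ss$records), 3L)
  expect_equal(ss$records$mean_treat[1], (120 + 140) / 2)
  expect_equal(ss$records$sd_treat[1], (12 + 16) / 2)
  key <- with(ss$records, paste(site_id, metric, treatment, driver_window))
  expect_false(anyDuplicated(key) > 0)
})

test_that("effect-size table is internally consistent", {
  df <- make_valid_records()
  es <- compute_effect_sizes(study_set(df))
  expect_equal(nrow(es), 3L)
  expect_equal(es$rr, log(df$mean_treat / df$mean_ctrl))
  expect_equal(es$percent, 100 * (exp(es$rr) - 1))
  expect_equal(es$se, sqrt(es$vi))
  expect_equal(es$sensitivity, es$percent / df$driver_magnitude)
  # delta-rule variance on the sensitivity scale
  expect_equal(es$sens_vi,
               (100 * exp(es$rr))^2 * es$vi / df$driver_magnitude^2)
  # duplicate keys must be collapsed first
  expect_error(compute_effect_sizes(study_set(df[c(1, 1, 2), ])),
               "duplicate")
  # combination treatments carry no sensitivity
  df$treatment <- "warming_nitrogen"
  es2 <- compute_effect_sizes(study_set(df))
  expect_true(all(is.na(es2$sensitivity)))
})

test_that("annual and growing-season warming rows are compiled per site", {
  df <- make_valid_records()
  extra <- df[1, ]
  extra$driver_window <- "growing_season"
  extra$mean_treat <- 130; extra$driver_magnitude <- 2.5
  es <- compute_effect_sizes(study_set(rbind(df, extra)))
  out <- compile_warming_windows(es)
  expect_equal(nrow(out), 3L)
  s1 <- out[out$site_id == "s1", ]
  expect_equal(s1$driver_window, "compiled")
  both <- es[es$site_id == "s1", ]
  expect_equal(s1$sensitivity, mean(both$sensitivity))
  expect_equal(s1$rr, mean(both$rr))
  # non-warming tables pass through untouched
  es_n <- es[es$driver_window == "annual", ]
  es_n$treatment <- "nitrogen"
  expect_identical(compile_warming_windows(es_n), es_n)
})
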