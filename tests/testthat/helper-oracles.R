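# Independent oracles and small simulators shared across test files.
# Deliberately written from the formulas directly, not via package code.

# DerSimonian-Laird moment estimator, step by step.
dl_tau2_oracle <- function(y, vi) {
  w <- 1 / vi
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (length(y) - 1)) / cc)
}

# Inverse-variance pooled mean and SE at a given tau2.
pool_oracle <- function(y, vi, tau2) {
  w <- 1 / (vi + tau2)
  list(mu = sum(w * y) / sum(w), se = 1 / sqrt(sum(w)))
}

# Restricted log-likelihood of the intercept-only random-effects model.
restricted_ll <- function(tau2, y, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

# Grid-search REML maximizer: coarse pass over [0, upper], then a fine
# grid at step `fine` around the coarse maximizer.
reml_grid_tau2 <- function(y, vi, fine = 1e-6, coarse = 1e-3) {
  upper <- max(10 * stats::var(y), 10 * max(vi), 0.1)
  g1 <- seq(0, upper, by = coarse)
  v1 <- vapply(g1, restricted_ll, numeric(1), y = y, vi = vi)
  c1 <- g1[which.max(v1)]
  g2 <- seq(max(0, c1 - 2 * coarse), c1 + 2 * coarse, by = fine)
  v2 <- vapply(g2, restricted_ll, numeric(1), y = y, vi = vi)
  g2[which.max(v2)]
}

# Effect-level meta-analysis sample: y_i ~ N(mu, vi_i + tau2).
sim_effects <- function(k, mu, tau2, vi_range = c(0.005, 0.02)) {
  vi <- stats::runif(k, vi_range[1], vi_range[2])
  list(y = stats::rnorm(k, mu, sqrt(vi + tau2)), vi = vi)
}

# A small hand-built valid records table (3 sites, one stratum).
make_valid_records <- function() {
  data.frame(
    site_id = c("s1", "s2", "s3"),
    metric = "AGB", treatment = "warming",
    mean_treat = c(120, 95, 210), mean_ctrl = c(100, 90, 180),
    sd_treat = c(12, 10, 25), sd_ctrl = c(11, 9, 20),
    n_treat = c(4L, 5L, 3L), n_ctrl = c(4L, 5L, 3L),
    driver_magnitude = c(1.5, 2.0, 3.0),
    driver_window = "annual",
    duration_yr = c(3, 6, 4.5),
    mat_c = c(2.5, 8.0, 15.0),
    aridity_index = c(0.2, 0.6, 1.1),
    stringsAsFactors = FALSE)
}
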