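.check_meta_input <- function(effects, variances, min_k = 2L,
                              positive_vi = TRUE) {
  if (length(effects) != length(variances))
    stop("effects and variances differ in length")
  if (length(effects) < min_k)
    stop("at least ", min_k, " studies required (got ",
         length(effects), ")")
  if (any(!is.finite(effects)) || any(!is.finite(variances)))
    stop("effects and variances must be finite")
  if (positive_vi && any(variances <= 0))
    stop("all sampling variances must be > 0")
  invisible(TRUE)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w (y - ybar_w)^2 with fixed-effect weights w = 1/vi; under
#' homogeneity Q ~ chi-square with k - 1 degrees of freedom.
#'
#' @param effects log response ratios.
#' @param variances their sampling variances (> 0).
#' @return the Q statistic.
#' @export
cochran_q <- function(effects, variances) {
  .check_meta_input(effects, variances, min_k = 1L)
  w <- 1 / variances
  ybar <- sum(w * effects) / sum(w)
  sum(w * (effects - ybar)^2)
}

#' DerSimonian-Laird estimate of between-study variance
#'
#' Moment estimator tau2 = max(0, (Q - (k - 1)) / C) with
#' C = sum w - sum w^2 / sum w, w = 1/vi.
#'
#' @inheritParams cochran_q
#' @return tau2 >= 0.
#' @export
estimate_tau2_dl <- function(effects, variances) {
  .check_meta_input(effects, variances)
  k <- length(effects)
  w <- 1 / variances
  q <- cochran_q(effects, variances)
  cc <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / cc)
}

# Restricted (REML) and full (ML) log-likelihood of the random-effects
# model y ~ N(X beta, diag(vi + tau2)), up to the -n/2 log(2 pi)
# constant for REML profiles (the full constant is kept for AIC).
.meta_loglik <- function(tau2, y, vi, X, restricted = TRUE) {
  w <- 1 / (vi + tau2)
  xtwx <- crossprod(X, w * X)
  beta <- solve(xtwx, crossprod(X, w * y))
  r <- y - X %*% beta
  ll <- -0.5 * (sum(log(vi + tau2)) + sum(w * r^2))
  if (restricted) ll <- ll - 0.5 * determinant(xtwx)$modulus[1]
  as.numeric(ll)
}

.fit_tau2 <- function(y, vi, X, method = c("REML", "ML"),
                      tol = 1e-10) {
  method <- match.arg(method)
  restricted <- method == "REML"
  upper <- max(10 * stats::var(y), 10 * max(vi), 0.1)
  f <- function(t2) .meta_loglik(t2, y, vi, X, restricted)
  opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = tol)
  # the optimum can sit on the tau2 = 0 boundary, where optimize()
  # never evaluates exactly; take whichever is better
  if (f(0) >= opt$objective) 0 else opt$maximum
}

#' REML estimate of between-study variance
#'
#' Maximiser of the restricted log-likelihood of
#' y_i ~ Normal(mu, vi_i + tau2) over tau2 >= 0, found by golden-section
#' search on the profiled restricted likelihood (tolerance 1e-10 on
#' tau2), with the tau2 = 0 boundary checked explicitly.
#'
#' @inheritParams cochran_q
#' @return tau2 >= 0.
#' @export
estimate_tau2_reml <- function(effects, variances) {
  .check_meta_input(effects, variances)
  X <- matrix(1, length(effects), 1L)
  .fit_tau2(effects, variances, X, method = "REML")
}

#' Random-effects pooling of one metric x treatment stratum
#'
#' Pools log response ratios with inverse-variance random-effects
#' weights w* = 1/(vi + tau2): mu = sum(w* y)/sum(w*),
#' se = sum(w*)^(-1/2), Wald z = mu/se with a two-sided normal p-value,
#' and the 95% interval mu +/- 1.96 se. tau2 is estimated by REML
#' (default) or DerSimonian-Laird unless supplied. A single-study
#' stratum is returned as-is with tau2 = 0 and no test (z, p, Q are
#' `NA`). Percentage-scale transforms of mu and the CI are included.
#'
#' @inheritParams cochran_q
#' @param method tau2 estimator, `"REML"` or `"DL"`.
#' @param tau2 optional fixed tau2 (skips estimation).
#' @return an object of class `pooled_result`.
#' @export
pool <- function(effects, variances, method = c("REML", "DL"),
                 tau2 = NULL) {
  method <- match.arg(method)
  .check_meta_input(effects, variances, min_k = 1L)
  k <- length(effects)
  if (k == 1L) {
    mu <- effects[1]; se <- sqrt(variances[1])
    res <- list(k = 1L, mu = mu, se_mu = se, tau2 = 0,
                ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se,
                z = NA_real_, p = NA_real_, Q = NA_real_,
                method = method)
  } else {
    if (is.null(tau2))
      tau2 <- if (method == "DL") estimate_tau2_dl(effects, variances)
              else estimate_tau2_reml(effects, variances)
    w <- 1 / (variances + tau2)
    mu <- sum(w * effects) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- mu / se
    res <- list(k = k, mu = mu, se_mu = se, tau2 = tau2,
                ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se,
                z = z, p = 2 * stats::pnorm(-abs(z)),
                Q = cochran_q(effects, variances), method = method)
  }
  res$percent_mu <- to_percent(res$mu)
  res$percent_ci_low <- to_percent(res$ci_low)
  res$percent_ci_high <- to_percent(res$ci_high)
  structure(res, class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("<pooled_result> k=%d  mu=%.4f (SE %.4f)  tau2=%.4f [%s]\n",
              x$k, x$mu, x$se_mu, x$tau2, x$method))
  cat(sprintf("  percent: %.2f%% [%.2f, %.2f]", x$percent_mu,
              x$percent_ci_low, x$percent_ci_high))
  if (!is.na(x$p)) cat(sprintf("  z=%.3f p=%.4g", x$z, x$p))
  cat("\n")
  invisible(x)
}

#' Bias-corrected bootstrap confidence interval for the pooled effect
#'
#' Resamples studies with replacement B times, re-pools each replicate
#' (re-estimating tau2), and returns the bias-corrected (BC, no
#' acceleration) 95% percentile interval: z0 is the normal quantile of
#' the fraction of replicates below the point estimate. Deterministic
#' given `seed`. If the effects are all identical the interval
#' degenerates to the point estimate and `degenerate` is flagged.
#'
#' @inheritParams pool
#' @param B number of bootstrap replicates (>= 1000).
#' @param seed integer RNG seed.
#' @param level confidence level.
#' @return list with `ci_low`, `ci_high`, `degenerate`.
#' @export
bootstrap_ci <- function(effects, variances, B = 2000L, seed = 1L,
                         method = c("REML", "DL"), level = 0.95) {
  method <- match.arg(method)
  .check_meta_input(effects, variances)
  if (B < 1000L) stop("B must be >= 1000")
  k <- length(effects)
  hat <- pool(effects, variances, method = method)$mu
  if (length(unique(effects)) == 1L) {
    warning("all effects identical: degenerate bootstrap interval")
    return(list(ci_low = hat, ci_high = hat, degenerate = TRUE))
  }
  boot <- numeric(B)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(k, k, replace = TRUE)
    boot[b] <- pool(effects[idx], variances[idx], method = method)$mu
  }
  # BC adjustment; clamp the below-fraction away from 0/1 so z0 is finite
  frac <- min(max(mean(boot < hat), 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(frac)
  alpha <- (1 - level) / 2
  lo_p <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  qs <- stats::quantile(boot, c(lo_p, hi_p), names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], degenerate = FALSE)
}

#' Short-term versus long-term subgroup contrast
#'
#' Splits a stratum at the duration boundary (short-term: 1-5 yr,
#' long-term: > 5 yr), pools each subgroup separately, and tests their
#' difference with diff_z = (mu_s - mu_l)/sqrt(se_s^2 + se_l^2) against
#' the standard normal. An empty subgroup is reported absent and the
#' contrast marked unavailable.
#'
#' @inheritParams pool
#' @param duration_yr experiment durations (years, > 0), one per study.
#' @param boundary split point in years (default 5; short is <= boundary).
#' @return list with `short`, `long` (each a `pooled_result` or `NULL`),
#'   `diff_z`, `diff_p`, `contrast_available`.
#' @export
subgroup_by_duration <- function(effects, variances, duration_yr,
                                 method = c("REML", "DL"),
                                 boundary = 5) {
  method <- match.arg(method)
  if (length(duration_yr) != length(effects))
    stop("duration_yr must match effects in length")
  if (any(!(duration_yr > 0))) stop("duration_yr must be > 0")
  is_short <- duration_yr <= boundary
  pool_sub <- function(sel)
    if (any(sel)) pool(effects[sel], variances[sel], method = method)
    else NULL
  short <- pool_sub(is_short)
  long <- pool_sub(!is_short)
  if (is.null(short) || is.null(long)) {
    return(list(short = short, long = long, diff_z = NA_real_,
                diff_p = NA_real_, contrast_available = FALSE))
  }
  dz <- (short$mu - long$mu) / sqrt(short$se_mu^2 + long$se_mu^2)
  list(short = short, long = long, diff_z = dz,
       diff_p = 2 * stats::pnorm(-abs(dz)), contrast_available = TRUE)
}
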