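.default_driver_ranges <- list(
  warming = c(0.5, 4),                 # degrees C of warming
  increased_precipitation = c(30, 120),# mm yr-1 added
  drought = c(-120, -30),              # mm yr-1 removed
  nitrogen = c(2, 10))                 # g N m-2 yr-1

#' Configuration of a synthetic multi-site experiment network
#'
#' Parameterises [simulate_dataset()]: the true effect structure (an
#' intercept and optionally a slope on a site climate moderator, on the
#' log response-ratio scale), between-site heterogeneity, within-plot
#' noise, replication, driver magnitudes, duration mix, site climate
#' supports, publication censoring, and the seed. Defaults emulate a
#' single-treatment arm of a global shrubland experiment network:
#' about 30 sites, 3-6 plot replicates per arm, 20% within-plot
#' relative SD, and moderate between-site heterogeneity.
#'
#' @param k_sites number of sites (one record per site).
#' @param treatment,metric stratum the records belong to.
#' @param true_beta0 true mean log response ratio (at g(x) = 0 when a
#'   moderator slope is set).
#' @param true_beta1 true slope of the log response ratio on the
#'   transformed moderator (0 = no climate dependence).
#' @param moderator which site covariate carries the trend:
#'   `"aridity_index"` or `"mat_c"`.
#' @param moderator_transform `"linear"` or `"log"` (natural log).
#' @param tau2 between-site variance of the true log response ratio.
#' @param sigma_rel within-plot relative SD (SD/mean) in each arm.
#' @param n_reps integer range `c(min, max)` of replicates per arm.
#' @param ctrl_mean_range support of the control mean (native units).
#' @param driver_range support of the driver magnitude; defaults depend
#'   on the treatment (warming +0.5-4 degC, precipitation +30-120 mm,
#'   drought -120 to -30 mm, nitrogen 2-10 g N m-2 yr-1).
#' @param duration_mix fraction of sites with duration > 5 yr.
#' @param aridity_range,mat_range supports of the site covariates.
#' @param censor_strength probability that a non-significant study is
#'   dropped by [apply_publication_censoring()].
#' @param seed integer seed; drives per-site substreams so earlier
#'   sites' draws are unchanged when `k_sites` grows.
#' @return validated object of class `simulation_config`.
#' @export
simulation_config <- function(k_sites = 30L,
                              treatment = "warming",
                              metric = "AGB",
                              true_beta0 = 0.1,
                              true_beta1 = 0,
                              moderator = c("aridity_index", "mat_c"),
                              moderator_transform = c("log", "linear"),
                              tau2 = 0.02,
                              sigma_rel = 0.2,
                              n_reps = c(3L, 6L),
                              ctrl_mean_range = c(50, 500),
                              driver_range = NULL,
                              duration_mix = 0.3,
                              aridity_range = c(0.05, 1.5),
                              mat_range = c(-5, 20),
                              censor_strength = 0,
                              seed = 1L) {
  moderator <- match.arg(moderator)
  moderator_transform <- match.arg(moderator_transform)
  if (is.null(driver_range))
    driver_range <- .default_driver_ranges[[treatment]]
  cfg <- list(k_sites = as.integer(k_sites), treatment = treatment,
              metric = metric, true_beta0 = true_beta0,
              true_beta1 = true_beta1, moderator = moderator,
              moderator_transform = moderator_transform, tau2 = tau2,
              sigma_rel = sigma_rel, n_reps = as.integer(n_reps),
              ctrl_mean_range = ctrl_mean_range,
              driver_range = driver_range, duration_mix = duration_mix,
              aridity_range = aridity_range, mat_range = mat_range,
              censor_strength = censor_strength, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @param cfg a candidate configuration list.
#' @export
validate_simulation_config <- function(cfg) {
  ok <- function(cond, what) if (!isTRUE(cond)) stop("invalid config: ", what)
  ok(cfg$k_sites >= 1, "k_sites must be >= 1")
  ok(cfg$treatment %in% SINGLE_DRIVER_TREATMENTS,
     "treatment must be a single-driver treatment")
  ok(cfg$metric %in% METRICS, "unknown metric")
  ok(cfg$tau2 >= 0, "tau2 must be >= 0")
  ok(cfg$sigma_rel > 0, "sigma_rel must be > 0")
  ok(length(cfg$n_reps) == 2 && cfg$n_reps[1] >= 2 &&
       cfg$n_reps[2] >= cfg$n_reps[1], "n_reps must be a range with min >= 2")
  ok(length(cfg$ctrl_mean_range) == 2 && cfg$ctrl_mean_range[1] > 0 &&
       cfg$ctrl_mean_range[2] >= cfg$ctrl_mean_range[1],
     "ctrl_mean_range must be a positive non-empty interval")
  ok(length(cfg$driver_range) == 2 &&
       cfg$driver_range[2] >= cfg$driver_range[1],
     "driver_range must be a non-empty interval")
  if (cfg$treatment == "drought") ok(cfg$driver_range[2] < 0,
     "drought driver_range must be negative")
  else ok(cfg$driver_range[1] > 0,
     "driver_range must be positive for this treatment")
  ok(cfg$duration_mix >= 0 && cfg$duration_mix <= 1,
     "duration_mix must be in [0, 1]")
  ok(cfg$aridity_range[1] > 0, "aridity_range must be positive")
  ok(cfg$censor_strength >= 0 && cfg$censor_strength <= 1,
     "censor_strength must be in [0, 1]")
  ok(is.finite(cfg$seed) && abs(cfg$seed) < 2^31, "seed must be a 32-bit integer")
  invisible(cfg)
}

# Derived per-site seed: a fixed substream per site index so that
# increasing k_sites appends sites without disturbing earlier draws.
# Stays below 2^31 - 1 for site indices up to 20000.
.site_seed <- function(seed, i) {
  (abs(seed) %% 100000) * 20000 + (i %% 20000)
}

.run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# Sample mean and SD of one arm of n plots with true mean mu and
# relative SD sigma_rel: mean ~ N(mu, (sigma_rel mu)^2 / n) (redrawn if
# non-positive), SD from the exact chi-square sampling law.
.draw_arm <- function(mu, sigma_rel, n) {
  sd_true <- sigma_rel * mu
  m <- stats::rnorm(1, mu, sd_true / sqrt(n))
  redraws <- 0L
  while (m <= 0) {   # multiplicative noise keeps this very rare
    m <- stats::rnorm(1, mu, sd_true / sqrt(n))
    redraws <- redraws + 1L
    if (redraws > 1000L) stop("arm mean repeatedly non-positive")
  }
  s <- sd_true * sqrt(stats::rchisq(1, n - 1) / (n - 1))
  list(mean = m, sd = s, redraws = redraws)
}

#' Simulate a multi-site experiment network with known truth
#'
#' For each site: a climate moderator is drawn uniformly on its
#' support; the true log response ratio is
#' theta_i = beta0 + beta1 g(x_i) + Normal(0, tau2); a control mean is
#' drawn and the treatment mean set to ctrl * exp(theta_i); each arm's
#' sample mean and sample SD are drawn from the normal and chi-square
#' sampling laws at the configured relative SD and replicate count.
#' Deterministic given the config seed, with per-site substreams.
#'
#' @param config a [simulation_config()].
#' @return list with `studyset` (a [study_set()]), and `truth` (list:
#'   per-site `theta`, `beta0`, `beta1`, `moderator`, `transform`,
#'   `tau2`, `redraws`).
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  k <- config$k_sites
  rows <- vector("list", k)
  theta <- numeric(k)
  redraws <- 0L
  for (i in seq_len(k)) {
    site <- .run_seeded(.site_seed(config$seed, i), {
      ai <- stats::runif(1, config$aridity_range[1], config$aridity_range[2])
      mat <- stats::runif(1, config$mat_range[1], config$mat_range[2])
      x <- if (config$moderator == "aridity_index") ai else mat
      gx <- if (config$moderator_transform == "log") log(x) else x
      th <- config$true_beta0 + config$true_beta1 * gx +
        stats::rnorm(1, 0, sqrt(config$tau2))
      mu_c <- stats::runif(1, config$ctrl_mean_range[1],
                           config$ctrl_mean_range[2])
      mu_t <- mu_c * exp(th)
      reps <- seq(config$n_reps[1], config$n_reps[2])
      n_t <- reps[sample.int(length(reps), 1)]
      n_c <- reps[sample.int(length(reps), 1)]
      arm_t <- .draw_arm(mu_t, config$sigma_rel, n_t)
      arm_c <- .draw_arm(mu_c, config$sigma_rel, n_c)
      drv <- stats::runif(1, config$driver_range[1], config$driver_range[2])
      dur <- if (stats::runif(1) < config$duration_mix)
        stats::runif(1, 5.5, 12) else stats::runif(1, 1, 5)
      list(row = data.frame(
             site_id = sprintf("site_%03d", i),
             metric = config$metric, treatment = config$treatment,
             mean_treat = arm_t$mean, mean_ctrl = arm_c$mean,
             sd_treat = arm_t$sd, sd_ctrl = arm_c$sd,
             n_treat = n_t, n_ctrl = n_c, driver_magnitude = drv,
             driver_window = "annual", duration_yr = dur,
             mat_c = mat, aridity_index = ai,
             stringsAsFactors = FALSE),
           theta = th, redraws = arm_t$redraws + arm_c$redraws)
    })
    rows[[i]] <- site$row
    theta[i] <- site$theta
    redraws <- redraws + site$redraws
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  list(studyset = study_set(df, provenance = sprintf(
         "simulated(%s, %s, seed=%d)", config$metric, config$treatment,
         config$seed)),
       truth = list(theta = theta, beta0 = config$true_beta0,
                    beta1 = config$true_beta1,
                    moderator = config$moderator,
                    transform = config$moderator_transform,
                    tau2 = config$tau2, redraws = redraws))
}

#' Apply publication censoring to a study set
#'
#' Emulates the file-drawer mechanism that funnel asymmetry diagnostics
#' must detect: each study whose per-study Wald test (rr / sqrt(vi)) is
#' non-significant at alpha = 0.05 is dropped independently with
#' probability `censor_strength`; significant studies are always kept.
#' Deterministic given `seed`.
#'
#' @param x a [study_set()].
#' @param censor_strength drop probability in [0, 1].
#' @param seed integer seed.
#' @param alpha per-study significance level (default 0.05).
#' @return list with `studyset` (censored) and `kept` (logical vector
#'   of censoring decisions).
#' @export
apply_publication_censoring <- function(x, censor_strength, seed = 1L,
                                        alpha = 0.05) {
  stopifnot(inherits(x, "study_set"))
  if (censor_strength < 0 || censor_strength > 1)
    stop("censor_strength must be in [0, 1]")
  df <- x$records
  rr <- compute_log_rr(df$mean_treat, df$mean_ctrl)
  vi <- compute_variance(df$mean_treat, df$sd_treat, df$n_treat,
                         df$mean_ctrl, df$sd_ctrl, df$n_ctrl)
  p <- 2 * stats::pnorm(-abs(rr / sqrt(vi)))
  kept <- .run_seeded(seed, {
    u <- stats::runif(nrow(df))
    p < alpha | u >= censor_strength
  })
  list(studyset = study_set(df[kept, , drop = FALSE],
                            provenance = paste0(x$provenance, "+censored"),
                            n_dropped = x$n_dropped),
       kept = kept)
}

#' Write a deterministic battery of CSV fixtures
#'
#' Generates small named scenarios (null, heterogeneous,
#' moderator-driven, censored, duration-split, degenerate k = 1 and
#' k = 2 strata) as records CSVs with truth sidecar JSONs, for tests
#' and documentation. Running twice produces identical files.
#'
#' @param out_dir writable directory (created if absent).
#' @return invisible character vector of the files written.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, sim, kept = NULL) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    json <- file.path(out_dir, paste0(name, "_truth.json"))
    write_records(sim$studyset, csv)
    truth <- sim$truth
    if (!is.null(kept)) truth$kept <- kept
    write_results(truth, json)
    written <<- c(written, csv, json)
  }
  emit("null", simulate_dataset(simulation_config(
    k_sites = 20L, true_beta0 = 0, tau2 = 0, seed = 101L)))
  emit("heterogeneous", simulate_dataset(simulation_config(
    k_sites = 25L, true_beta0 = 0.15, tau2 = 0.05, seed = 102L)))
  emit("moderator", simulate_dataset(simulation_config(
    k_sites = 40L, treatment = "drought", true_beta0 = -0.2,
    true_beta1 = -0.5, moderator = "aridity_index",
    moderator_transform = "log", seed = 103L)))
  cens_sim <- simulate_dataset(simulation_config(
    k_sites = 60L, true_beta0 = 0.1, tau2 = 0.01, seed = 104L))
  cens <- apply_publication_censoring(cens_sim$studyset, 0.8, seed = 104L)
  emit("censored", list(studyset = cens$studyset,
                        truth = cens_sim$truth), kept = cens$kept)
  emit("duration", simulate_dataset(simulation_config(
    k_sites = 30L, true_beta0 = 0.2, duration_mix = 0.5, seed = 105L)))
  deg <- simulate_dataset(simulation_config(
    k_sites = 1L, metric = "H", seed = 106L))
  deg2 <- simulate_dataset(simulation_config(
    k_sites = 2L, metric = "SP", seed = 107L))
  both <- study_set(rbind(deg$studyset$records, deg2$studyset$records),
                    provenance = "simulated(degenerate)")
  emit("degenerate", list(studyset = both,
                          truth = list(theta = c(deg$truth$theta,
                                                 deg2$truth$theta),
                                       beta0 = 0.1, beta1 = 0,
                                       tau2 = 0.02)))
  invisible(written)
}
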