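#' Log response ratio of one treatment-control contrast
#'
#' RR = ln(mean_treat / mean_ctrl): positive when the treatment
#' increases the metric, zero when the arms are equal.
#'
#' @param mean_treat,mean_ctrl strictly positive arm means.
#' @return the natural-log response ratio.
#' @export
compute_log_rr <- function(mean_treat, mean_ctrl) {
  if (any(!(mean_treat > 0)) || any(!(mean_ctrl > 0)))
    stop("log response ratio undefined: arm means must be > 0")
  log(mean_treat / mean_ctrl)
}

#' Sampling variance of the log response ratio
#'
#' vi = sd_t^2 / (n_t * mean_t^2) + sd_c^2 / (n_c * mean_c^2): the
#' delta-method variance of ln(Xt/Xc) from the two arm summaries. Each
#' arm contributes its squared relative error over its replicate count,
#' so vi is invariant to rescaling both arms by a common factor.
#'
#' @param mean_treat,mean_ctrl strictly positive arm means.
#' @param sd_treat,sd_ctrl non-negative arm standard deviations.
#' @param n_treat,n_ctrl replicate counts, both >= 2.
#' @return the sampling variance (dimensionless).
#' @export
compute_variance <- function(mean_treat, sd_treat, n_treat,
                             mean_ctrl, sd_ctrl, n_ctrl) {
  if (any(!(n_treat >= 2)) || any(!(n_ctrl >= 2)))
    stop("replicate counts must be >= 2 in both arms")
  if (any(!(mean_treat > 0)) || any(!(mean_ctrl > 0)))
    stop("arm means must be > 0")
  sd_treat^2 / (n_treat * mean_treat^2) +
    sd_ctrl^2 / (n_ctrl * mean_ctrl^2)
}

#' Percentage change from a log response ratio
#'
#' percent = 100 * (exp(rr) - 1); the reporting scale of the pooled
#' figures. Strictly increasing in rr and bounded below by -100.
#'
#' @param rr log response ratio(s), finite.
#' @return percentage change(s).
#' @export
to_percent <- function(rr) {
  if (any(!is.finite(rr))) stop("rr must be finite")
  100 * (exp(rr) - 1)
}

#' Log response ratio from a percentage change (inverse of [to_percent()])
#' @param percent percentage change(s), each > -100.
#' @return rr value(s).
#' @export
from_percent <- function(percent) {
  if (any(!(percent > -100))) stop("percent must exceed -100")
  log(1 + percent / 100)
}

# Driver divisor that standardises a percentage change to the
# per-unit sensitivity scale. Precipitation changes are expressed per
# 10 mm of change, warming per degree C, nitrogen per g N m-2 yr-1.
driver_divisor <- function(treatment, driver_magnitude) {
  if (any(driver_magnitude == 0)) stop("driver magnitude must be non-zero")
  unsupported <- !(treatment %in% SINGLE_DRIVER_TREATMENTS)
  if (any(unsupported))
    stop("sensitivity is not defined for combination treatments: ",
         paste(unique(treatment[unsupported]), collapse = ", "))
  ifelse(treatment %in% c("increased_precipitation", "drought"),
         abs(driver_magnitude) / 10, abs(driver_magnitude))
}

#' Driver-standardised sensitivity
#'
#' Divides a percentage change by the net driver change so experiments
#' of different intensity are comparable: percent per degree C
#' (warming), percent per g N m-2 yr-1 (nitrogen addition), and percent
#' per 10 mm of precipitation change (increased precipitation and
#' drought, using the absolute change). The sign of the percentage
#' change is preserved. Combination treatments have no sensitivity.
#'
#' @param percent percentage change(s).
#' @param treatment single-driver treatment name(s).
#' @param driver_magnitude net driver change(s): degrees C, g N m-2
#'   yr-1, or mm yr-1 (negative for drought); must be non-zero.
#' @return sensitivity in percent per driver unit.
#' @export
to_sensitivity <- function(percent, treatment, driver_magnitude) {
  percent / driver_divisor(treatment, driver_magnitude)
}

#' Collapse multiple timepoints of one study
#'
#' When a study reports several timepoints, each arm is summarised once:
#' the arithmetic mean of the timepoint means and the arithmetic mean of
#' the timepoint SDs. Averaging SDs (rather than taking the SD of the
#' means) keeps the within-plot replication scale and does not conflate
#' a temporal trend with sampling error.
#'
#' @param means numeric vector of timepoint means (non-empty).
#' @param sds numeric vector of timepoint SDs (same length, all >= 0).
#' @return named numeric vector `c(mean = ..., sd = ...)`.
#' @export
aggregate_timepoints <- function(means, sds) {
  if (length(means) == 0L) stop("no timepoints to aggregate")
  if (length(sds) != length(means)) stop("means and sds differ in length")
  if (any(!(sds >= 0))) stop("sds must be >= 0")
  c(mean = mean(means), sd = mean(sds))
}

#' Collapse duplicate record keys of a study set
#'
#' Applies [aggregate_timepoints()] to both arms of every duplicated
#' (site_id, metric, treatment, driver_window) key, so each study
#' contributes exactly one mean and SD per arm downstream. Replicate
#' counts are averaged (rounded); driver magnitude, duration and site
#' covariates are averaged.
#'
#' @param x a [study_set()].
#' @return a [study_set()] with unique record keys.
#' @export
aggregate_studyset <- function(x) {
  stopifnot(inherits(x, "study_set"))
  df <- x$records
  if (nrow(df) == 0L) return(x)
  key <- paste(df$site_id, df$metric, df$treatment, df$driver_window,
               sep = "\r")
  pieces <- lapply(split(df, factor(key, levels = unique(key))),
                   function(g) {
    if (nrow(g) == 1L) return(g)
    out <- g[1, , drop = FALSE]
    at <- aggregate_timepoints(g$mean_treat, g$sd_treat)
    ac <- aggregate_timepoints(g$mean_ctrl, g$sd_ctrl)
    out$mean_treat <- at[["mean"]]; out$sd_treat <- at[["sd"]]
    out$mean_ctrl <- ac[["mean"]]; out$sd_ctrl <- ac[["sd"]]
    out$n_treat <- round(mean(g$n_treat))
    out$n_ctrl <- round(mean(g$n_ctrl))
    out$driver_magnitude <- mean(g$driver_magnitude)
    out$duration_yr <- mean(g$duration_yr)
    out$mat_c <- mean(g$mat_c)
    out$aridity_index <- mean(g$aridity_index)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  study_set(out, provenance = x$provenance, n_dropped = x$n_dropped)
}

#' Per-record effect sizes for a study set
#'
#' Computes, for every record, the log response ratio, its sampling
#' variance and SE, the percentage change (always derived from rr so
#' the two are consistent), and — for single-driver treatments — the
#' driver-standardised sensitivity with its delta-rule variance
#' var(sens) = (100 exp(rr))^2 * vi / c^2, where c is the driver
#' divisor. Duplicate keys must have been collapsed first
#' ([aggregate_studyset()]).
#'
#' @param x a [study_set()] with unique record keys.
#' @return data.frame with one row per record: the identifying columns,
#'   `rr`, `vi`, `se`, `percent`, `sensitivity`, `sens_vi` (the last two
#'   `NA` for combination treatments), plus duration and site
#'   covariates carried through for subgrouping and meta-regression.
#' @export
compute_effect_sizes <- function(x) {
  stopifnot(inherits(x, "study_set"))
  df <- x$records
  if (nrow(df) == 0L) stop("empty study set")
  key <- paste(df$site_id, df$metric, df$treatment, df$driver_window,
               sep = "|")
  if (anyDuplicated(key))
    stop("duplicate record keys: run aggregate_studyset() first")
  rr <- compute_log_rr(df$mean_treat, df$mean_ctrl)
  vi <- compute_variance(df$mean_treat, df$sd_treat, df$n_treat,
                         df$mean_ctrl, df$sd_ctrl, df$n_ctrl)
  percent <- to_percent(rr)
  single <- df$treatment %in% SINGLE_DRIVER_TREATMENTS
  sens <- rep(NA_real_, nrow(df))
  sens_vi <- rep(NA_real_, nrow(df))
  if (any(single)) {
    div <- driver_divisor(df$treatment[single], df$driver_magnitude[single])
    sens[single] <- percent[single] / div
    sens_vi[single] <- (100 * exp(rr[single]))^2 * vi[single] / div^2
  }
  data.frame(record_key = key,
             site_id = df$site_id, metric = df$metric,
             treatment = df$treatment, driver_window = df$driver_window,
             driver_magnitude = df$driver_magnitude,
             duration_yr = df$duration_yr,
             mat_c = df$mat_c, aridity_index = df$aridity_index,
             rr = rr, vi = vi, se = sqrt(vi),
             percent = percent, sensitivity = sens, sens_vi = sens_vi,
             stringsAsFactors = FALSE)
}

#' Compile warming sensitivities across driver windows
#'
#' Warming experiments report annual and growing-season temperature
#' changes separately; when one site x metric has both, their
#' sensitivities are averaged into a single row before pooling so the
#' site is not counted twice. The variance of the averaged row is the
#' mean of the two delta-rule variances. Non-warming rows and sites
#' with a single window pass through unchanged.
#'
#' @param es effect-size table from [compute_effect_sizes()].
#' @return the table with at most one warming row per site x metric,
#'   `driver_window` set to `"compiled"` where averaging occurred.
#' @export
compile_warming_windows <- function(es) {
  w <- es$treatment == "warming"
  if (!any(w)) return(es)
  key <- paste(es$site_id, es$metric, sep = "\r")
  dup_keys <- unique(key[w][duplicated(key[w])])
  if (!length(dup_keys)) return(es)
  keep <- rep(TRUE, nrow(es))
  for (kk in dup_keys) {
    idx <- which(w & key == kk)
    first <- idx[1]
    es$sensitivity[first] <- mean(es$sensitivity[idx])
    es$sens_vi[first] <- mean(es$sens_vi[idx])
    es$rr[first] <- mean(es$rr[idx])
    es$vi[first] <- mean(es$vi[idx])
    es$se[first] <- sqrt(es$vi[first])
    es$percent[first] <- to_percent(es$rr[first])
    es$driver_window[first] <- "compiled"
    keep[idx[-1]] <- FALSE
  }
  out <- es[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
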