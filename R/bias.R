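#' Funnel-plot data for one stratum
#'
#' Returns the (effect, se) points sorted by se plus the 95%
#' pseudo-confidence contour mu +/- 1.96 se anchored at the naive
#' fixed-effect mean, ready for plotting; no inference is performed.
#'
#' @param effects log response ratios.
#' @param ses their standard errors (> 0).
#' @return list with `points` (data.frame effect, se) and `contour`
#'   (data.frame se, low, high) and `center` (fixed-effect mean).
#' @export
funnel_data <- function(effects, ses) {
  .check_meta_input(effects, ses, min_k = 1L)
  o <- order(ses)
  pts <- data.frame(effect = effects[o], se = ses[o])
  w <- 1 / ses^2
  center <- sum(w * effects) / sum(w)
  grid <- seq(0, max(ses), length.out = 50L)
  list(points = pts,
       contour = data.frame(se = grid, low = center - 1.96 * grid,
                            high = center + 1.96 * grid),
       center = center)
}

#' Egger's regression test of funnel asymmetry
#'
#' Classical form: ordinary least squares of the standardised effect
#' y/se on precision 1/se. A non-zero intercept signals small-study
#' asymmetry; the slope estimates the underlying effect. Returns the
#' intercept, its SE, z = intercept/SE, and the two-sided normal
#' p-value.
#'
#' @param effects log response ratios (k >= 3).
#' @param ses standard errors (> 0, at least two distinct values).
#' @return list with `intercept`, `se`, `z`, `p`, `slope`, `k`.
#' @export
egger_test <- function(effects, ses) {
  .check_meta_input(effects, ses, min_k = 3L)
  if (length(unique(ses)) < 2L)
    stop("Egger regression is rank-deficient: all standard errors equal")
  fit <- stats::lm(I(effects / ses) ~ I(1 / ses))
  est <- stats::coef(fit)
  se_int <- sqrt(diag(stats::vcov(fit)))[1]
  z <- est[[1]] / se_int
  list(intercept = est[[1]], se = se_int[[1]], z = z[[1]],
       p = 2 * stats::pnorm(-abs(z[[1]])), slope = est[[2]],
       k = length(effects))
}

#' PEESE bias-corrected pooled effect
#'
#' Precision-effect estimate with standard error: weighted least
#' squares of y on its sampling variance vi with weights 1/vi. The
#' intercept is the bias-corrected pooled effect — the limit of a
#' hypothetically infinitely precise study — and the slope captures
#' small-study effects.
#'
#' @param effects log response ratios (k >= 3).
#' @param variances sampling variances (> 0, at least two distinct).
#' @return list with `intercept`, `slope`, `se` (of the intercept),
#'   `z`, `p`, `corrected_percent`, `k`.
#' @export
peese_adjust <- function(effects, variances) {
  .check_meta_input(effects, variances, min_k = 3L)
  if (length(unique(variances)) < 2L)
    stop("PEESE regression is rank-deficient: all variances equal")
  fit <- stats::lm(effects ~ variances, weights = 1 / variances)
  est <- stats::coef(fit)
  se_int <- sqrt(diag(stats::vcov(fit)))[1]
  z <- est[[1]] / se_int
  list(intercept = est[[1]], slope = est[[2]], se = se_int[[1]],
       z = z[[1]], p = 2 * stats::pnorm(-abs(z[[1]])),
       corrected_percent = to_percent(est[[1]]), k = length(effects))
}

#' Publication-bias workflow for one stratum
#'
#' Runs Egger's test and the PEESE correction; PEESE replaces the naive
#' random-effects estimate as the headline value only when the Egger
#' intercept is significant at `egger_alpha`. Both estimates are always
#' reported so the conditioning is reversible downstream. Strata with
#' fewer than three studies get no diagnostics and keep the naive
#' estimate.
#'
#' @inheritParams peese_adjust
#' @param egger_alpha significance threshold that triggers the PEESE
#'   replacement (default 0.10).
#' @param method tau2 estimator for the naive pooled estimate.
#' @return an object of class `bias_diagnostics`: naive `pooled_result`,
#'   `egger`, `peese`, `applied`, `headline_rr`, `headline_percent`,
#'   `available`.
#' @export
bias_workflow <- function(effects, variances, egger_alpha = 0.10,
                          method = c("REML", "DL")) {
  method <- match.arg(method)
  naive <- pool(effects, variances, method = method)
  if (length(effects) < 3L) {
    out <- list(naive = naive, egger = NULL, peese = NULL,
                applied = FALSE, available = FALSE,
                headline_rr = naive$mu,
                headline_percent = naive$percent_mu)
    return(structure(out, class = "bias_diagnostics"))
  }
  egger <- egger_test(effects, sqrt(variances))
  peese <- peese_adjust(effects, variances)
  applied <- is.finite(egger$p) && egger$p < egger_alpha
  headline <- if (applied) peese$intercept else naive$mu
  structure(list(naive = naive, egger = egger, peese = peese,
                 applied = applied, available = TRUE,
                 headline_rr = headline,
                 headline_percent = to_percent(headline)),
            class = "bias_diagnostics")
}

#' @export
print.bias_diagnostics <- function(x, ...) {
  cat("<bias_diagnostics>")
  if (!x$available) {
    cat(" unavailable (k < 3); naive estimate retained\n")
    return(invisible(x))
  }
  cat(sprintf(" Egger intercept %.3f (p=%.3g); PEESE %.4f; applied=%s\n",
              x$egger$intercept, x$egger$p, x$peese$intercept,
              x$applied))
  cat(sprintf("  headline: %.2f%%\n", x$headline_percent))
  invisible(x)
}
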