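#' Mixed-effects meta-regression on one moderator
#'
#' Fits y_i ~ Normal(beta0 + beta1 g(x_i), vi_i + tau2) with g the
#' identity or the natural log, tau2 by REML (reporting default) or ML,
#' Wald z tests for the slope, the omnibus moderator statistic
#' QM = z1^2, and the AIC of a maximum-likelihood refit (ML AICs are
#' the ones comparable across fixed-effect structures). With `x = NULL`
#' the model reduces exactly to intercept-only pooling.
#'
#' @param y effect sizes or sensitivities (k >= 3 with a moderator).
#' @param v their variances (> 0).
#' @param x moderator values, or `NULL` for intercept-only.
#' @param transform `"linear"` or `"log"` (natural log; requires x > 0).
#' @param method tau2 estimator for the reported coefficients.
#' @param tau2 optional fixed residual tau2 (skips estimation; the ML
#'   refit for the AIC still estimates its own tau2).
#' @param moderator_name label stored on the result.
#' @return object of class `meta_reg_result`: `beta0`, `beta1`, `se0`,
#'   `se1`, `z1`, `p1`, `tau2_resid`, `QM`, `aic`, `k`, `transform`,
#'   `moderator_name`, `method`.
#' @export
fit_meta_regression <- function(y, v, x = NULL,
                                transform = c("linear", "log"),
                                method = c("REML", "ML"),
                                tau2 = NULL,
                                moderator_name = "moderator") {
  transform <- match.arg(transform)
  method <- match.arg(method)
  has_mod <- !is.null(x)
  .check_meta_input(y, v, min_k = if (has_mod) 3L else 2L)
  if (has_mod) {
    if (length(x) != length(y)) stop("moderator length mismatch")
    if (any(!is.finite(x))) stop("moderator values must be finite")
    if (transform == "log") {
      if (any(!(x > 0)))
        stop("log transform requires strictly positive moderator values")
      x <- log(x)
    }
    if (length(unique(x)) < 2L)
      stop("constant moderator: meta-regression is rank-deficient")
    X <- cbind(1, x)
  } else {
    X <- matrix(1, length(y), 1L)
  }
  if (is.null(tau2)) tau2 <- .fit_tau2(y, v, X, method = method)
  w <- 1 / (v + tau2)
  xtwx <- crossprod(X, w * X)
  beta <- solve(xtwx, crossprod(X, w * y))
  vc <- solve(xtwx)
  se <- sqrt(diag(vc))
  # ML refit for a likelihood comparable across fixed-effect structures
  tau2_ml <- if (method == "ML") tau2 else .fit_tau2(y, v, X, method = "ML")
  wm <- 1 / (v + tau2_ml)
  beta_ml <- solve(crossprod(X, wm * X), crossprod(X, wm * y))
  r_ml <- y - X %*% beta_ml
  ll_ml <- -0.5 * (length(y) * log(2 * pi) + sum(log(v + tau2_ml)) +
                     sum(wm * r_ml^2))
  aic <- -2 * ll_ml + 2 * (ncol(X) + 1L)
  if (has_mod) {
    z1 <- beta[2] / se[2]
    res <- list(moderator_name = moderator_name, transform = transform,
                beta0 = beta[[1]], beta1 = beta[[2]],
                se0 = se[[1]], se1 = se[[2]],
                z1 = z1[[1]], p1 = 2 * stats::pnorm(-abs(z1[[1]])),
                QM = z1[[1]]^2, tau2_resid = tau2, aic = aic,
                k = length(y), method = method)
  } else {
    res <- list(moderator_name = "(intercept only)", transform = "linear",
                beta0 = beta[[1]], beta1 = NA_real_,
                se0 = se[[1]], se1 = NA_real_,
                z1 = NA_real_, p1 = NA_real_, QM = NA_real_,
                tau2_resid = tau2, aic = aic, k = length(y),
                method = method)
  }
  structure(res, class = "meta_reg_result")
}

#' @export
print.meta_reg_result <- function(x, ...) {
  cat(sprintf("<meta_reg_result> %s (%s), k=%d [%s]\n", x$moderator_name,
              x$transform, x$k, x$method))
  cat(sprintf("  beta0=%.4f (SE %.4f)  beta1=%.4f (SE %.4f)\n",
              x$beta0, x$se0, x$beta1, x$se1))
  cat(sprintf("  z1=%.3f p1=%.4g  tau2_resid=%.4f  AIC=%.2f\n",
              x$z1, x$p1, x$tau2_resid, x$aic))
  invisible(x)
}

#' Select the best moderator by AIC
#'
#' Fits each candidate moderator by maximum likelihood (REML AICs are
#' not comparable across fixed-effect structures) and returns the
#' lowest-AIC fit plus the full ranking; ties are broken by candidate
#' order. Candidates that fail to fit are recorded and skipped.
#'
#' @inheritParams fit_meta_regression
#' @param candidates named list; each element is a list with `x`
#'   (moderator values) and `transform` (`"linear"` or `"log"`).
#' @return list with `best` (a `meta_reg_result` refitted with REML for
#'   reporting), `best_name`, and `ranking` (data.frame of name,
#'   transform, aic, beta1, p1, error).
#' @export
select_moderator <- function(y, v, candidates) {
  if (length(candidates) < 1L) stop("no candidate moderators")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be named")
  rows <- vector("list", length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    nm <- names(candidates)[i]
    cand <- candidates[[i]]
    fit <- tryCatch(
      fit_meta_regression(y, v, cand$x, transform = cand$transform,
                          method = "ML", moderator_name = nm),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(name = nm, transform = cand$transform,
                              aic = NA_real_, beta1 = NA_real_,
                              p1 = NA_real_,
                              error = conditionMessage(fit),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- fit
      rows[[i]] <- data.frame(name = nm, transform = cand$transform,
                              aic = fit$aic, beta1 = fit$beta1,
                              p1 = fit$p1, error = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  ranking <- do.call(rbind, rows)
  ok <- which(!is.na(ranking$aic))
  if (!length(ok))
    stop("all candidate moderators failed to fit: ",
         paste(sprintf("%s: %s", ranking$name, ranking$error),
               collapse = "; "))
  best_i <- ok[which.min(ranking$aic[ok])]   # which.min keeps first tie
  best_name <- ranking$name[best_i]
  cand <- candidates[[best_i]]
  best <- fit_meta_regression(y, v, cand$x, transform = cand$transform,
                              method = "REML", moderator_name = best_name)
  best$aic <- ranking$aic[best_i]  # report the comparable ML AIC
  list(best = best, best_name = best_name,
       ranking = ranking[order(ranking$aic), , drop = FALSE])
}

# Candidate moderator sets mirroring the reporting convention:
# warming sensitivities are screened against site mean annual
# temperature and the aridity index (linear and log); the other
# single-driver treatments use the aridity index only.
.moderator_candidates <- function(treatment, mat_c, aridity_index) {
  if (treatment == "warming") {
    list(MAT_linear = list(x = mat_c, transform = "linear"),
         AI_linear = list(x = aridity_index, transform = "linear"),
         AI_log = list(x = aridity_index, transform = "log"))
  } else {
    list(AI_linear = list(x = aridity_index, transform = "linear"),
         AI_log = list(x = aridity_index, transform = "log"))
  }
}

#' Sensitivity-gradient report across strata
#'
#' For every metric x single-driver-treatment stratum with at least
#' three records, regresses the driver-standardised sensitivities
#' (delta-rule variances) on site climate: warming strata screen
#' {MAT linear, AI linear, AI log} by ML AIC; the other treatments fit
#' the aridity index only (linear vs natural log, lower AIC kept).
#' Slopes are labelled `significant` at p < `sig_level`, `marginal` at
#' p < `marginal_level`, `ns` otherwise; strata with k < 3 are reported
#' as `not_estimable`, never dropped.
#'
#' @param es effect-size table from [compute_effect_sizes()] (after
#'   [compile_warming_windows()]).
#' @param sig_level,marginal_level significance and marginal-significance
#'   thresholds (defaults 0.05 and 0.10).
#' @return data.frame with one row per metric x treatment: chosen
#'   moderator, transform, slope, SE, z, p, AIC, label, k.
#' @export
sensitivity_gradient_report <- function(es, sig_level = 0.05,
                                        marginal_level = 0.10) {
  es <- es[es$treatment %in% SINGLE_DRIVER_TREATMENTS &
             is.finite(es$sensitivity) & is.finite(es$sens_vi) &
             es$sens_vi > 0, , drop = FALSE]
  combos <- unique(es[, c("metric", "treatment")])
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    g <- es[es$metric == combos$metric[i] &
              es$treatment == combos$treatment[i], , drop = FALSE]
    base <- data.frame(metric = combos$metric[i],
                       treatment = combos$treatment[i],
                       k = nrow(g), moderator = NA_character_,
                       transform = NA_character_, slope = NA_real_,
                       se = NA_real_, z = NA_real_, p = NA_real_,
                       aic = NA_real_, label = "not_estimable",
                       stringsAsFactors = FALSE)
    if (nrow(g) < 3L) { rows[[i]] <- base; next }
    cands <- .moderator_candidates(combos$treatment[i], g$mat_c,
                                   g$aridity_index)
    sel <- tryCatch(select_moderator(g$sensitivity, g$sens_vi, cands),
                    error = function(e) NULL)
    if (is.null(sel)) { rows[[i]] <- base; next }
    fit <- sel$best
    base$moderator <- fit$moderator_name
    base$transform <- fit$transform
    base$slope <- fit$beta1
    base$se <- fit$se1
    base$z <- fit$z1
    base$p <- fit$p1
    base$aic <- fit$aic
    base$label <- if (fit$p1 < sig_level) "significant"
                  else if (fit$p1 < marginal_level) "marginal"
                  else "ns"
    rows[[i]] <- base
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
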