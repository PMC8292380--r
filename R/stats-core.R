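#' Standardize a numeric vector to z-scores
#'
#' Centers and scales to mean 0 and standard deviation 1 (denominator n - 1).
#' Exposure variables in all association models are used on this per-1-SD
#' scale, so slopes are directly comparable across behavioral metrics.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector of z-scores.
#' @export
standardize <- function(x) {
  .assert(is.numeric(x), "`x` must be numeric")
  ok <- is.finite(x)
  .assert(length(unique(x[ok])) >= 2L,
          "cannot standardize: fewer than 2 distinct values")
  (x - mean(x[ok])) / stats::sd(x[ok])
}

#' Fit a linear mixed model with a single random intercept
#'
#' Restricted maximum likelihood (REML) fit of
#' \eqn{y = X\beta + Zb + e}, \eqn{b \sim N(0, \sigma_b^2 I)}, with one
#' grouping factor (e.g. hyena ID for repeated fecal glucocorticoid
#' metabolite (fGCM) measurements, or maternal ID for sibling-clustered
#' global methylation).  The variance ratio is profiled in one dimension,
#' which keeps a fit cheap enough that percentile-bootstrap confidence
#' intervals with thousands of refits are practical.
#'
#' Wald standard errors are reported for screening; confidence intervals for
#' reported estimates come from [percentile_bootstrap_ci()].  Rows with
#' missing values in any model variable are dropped (complete-case) and the
#' number of exclusions is recorded in the fit.
#'
#' @param formula fixed-effects formula, e.g. `log_fgcm ~ exposure + sex`.
#' @param data data frame.
#' @param group name of the grouping (random-intercept) column.
#' @return an object of class `socmethyl_lmm`: named fixed-effect estimates
#'   (`beta`), Wald `se`, Wald `p`, variance components `sigma2_id` and
#'   `sigma2_res`, per-cluster `blups`, `n_obs`, `n_groups`, `n_excluded`,
#'   and the REML log likelihood.
#' @export
fit_lmm <- function(formula, data, group) {
  des <- .lmm_design(formula, data, group)
  gs <- .lmm_group_stats(des$X, des$y, des$g)
  fit <- .lmm_fit_agg(.lmm_aggregate(gs))
  .assert(!is.null(fit), "mixed-model fit failed (singular aggregated design)")
  if (fit$lambda <= 0) {
    warning("random-intercept variance estimated as 0 (boundary fit)",
            call. = FALSE)
  }
  zval <- ifelse(fit$se > 0, fit$beta / fit$se, Inf * sign(fit$beta))
  out <- list(
    beta = stats::setNames(fit$beta, gs$terms),
    se = stats::setNames(fit$se, gs$terms),
    p = stats::setNames(2 * stats::pnorm(-abs(zval)), gs$terms),
    vcov = fit$cov_beta,
    sigma2_id = fit$sigma_b2,
    sigma2_res = fit$sigma_e2,
    blups = .lmm_blups(fit, gs),
    group = group,
    formula = formula,
    n_obs = fit$N,
    n_groups = gs$G,
    n_excluded = des$n_excluded,
    logLik_reml = fit$logLik_reml
  )
  class(out) <- "socmethyl_lmm"
  out
}

#' @export
print.socmethyl_lmm <- function(x, ...) {
  cat("Linear mixed model (REML), random intercept for", x$group, "\n")
  cat(sprintf("  %d observations in %d groups (%d rows excluded)\n",
              x$n_obs, x$n_groups, x$n_excluded))
  tab <- data.frame(beta = x$beta, se = x$se, p = x$p)
  print(round(tab, 4))
  cat(sprintf("  sigma2_id = %.4g, sigma2_res = %.4g, logLik(REML) = %.2f\n",
              x$sigma2_id, x$sigma2_res, x$logLik_reml))
  invisible(x)
}

#' Percentile-bootstrap confidence intervals for mixed-model fixed effects
#'
#' Resamples clusters (the random-intercept grouping unit) with replacement,
#' refits the REML model on each resample, and reports empirical percentile
#' intervals (default 2.5/97.5 at `level = 0.95`, `n_boot = 2000`).  Cluster
#' resampling preserves the within-group dependence that the random intercept
#' models.  Resamples whose design collapses (e.g. a covariate becomes
#' constant) are skipped and counted; more than `max_fail` failures is an
#' error.
#'
#' @param formula,data,group as in [fit_lmm()].
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed optional integer seed for reproducible resampling.
#' @param max_fail maximum tolerated fraction of failed refits.
#' @return data frame with one row per fixed-effect term: `term`, `estimate`
#'   (full-data REML), `lower`, `upper`, `n_boot_ok`, `n_boot_failed`,
#'   `level`.
#' @export
percentile_bootstrap_ci <- function(formula, data, group, n_boot = 2000,
                                    level = 0.95, seed = NULL, max_fail = 0.1) {
  .assert(n_boot >= 2, "n_boot must be >= 2")
  des <- .lmm_design(formula, data, group)
  gs <- .lmm_group_stats(des$X, des$y, des$g)
  full <- .lmm_fit_agg(.lmm_aggregate(gs))
  .assert(!is.null(full), "full-data model must fit before bootstrapping")
  .with_seed(seed, {
    B <- matrix(NA_real_, n_boot, gs$p)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(gs$G, gs$G, replace = TRUE)
      ft <- .lmm_fit_agg(.lmm_aggregate(gs, idx))
      if (!is.null(ft)) B[b, ] <- ft$beta
    }
    n_fail <- sum(!stats::complete.cases(B))
    if (n_fail / n_boot > max_fail) {
      stop(sprintf(paste0("bootstrap failure rate %.1f%% exceeds %.0f%% ",
                          "(%d of %d refits failed; %d clusters, %d terms)"),
                   100 * n_fail / n_boot, 100 * max_fail, n_fail, n_boot,
                   gs$G, gs$p), call. = FALSE)
    }
    alpha <- (1 - level) / 2
    qs <- apply(B, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE)
    data.frame(term = gs$terms,
               estimate = full$beta,
               lower = qs[1L, ],
               upper = qs[2L, ],
               n_boot_ok = n_boot - n_fail,
               n_boot_failed = n_fail,
               level = level,
               row.names = NULL)
  })
}

#' Consolidate repeated log-fGCM measurements into per-individual BLUPs
#'
#' Fits an intercept-only mixed model with a random intercept per individual
#' to repeated natural-log fGCM measurements and returns the best linear
#' unbiased predictors (BLUPs): the shrunken deviation of each individual's
#' mean from the population mean.  In a balanced design the BLUP equals the
#' raw deviation times the shrinkage factor
#' \eqn{n_i\sigma_b^2 / (n_i\sigma_b^2 + \sigma_e^2)}, so individuals with
#' more repeats are shrunk less.  These BLUPs are the per-individual stress
#' phenotype used as the explanatory variable in the EWAS.
#'
#' @param samples data frame of repeated measurements.
#' @param id_col name of the individual-ID column.
#' @param value_col name of the (log-scale) outcome column.
#' @return data frame with `id`, `blup`, `n_obs` per individual.
#' @export
extract_blups <- function(samples, id_col = "id", value_col = "log_fgcm") {
  .assert(all(c(id_col, value_col) %in% names(samples)),
          "samples must contain the id and value columns")
  ids <- samples[[id_col]]
  .assert(length(unique(ids)) >= 2L,
          "need >= 2 individuals to separate between- from within-variance")
  dat <- data.frame(.y = samples[[value_col]], .id = ids)
  des <- .lmm_design(.y ~ 1, dat, ".id")
  gs <- .lmm_group_stats(des$X, des$y, des$g)
  fit <- .lmm_fit_agg(.lmm_aggregate(gs))
  .assert(!is.null(fit), "BLUP model failed to fit")
  blup <- .lmm_blups(fit, gs)
  data.frame(id = names(blup), blup = as.numeric(blup),
             n_obs = gs$n_g, row.names = NULL)
}

#' Convert a natural-log-scale slope to a percent change
#'
#' A slope \eqn{\beta} from a model of log-transformed concentrations
#' corresponds to a multiplicative effect; `100 * (exp(beta) - 1)` is the
#' percent change per unit of the exposure, rounded to the nearest integer
#' for reporting (`round = FALSE` returns the exact value).
#'
#' @param beta_log slope(s) on the natural-log scale.
#' @param round round to the nearest integer percent?
#' @return percent change per exposure unit.
#' @export
percent_change <- function(beta_log, round = TRUE) {
  .assert(is.numeric(beta_log) && all(is.finite(beta_log)),
          "beta_log must be finite numeric")
  pc <- 100 * (exp(beta_log) - 1)
  if (round) base::round(pc) else pc
}

#' Flag effect modification from an interaction term
#'
#' Wald test of a single coefficient against a relaxed threshold
#' (`alpha = 0.10` by default, the conventional screen for interaction
#' terms).  The flag is `TRUE` only for strict `p < alpha`.
#'
#' @param fit a [fit_lmm()] object.
#' @param term name of the interaction coefficient in the fit.
#' @param alpha significance threshold for the interaction screen.
#' @return list with `term`, `estimate`, `se`, `p`, `flag`.
#' @export
test_interaction <- function(fit, term, alpha = 0.10) {
  .assert(inherits(fit, "socmethyl_lmm"), "fit must come from fit_lmm()")
  .assert(term %in% names(fit$beta),
          paste0("term not in fit: ", term))
  p <- unname(fit$p[term])
  list(term = term, estimate = unname(fit$beta[term]),
       se = unname(fit$se[term]), p = p, flag = p < alpha)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure; rejections are sites whose BH-adjusted p-value is
#' at most `q`.  Adjusted p-values are monotone non-decreasing in raw-p rank.
#'
#' @param pvalues raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return data frame with `p`, `q_bh` (adjusted p) and `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  .assert(is.numeric(pvalues) && all(is.finite(pvalues)) &&
            all(pvalues >= 0 & pvalues <= 1),
          "p-values must be finite and in [0, 1]")
  .assert(q > 0 && q < 1, "q must be in (0, 1)")
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q_bh = adj, reject = adj <= q)
}
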