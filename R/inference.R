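# Linking analyses: three-step mediation with an attenuation criterion, and
# the meet-in-the-middle screen that asks whether a stress-associated CpG
# site is also associated with early maternal care in the opposite
# direction.

#' Three-step mediation analysis with an attenuation criterion
#'
#' Classic three-step procedure on the complete-case subsample: Step 1
#' regresses the outcome (repeated log fGCM, individual random intercept)
#' on the exposure; Step 2 regresses the mediator (e.g. global %CCGG,
#' maternal random intercept) on the exposure (2a) and the outcome on the
#' mediator (2b).  Step 3 runs only when all three associations pass (their
#' percentile-bootstrap CIs exclude zero): the Step-1 model is refit with
#' the mediator added, and mediation is flagged when the exposure
#' coefficient is attenuated by more than `attenuation_cut` percent
#' (`100 * (|b_unadj| - |b_adj|) / |b_unadj|`).  The exposure is
#' standardized internally, so the attenuation is scale-invariant.
#'
#' @param samples repeated-outcome data frame (one row per measurement) with
#'   the outcome, the individual id, and any covariates.
#' @param individuals per-individual data frame with the exposure, the
#'   mediator and the mediator-model grouping column (e.g. `mother_id`).
#' @param exposure,mediator column names in `individuals`.
#' @param outcome outcome column name in `samples`.
#' @param id_col individual-id column (in both data frames).
#' @param mediator_group grouping column for the mediator model.
#' @param covariates_y,covariates_m optional covariate names for the
#'   outcome- and mediator-side models.
#' @param n_boot,level,seed bootstrap CI settings.
#' @param attenuation_cut percent attenuation required to flag mediation.
#' @return object of class `mediation_result`: per-step estimates and CIs
#'   with pass flags, `step3_run`, `beta_adjusted`, `attenuation_percent`,
#'   `mediation_flag`.
#' @export
mediation_analysis <- function(samples, individuals, exposure,
                               mediator = "ccgg", outcome = "log_fgcm",
                               id_col = "id", mediator_group = "mother_id",
                               covariates_y = character(),
                               covariates_m = character(),
                               n_boot = 1000, level = 0.95, seed = 1L,
                               attenuation_cut = 10) {
  .assert(all(c(exposure, mediator, mediator_group) %in% names(individuals)),
          "individuals lacks exposure/mediator/grouping columns")
  .assert(all(c(outcome, id_col) %in% names(samples)),
          "samples lacks outcome/id columns")
  med_vals <- individuals[[mediator]]
  .assert(stats::sd(med_vals, na.rm = TRUE) > 0, "mediator is constant")

  ind <- individuals[stats::complete.cases(
    individuals[, c(id_col, exposure, mediator, mediator_group, covariates_m),
                drop = FALSE]), , drop = FALSE]
  ind$.x <- standardize(ind[[exposure]])
  ind$.m <- ind[[mediator]]
  sam <- merge(samples, ind[, c(id_col, ".x", ".m")], by = id_col)
  sam <- sam[stats::complete.cases(
    sam[, c(outcome, ".x", ".m", covariates_y), drop = FALSE]), , drop = FALSE]

  fy <- function(rhs) stats::reformulate(c(rhs, covariates_y), response = outcome)
  fm <- stats::reformulate(c(".x", covariates_m), response = ".m")
  seeds <- .sub_seeds(seed, c("s1", "s2a", "s2b", "s3"))

  step_ci <- function(formula, data, group, term, sd) {
    ci <- percentile_bootstrap_ci(formula, data, group, n_boot = n_boot,
                                  level = level, seed = sd)
    row <- ci[ci$term == term, ]
    list(beta = row$estimate, lower = row$lower, upper = row$upper,
         passed = row$lower > 0 || row$upper < 0)
  }

  s1 <- step_ci(fy(".x"), sam, id_col, ".x", seeds["s1"])
  s2a <- step_ci(fm, ind, mediator_group, ".x", seeds["s2a"])
  s2b <- step_ci(fy(".m"), sam, id_col, ".m", seeds["s2b"])

  step3_run <- s1$passed && s2a$passed && s2b$passed
  beta_adjusted <- NA_real_
  attenuation <- NA_real_
  flag <- FALSE
  if (step3_run) {
    f3 <- fit_lmm(fy(c(".x", ".m")), sam, id_col)
    beta_adjusted <- unname(f3$beta[".x"])
    attenuation <- 100 * (abs(s1$beta) - abs(beta_adjusted)) / abs(s1$beta)
    flag <- attenuation > attenuation_cut
  }
  out <- list(exposure = exposure, mediator = mediator,
              step1 = s1, step2a = s2a, step2b = s2b,
              step3_run = step3_run, beta_unadjusted = s1$beta,
              beta_adjusted = beta_adjusted,
              attenuation_percent = attenuation, mediation_flag = flag,
              n_individuals = nrow(ind), n_samples = nrow(sam),
              n_boot = n_boot, level = level)
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(s) sprintf("%.3f [%.3f, %.3f] %s", s$beta, s$lower, s$upper,
                             if (s$passed) "PASS" else "fail")
  cat("Three-step mediation:", x$exposure, "->", x$mediator, "-> outcome\n")
  cat("  Step 1  (X -> Y):", fmt(x$step1), "\n")
  cat("  Step 2a (X -> M):", fmt(x$step2a), "\n")
  cat("  Step 2b (M -> Y):", fmt(x$step2b), "\n")
  if (x$step3_run) {
    cat(sprintf("  Step 3: adjusted beta %.3f, attenuation %.1f%% -> %s\n",
                x$beta_adjusted, x$attenuation_percent,
                if (x$mediation_flag) "mediation flagged" else "no mediation"))
  } else {
    cat("  Step 3 not run (a prior step failed)\n")
  }
  invisible(x)
}

#' Detect overdispersion in a Poisson fit
#'
#' Pearson chi-square over residual degrees of freedom, compared against the
#' upper 5% tail of the chi-square distribution; the flag is `TRUE` only on
#' strict exceedance of the critical value.
#'
#' @param fit a fitted Poisson [stats::glm()] (alternatively supply
#'   `pearson` and `df` directly).
#' @param pearson,df Pearson statistic and residual degrees of freedom.
#' @param alpha tail probability of the test.
#' @return logical flag.
#' @export
detect_overdispersion <- function(fit = NULL, pearson = NULL, df = NULL,
                                  alpha = 0.05) {
  if (!is.null(fit)) {
    pearson <- sum(stats::residuals(fit, type = "pearson")^2)
    df <- stats::df.residual(fit)
  }
  .assert(!is.null(pearson) && !is.null(df), "need a fit or pearson + df")
  .assert(df > 0, "residual degrees of freedom must be > 0")
  pearson > stats::qchisq(1 - alpha, df)
}

#' Count regression of methylated reads with a total-reads offset
#'
#' Poisson log-linear model in which methylated read counts are the outcome
#' and `log(total reads)` enters as an offset (so the modeled rate is the
#' methylation proportion, invariant to sequencing depth); age in months is
#' a precision covariate.  If overdispersion is detected on the Poisson fit
#' (Pearson chi-square test, [detect_overdispersion()]), a negative binomial
#' model is fit instead.
#'
#' @param methylated,totals count vectors (all totals > 0).
#' @param exposure explanatory variable (care metric or maternal rank).
#' @param age optional age covariate.
#' @param family `"auto"` (default: Poisson, upgraded to negative binomial
#'   when overdispersion is detected) or a fixed family.
#' @return list with exposure `beta`, `se`, `p`, the chosen `family`
#'   (`"poisson"` or `"negative_binomial"`), `overdispersed`, `converged`,
#'   and the underlying `fit`.
#' @export
fit_count_model <- function(methylated, totals, exposure, age = NULL,
                            family = c("auto", "poisson",
                                       "negative_binomial")) {
  family <- match.arg(family)
  n <- length(methylated)
  .assert(length(totals) == n && length(exposure) == n, "length mismatch")
  .assert(all(totals > 0), "all totals must be > 0 (offset is log(total))")
  dat <- data.frame(y = methylated, off = log(totals), x = exposure)
  rhs <- "x"
  if (!is.null(age)) { dat$age <- age; rhs <- c(rhs, "age") }
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + "),
                                 "+ offset(off)"))
  pf <- tryCatch(stats::glm(fml, family = stats::poisson(), data = dat),
                 error = function(e) NULL)
  if (is.null(pf)) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                family = "poisson", overdispersed = NA, converged = FALSE,
                fit = NULL))
  }
  od <- detect_overdispersion(pf)
  fit <- pf
  if (family == "auto") family <- if (od) "negative_binomial" else "poisson"
  if (family == "negative_binomial") {
    nb <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = dat)),
                   error = function(e) NULL)
    if (!is.null(nb)) fit <- nb else family <- "poisson"
  }
  sm <- summary(fit)$coefficients
  list(beta = sm["x", 1L], se = sm["x", 2L], p = sm["x", 4L],
       family = family, overdispersed = od,
       converged = isTRUE(fit$converged %||% TRUE), fit = fit)
}

#' Meet-in-the-middle hit decision
#'
#' A site x care-variable pair is a hit when the care-model p-value is below
#' `p_cut` and the care and fGCM coefficients point in opposite directions
#' (a protective exposure should relate to methylation oppositely from the
#' stress phenotype).
#'
#' @param beta_care,p_care care-model coefficient and p-value.
#' @param beta_fgcm fGCM-model coefficient at the same site.
#' @param p_cut nominal screening threshold.
#' @return data frame `opposite_sign`, `is_hit`; vectorized.
#' @export
mitm_decision <- function(beta_care, p_care, beta_fgcm, p_cut = 0.1) {
  opp <- sign(beta_care) != sign(beta_fgcm) & sign(beta_care) != 0 &
    sign(beta_fgcm) != 0
  data.frame(opposite_sign = opp, is_hit = p_care < p_cut & opp)
}

#' Meet-in-the-middle screen over stress-associated DMSs
#'
#' For every differentially methylated site and every early-social variable
#' (care metrics and, when supplied, maternal rank), fits the offset count
#' model ([fit_count_model()]) and flags hits by [mitm_decision()]: nominal
#' `p < p_cut` with the care and fGCM coefficients in opposite directions.
#'
#' @param dms_table data frame with `site_id` and `beta_fgcm` (the
#'   corrected EWAS coefficient whose sign is screened against).
#' @param counts a [meth_counts()] object containing the DMS sites.
#' @param care per-individual data frame with `id` and the columns named in
#'   `care_vars`.
#' @param care_vars care/rank variable names to screen.
#' @param age optional named age vector (months).
#' @param p_cut nominal screening threshold.
#' @return data frame with one row per site x variable: `site_id`,
#'   `variable`, `beta_care`, `se_care`, `p_care`, `family`, `beta_fgcm`,
#'   `opposite_sign`, `is_hit`, `matches_prediction` ("Yes"/"No" for
#'   nominally significant pairs, `NA` otherwise).
#' @export
mitm_screen <- function(dms_table, counts, care,
                        care_vars = c("prop_close", "prop_nursing",
                                      "prop_grooming", "maternal_rank"),
                        age = NULL, p_cut = 0.1) {
  if (is.null(dms_table) || nrow(dms_table) == 0L) {
    return(data.frame(site_id = character(), variable = character(),
                      beta_care = numeric(), se_care = numeric(),
                      p_care = numeric(), family = character(),
                      beta_fgcm = numeric(), opposite_sign = logical(),
                      is_hit = logical(), matches_prediction = character()))
  }
  .assert(all(c("site_id", "beta_fgcm") %in% names(dms_table)),
          "dms_table needs site_id and beta_fgcm")
  .assert(inherits(counts, "meth_counts"), "need a meth_counts object")
  care_vars <- intersect(care_vars, names(care))
  .assert(length(care_vars) > 0, "no care variables found in `care`")
  rows <- list()
  for (i in seq_len(nrow(dms_table))) {
    sid <- dms_table$site_id[i]
    si <- match(sid, counts$sites$site_id)
    .assert(!is.na(si), paste0("site not in counts: ", sid))
    for (v in care_vars) {
      keep <- !is.na(care[[v]]) & counts$total[si, care$id] > 0
      ids <- care$id[keep]
      a <- if (!is.null(age)) as.numeric(age[ids]) else NULL
      cm <- fit_count_model(counts$meth[si, ids], counts$total[si, ids],
                            care[[v]][keep], age = a)
      dec <- mitm_decision(cm$beta, cm$p, dms_table$beta_fgcm[i], p_cut)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sid, variable = v, beta_care = cm$beta, se_care = cm$se,
        p_care = cm$p, family = cm$family,
        beta_fgcm = dms_table$beta_fgcm[i],
        opposite_sign = dec$opposite_sign, is_hit = dec$is_hit,
        matches_prediction = if (is.finite(cm$p) && cm$p < p_cut) {
          if (dec$opposite_sign) "Yes" else "No"
        } else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
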