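# Synthetic study generator.  Emulates the statistical structure of a
# longitudinal field study of a social carnivore: a maternal pedigree with
# kinship, focal-animal-survey maternal care, co-occurrence sessions spanning
# matched communal-den (CD) and den-independent (DI) developmental windows,
# repeated fecal glucocorticoid metabolite (fGCM) measurements with
# individual random intercepts, sibling-clustered global (%CCGG) DNA
# methylation, and per-CpG methylated/total read counts with
# kinship-correlated logit-scale random effects.  Every planted parameter is
# recorded in a ground-truth ledger so downstream estimators can be tested
# for recovery.

#' Planted ("true") effect sizes for the synthetic study
#'
#' All slopes are on the per-1-SD exposure scale used by the analysis
#' models.  Defaults are the study conditions the generator emulates:
#' a -0.12 log-fGCM slope per SD of den-independent social connectedness
#' (about an 11% decrease in concentration), no maternal-care effect on
#' fGCMs, a +1.36 %CCGG effect per SD of close maternal proximity, and a
#' modest kinship variance on the methylation logit scale.
#'
#' @param beta_care_on_logfgcm log-scale fGCM slope per 1 SD of maternal
#'   close-proximity care.
#' @param beta_network_on_logfgcm log-scale fGCM slope per 1 SD of DI-period
#'   network degree.
#' @param beta_care_on_ccgg %CCGG change per 1 SD of close-proximity care.
#' @param sigma_id SD of the individual random intercept for log fGCM.
#' @param sigma_mom SD of the maternal random intercept for %CCGG.
#' @param tau_kinship logit-scale kinship variance of per-site methylation
#'   random effects.
#' @param frac_true_dms fraction of CpG sites with a nonzero planted effect
#'   of the stress phenotype on methylation.
#' @param beta_site logit-scale effect magnitude at true sites (sign is
#'   randomized per site).
#' @param z_bias,z_inflation planted additive bias and multiplicative
#'   inflation of EWAS test statistics (used by
#'   [simulate_null_zscores()] to exercise the empirical-null correction).
#' @param sigma_res_fgcm residual SD of log fGCM within individual.
#' @param sigma_res_ccgg residual SD of %CCGG.
#' @param covariate_effects named list of generative covariate coefficients;
#'   defaults follow the qualitative directions expected in the field (e.g.
#'   human disturbance lowers maternal care and raises stress hormones).
#' @return a `true_effects` list.
#' @export
true_effects <- function(beta_care_on_logfgcm = 0,
                         beta_network_on_logfgcm = -0.12,
                         beta_care_on_ccgg = 1.36,
                         sigma_id = 0.45,
                         sigma_mom = 1.5,
                         tau_kinship = 0.3,
                         frac_true_dms = 0.025,
                         beta_site = 1.0,
                         z_bias = 0,
                         z_inflation = 1,
                         sigma_res_fgcm = 0.55,
                         sigma_res_ccgg = 2.5,
                         covariate_effects = list()) {
  .assert(sigma_id >= 0 && sigma_mom >= 0 && tau_kinship >= 0 &&
            sigma_res_fgcm >= 0 && sigma_res_ccgg >= 0,
          "variance components must be >= 0")
  .assert(frac_true_dms >= 0 && frac_true_dms <= 1,
          "frac_true_dms must be in [0, 1]")
  .assert(z_inflation > 0, "z_inflation must be > 0")
  defaults <- list(
    fgcm_intercept = log(50),     # ~50 ng/g baseline
    fgcm_sex_male = 0.10,
    fgcm_disturbance = 0.08,      # per disturbance level (low->high raises stress)
    fgcm_age = -0.002,            # per month
    fgcm_pregnant = 0.20,
    fgcm_lactating = 0.10,
    fgcm_pm = 0.05,
    ccgg_intercept = 75,
    ccgg_age = -0.02,             # per month
    ccgg_sex_male = -0.20,
    ccgg_disturbance = -0.30,     # disturbance lowers global methylation
    ccgg_prey_high = 0.30,
    ccgg_rank = 0.20,
    care_disturbance = -0.25,     # disturbance lowers care (logit scale)
    meth_age = 0.005              # logit per month
  )
  covariate_effects <- utils::modifyList(defaults, covariate_effects)
  out <- list(beta_care_on_logfgcm = beta_care_on_logfgcm,
              beta_network_on_logfgcm = beta_network_on_logfgcm,
              beta_care_on_ccgg = beta_care_on_ccgg,
              sigma_id = sigma_id, sigma_mom = sigma_mom,
              tau_kinship = tau_kinship, frac_true_dms = frac_true_dms,
              beta_site = beta_site, z_bias = z_bias,
              z_inflation = z_inflation,
              sigma_res_fgcm = sigma_res_fgcm,
              sigma_res_ccgg = sigma_res_ccgg,
              covariate_effects = covariate_effects)
  class(out) <- "true_effects"
  out
}

#' Simulation configuration
#'
#' @param n_mothers number of founder mothers.
#' @param offspring_per_mother offspring per mother.
#' @param n_sessions number of co-occurrence observation sessions.
#' @param session_length_min length of each focal session in minutes.
#' @param n_cpg number of CpG sites in the methylation panel.
#' @param mean_coverage mean per-cell sequencing coverage (reads; >= 10).
#' @param n_meth_individuals size of the genome-wide methylation subsample
#'   (females, mirroring a sequencing budget constrained to one sex).
#' @param care_rates list of per-minute care probabilities: `p_close`
#'   (baseline probability of close proximity), `sd_logit` (between-mother
#'   SD on the logit scale), `p_nurse` and `p_groom` (conditional on close
#'   proximity).
#' @param seed integer seed; all randomness flows from it through named
#'   per-component sub-streams, so a fixed config is byte-identical across
#'   runs.
#' @param effects a [true_effects()] object.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mothers = 30, offspring_per_mother = 2,
                       n_sessions = 300, session_length_min = 30,
                       n_cpg = 2000, mean_coverage = 30,
                       n_meth_individuals = 25,
                       care_rates = list(),
                       seed = 1L, effects = true_effects()) {
  counts <- c(n_mothers, offspring_per_mother, n_sessions,
              session_length_min, n_cpg, n_meth_individuals)
  .assert(all(counts >= 1), "all counts must be >= 1")
  .assert(mean_coverage >= 10, "mean_coverage must be >= 10")
  .assert(inherits(effects, "true_effects"), "effects must be true_effects()")
  cr <- utils::modifyList(
    list(p_close = 0.40, sd_logit = 0.7, p_nurse = 0.45, p_groom = 0.30),
    care_rates)
  .assert(all(unlist(cr[c("p_close", "p_nurse", "p_groom")]) >= 0) &&
            all(unlist(cr[c("p_close", "p_nurse", "p_groom")]) <= 1),
          "care rates must be probabilities")
  out <- list(n_mothers = as.integer(n_mothers),
              offspring_per_mother = as.integer(offspring_per_mother),
              n_sessions = as.integer(n_sessions),
              session_length_min = as.integer(session_length_min),
              n_cpg = as.integer(n_cpg),
              mean_coverage = mean_coverage,
              n_meth_individuals = as.integer(n_meth_individuals),
              care_rates = cr,
              seed = as.integer(seed), effects = effects)
  class(out) <- "sim_config"
  out
}

#' Additive relationship (kinship) matrix from a maternal pedigree
#'
#' Tabular method over a pedigree with known mothers and unknown sires:
#' diagonal 1 (no inbreeding accumulates with unknown unrelated sires),
#' mother-offspring 0.5, maternal sibs 0.25.  Rows must be ordered so that
#' every mother precedes her offspring ([simulate_pedigree()] guarantees
#' this).
#'
#' @param pedigree data frame with `individual_id`, `mother_id` (`NA` for
#'   founders), `sex`, `birth_date`.
#' @return symmetric positive semidefinite matrix with unit diagonal,
#'   dimnames = individual ids.
#' @export
kinship_from_pedigree <- function(pedigree) {
  .assert(all(c("individual_id", "mother_id") %in% names(pedigree)),
          "pedigree needs individual_id and mother_id")
  ids <- as.character(pedigree$individual_id)
  .assert(!anyDuplicated(ids), "duplicate individual ids in pedigree")
  moms <- as.character(pedigree$mother_id)
  idx <- match(moms, ids)
  .assert(all(is.na(moms) | (!is.na(idx) & idx < seq_along(ids))),
          "every non-founder's mother must exist and precede her offspring")
  n <- length(ids)
  A <- diag(1, n)
  dimnames(A) <- list(ids, ids)
  for (i in seq_len(n)) {
    m <- idx[i]
    if (is.na(m)) next
    js <- seq_len(i - 1L)
    A[i, js] <- A[js, i] <- 0.5 * A[m, js]
    A[i, i] <- 1
  }
  A
}

#' Simulate a maternal pedigree and its kinship matrix
#'
#' Founder mothers plus `offspring_per_mother` cubs each, grouped into
#' litters of one or two separated by realistic interbirth intervals.
#'
#' @param config a [sim_config()].
#' @return list with `pedigree` (data frame `individual_id`, `mother_id`,
#'   `sex`, `birth_date`, `litter_id`, `litter_size`, `parity`) and
#'   `kinship`.
#' @export
simulate_pedigree <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be sim_config()")
  seed <- .sub_seeds(config$seed, "pedigree")
  .with_seed(seed, {
    nm <- config$n_mothers
    k <- config$offspring_per_mother
    mother_ids <- sprintf("F%03d", seq_len(nm))
    mother_birth <- as.Date("2005-01-01") + round(stats::runif(nm, 0, 3 * 365))
    rows <- list(data.frame(individual_id = mother_ids,
                            mother_id = NA_character_, sex = "F",
                            birth_date = mother_birth,
                            litter_id = NA_character_, litter_size = NA_integer_,
                            parity = NA_integer_, stringsAsFactors = FALSE))
    cub <- 0L
    for (m in seq_len(nm)) {
      remaining <- k
      parity <- 0L
      base <- as.Date("2011-01-01") + round(stats::runif(1, 0, 365))
      while (remaining > 0L) {
        parity <- parity + 1L
        size <- min(remaining, sample(1:2, 1L))
        bd <- base + round((parity - 1L) * stats::runif(1, 14, 20) * 30.44)
        litter <- sprintf("L%03d_%d", m, parity)
        for (s in seq_len(size)) {
          cub <- cub + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            individual_id = sprintf("H%03d", cub),
            mother_id = mother_ids[m],
            sex = sample(c("F", "M"), 1L),
            birth_date = bd, litter_id = litter,
            litter_size = size, parity = parity,
            stringsAsFactors = FALSE)
        }
        remaining <- remaining - size
      }
    }
    pedigree <- do.call(rbind, rows)
    list(pedigree = pedigree, kinship = kinship_from_pedigree(pedigree))
  })
}

# Disturbance level (0/1/2) and prey abundance per birth event (litter):
# ecological context varies across birth cohorts and is shared by
# litter-mates.
.litter_context <- function(litter_ids) {
  ul <- unique(litter_ids)
  dist_lvl <- stats::setNames(sample(0:2, length(ul), replace = TRUE,
                                     prob = c(0.4, 0.35, 0.25)), ul)
  prey <- stats::setNames(sample(c("low", "high"), length(ul),
                                 replace = TRUE), ul)
  list(disturbance = dist_lvl[litter_ids], prey = prey[litter_ids])
}

#' Simulate behavioral observation data
#'
#' Generates, from latent maternal care quality and individual
#' gregariousness, (i) focal-animal-survey records with per-minute care
#' indicators satisfying nursing <= close proximity and grooming <= close
#' proximity, (ii) co-occurrence sessions timestamped to span every
#' offspring's CD and DI windows, and (iii) the covariate table (sex,
#' maternal rank, litter size, parity, clan size, human disturbance, prey
#' abundance).
#'
#' @param pedigree the `pedigree` element of [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return list with `fas`, `sessions` (long format), `covariates`,
#'   `windows`, `traits` (latent care quality and sociability).
#' @export
simulate_behavior <- function(pedigree, config) {
  .assert(nrow(pedigree) > 0, "pedigree is empty")
  seed <- .sub_seeds(config$seed, "behavior")
  .with_seed(seed, {
    eff <- config$effects$covariate_effects
    cr <- config$care_rates
    is_mom <- is.na(pedigree$mother_id)
    moms <- pedigree[is_mom, ]
    cubs <- pedigree[!is_mom, ]
    nm <- nrow(moms); nc <- nrow(cubs)

    # latent traits
    care_quality <- stats::setNames(stats::rnorm(nm), moms$individual_id)
    sociability <- stats::setNames(stats::rnorm(nm + nc),
                                   c(moms$individual_id, cubs$individual_id))

    # per-mother social rank (standardized)
    rank_z <- stats::setNames(as.numeric(scale(rank(stats::runif(nm)))),
                              moms$individual_id)

    # covariates per offspring
    birth_year <- as.integer(format(cubs$birth_date, "%Y"))
    ctx <- .litter_context(cubs$litter_id)
    covariates <- data.frame(
      id = cubs$individual_id,
      mother_id = cubs$mother_id,
      sex = cubs$sex,
      birth_date = cubs$birth_date,
      maternal_rank = unname(rank_z[cubs$mother_id]),
      litter_size = cubs$litter_size,
      parity = cubs$parity,
      clan_size = 90L + 3L * (birth_year - min(birth_year)),
      human_disturbance = factor(c("low", "medium", "high")[ctx$disturbance + 1L],
                                 levels = c("low", "medium", "high")),
      prey_abundance = factor(unname(ctx$prey), levels = c("low", "high")),
      age_dart_months = round(stats::runif(nc, 11, 27), 1),
      stringsAsFactors = FALSE)

    # developmental windows: CD from birth, duration ~ N(6.98, 1.74) months,
    # DI matched to CD duration
    cd_len_days <- pmax(30, round(stats::rnorm(nc, 6.98, 1.74) * 30.44))
    windows <- define_windows(cubs$birth_date, cubs$birth_date + cd_len_days,
                              individual_id = cubs$individual_id)

    # sessions span all windows
    span <- range(c(as.Date(windows$start), as.Date(windows$end)))
    ns <- config$n_sessions
    session_dates <- sort(span[1] + round(stats::runif(ns, 0, as.numeric(diff(span)))))
    session_ampm <- sample(c("am", "pm"), ns, replace = TRUE)
    session_ids <- sprintf("S%04d", seq_len(ns))

    # presence: mothers active throughout; cubs between birth and 30 months
    all_ids <- c(moms$individual_id, cubs$individual_id)
    birth_all <- c(moms$birth_date, cubs$birth_date)
    p_present <- stats::plogis(ifelse(all_ids %in% moms$individual_id, -0.8, -1.2) +
                                 0.8 * sociability[all_ids])
    age_mat <- outer(as.numeric(session_dates), as.numeric(birth_all), "-") / 30.44
    eligible <- t(age_mat) >= 0 & t(age_mat) <= 30           # id x session
    eligible[all_ids %in% moms$individual_id, ] <- TRUE
    pres <- eligible & matrix(stats::runif(length(all_ids) * ns),
                              length(all_ids), ns) < p_present
    dimnames(pres) <- list(all_ids, session_ids)

    sess_idx <- which(pres, arr.ind = TRUE)
    sessions <- data.frame(session_id = session_ids[sess_idx[, 2L]],
                           date = session_dates[sess_idx[, 2L]],
                           ampm = session_ampm[sess_idx[, 2L]],
                           id = all_ids[sess_idx[, 1L]],
                           stringsAsFactors = FALSE)
    sessions <- sessions[order(sessions$session_id, sessions$id), ]
    rownames(sessions) <- NULL

    # FAS records: every session with a mother-cub pair co-present and the
    # cub under 18 months yields a timed care record
    L <- config$session_length_min
    dist_num <- as.integer(covariates$human_disturbance) - 1L
    names(dist_num) <- covariates$id
    p_close_m <- stats::plogis(stats::qlogis(pmin(pmax(cr$p_close, 0), 1)) +
                                 cr$sd_logit * care_quality)
    fas_rows <- vector("list", 0L)
    for (ci in seq_len(nc)) {
      cid <- cubs$individual_id[ci]
      mid <- cubs$mother_id[ci]
      both <- pres[cid, ] & pres[mid, ]
      age_m <- (as.numeric(session_dates) - as.numeric(cubs$birth_date[ci])) / 30.44
      use <- both & age_m < 18
      if (!any(use)) next
      k <- sum(use)
      p_close <- stats::plogis(stats::qlogis(pmin(pmax(p_close_m[mid], 1e-12),
                                                  1 - 1e-12)) +
                                 eff$care_disturbance * dist_num[cid])
      if (cr$p_close == 0) p_close <- 0
      if (cr$p_close == 1) p_close <- 1
      m_close <- stats::rbinom(k, L, p_close)
      m_nurse <- stats::rbinom(k, m_close, cr$p_nurse)
      m_groom <- stats::rbinom(k, m_close, cr$p_groom)
      fas_rows[[length(fas_rows) + 1L]] <- data.frame(
        session_id = session_ids[use],
        date = session_dates[use],
        mother_id = mid, cub_id = cid,
        minutes_together = L,
        minutes_close = m_close,
        minutes_nursing = m_nurse,
        minutes_grooming = m_groom,
        cub_age_months = round(age_m[use], 2),
        mother_lactating = age_m[use] < 13,
        stringsAsFactors = FALSE)
    }
    fas <- if (length(fas_rows)) do.call(rbind, fas_rows) else
      data.frame(session_id = character(), date = as.Date(character()),
                 mother_id = character(), cub_id = character(),
                 minutes_together = numeric(), minutes_close = numeric(),
                 minutes_nursing = numeric(), minutes_grooming = numeric(),
                 cub_age_months = numeric(), mother_lactating = logical())
    rownames(fas) <- NULL

    traits <- data.frame(id = all_ids,
                         sociability = unname(sociability[all_ids]),
                         care_quality = unname(care_quality[all_ids]),
                         stringsAsFactors = FALSE)

    list(fas = fas, sessions = sessions, covariates = covariates,
         windows = windows, traits = traits)
  })
}

#' Simulate repeated fecal glucocorticoid metabolite measurements
#'
#' Each individual receives 1-18 sampling occasions.  On the natural-log
#' scale, concentration = intercept + covariate terms + planted exposure
#' effects + an individual random intercept (SD `sigma_id`) + residual
#' noise; reported concentrations are the exponential, hence strictly
#' positive.
#'
#' @param individuals data frame with `id`, `sex`, `human_disturbance`
#'   (factor low/medium/high), and standardized exposures `z_care`, `z_net`.
#' @param effects a [true_effects()].
#' @param config a [sim_config()] (supplies the seed sub-stream).
#' @return data frame of samples (`id`, `fgcm`, `log_fgcm`, `age_months`,
#'   `repro_state`, `tod`, covariates), with the drawn individual intercepts
#'   in attribute `"b_id"`.
#' @export
simulate_fgcm <- function(individuals, effects, config) {
  .assert(all(c("id", "sex", "human_disturbance", "z_care", "z_net") %in%
                names(individuals)), "individuals lacks required columns")
  seed <- .sub_seeds(config$seed, "fgcm")
  .with_seed(seed, {
    eff <- effects$covariate_effects
    n <- nrow(individuals)
    b_id <- stats::rnorm(n, 0, effects$sigma_id)
    names(b_id) <- individuals$id
    n_occ <- sample(1:18, n, replace = TRUE)
    rows <- lapply(seq_len(n), function(i) {
      k <- n_occ[i]
      age <- sort(round(stats::runif(k, 24, 96), 1))
      repro <- if (individuals$sex[i] == "F") {
        sample(c("nulliparous", "pregnant", "lactating", "other"), k,
               replace = TRUE, prob = c(0.25, 0.2, 0.35, 0.2))
      } else rep("other", k)
      tod <- sample(c("am", "pm"), k, replace = TRUE)
      dist_num <- as.integer(individuals$human_disturbance[i]) - 1L
      mu <- eff$fgcm_intercept +
        effects$beta_care_on_logfgcm * individuals$z_care[i] +
        effects$beta_network_on_logfgcm * individuals$z_net[i] +
        eff$fgcm_sex_male * (individuals$sex[i] == "M") +
        eff$fgcm_disturbance * dist_num +
        eff$fgcm_age * age +
        eff$fgcm_pregnant * (repro == "pregnant") +
        eff$fgcm_lactating * (repro == "lactating") +
        eff$fgcm_pm * (tod == "pm")
      logf <- mu + b_id[i] + stats::rnorm(k, 0, effects$sigma_res_fgcm)
      data.frame(id = individuals$id[i], fgcm = exp(logf), log_fgcm = logf,
                 age_months = age,
                 repro_state = factor(repro, levels = c("nulliparous",
                                                        "pregnant",
                                                        "lactating", "other")),
                 tod = factor(tod, levels = c("am", "pm")),
                 sex = individuals$sex[i],
                 human_disturbance = individuals$human_disturbance[i],
                 stringsAsFactors = FALSE)
    })
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
    attr(samples, "b_id") <- b_id
    samples
  })
}

#' Simulate per-CpG methylation counts and global %CCGG methylation
#'
#' For each CpG site, per-individual logit methylation probability =
#' site intercept + `x * beta_site` + age term + `u`, with
#' `u ~ MVN(0, tau_kinship * K)` capturing genetic correlation; methylated
#' reads are Binomial(total, p) and totals are `1 + Poisson(mean_coverage -
#' 1)`.  `frac_true_dms` of sites receive a nonzero `beta_site` with random
#' sign; the planted set is recorded in the ground-truth ledger.  Site
#' intercepts are drawn from a three-component mixture (low / intermediate /
#' high methylation) so that the mean-bounds filter has realistic work to
#' do.  Global %CCGG is a linear model with a maternal random intercept.
#'
#' @param individuals data frame with `id`, `x` (standardized stress
#'   phenotype driving true sites), `age_months`; for the %CCGG table also
#'   `mother_id` and `z_care` (defaulting to unrelated mothers / no care
#'   effect when absent).
#' @param kinship PSD relatedness matrix over `individuals$id` (dimension
#'   must match).
#' @param effects a [true_effects()].
#' @param config a [sim_config()].
#' @return list with `counts` (a [meth_counts()] object), `ccgg`
#'   (data frame `id`, `ccgg`), and `truth` (site ledger + random draws).
#' @export
simulate_methylation <- function(individuals, kinship, effects, config) {
  .assert(all(c("id", "x", "age_months") %in% names(individuals)),
          "individuals needs id, x, age_months")
  n <- nrow(individuals)
  .assert(nrow(kinship) == n && ncol(kinship) == n,
          "kinship dimension does not match individuals")
  seed <- .sub_seeds(config$seed, "methylation")
  .with_seed(seed, {
    S <- config$n_cpg
    eff <- effects$covariate_effects

    # sites on synthetic scaffolds, 0-based positions
    chrom <- paste0("scaffold_", ((seq_len(S) - 1L) %/% 200L) + 1L)
    gap <- 50L + stats::rpois(S, 450)
    pos <- as.integer(stats::ave(gap, chrom, FUN = cumsum))
    sites <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    sites$site_id <- paste0(sites$chrom, ":", sites$pos)

    comp <- sample(1:3, S, replace = TRUE, prob = c(0.15, 0.70, 0.15))
    intercept <- c(stats::rnorm(S, -3.5, 0.7), stats::rnorm(S, 0, 1),
                   stats::rnorm(S, 3.5, 0.7))[S * (comp - 1L) + seq_len(S)]

    n_true <- round(effects$frac_true_dms * S)
    true_idx <- if (n_true > 0) sort(sample.int(S, n_true)) else integer()
    beta_site <- numeric(S)
    if (n_true > 0) {
      beta_site[true_idx] <- effects$beta_site *
        sample(c(-1, 1), n_true, replace = TRUE)
    }

    # kinship-correlated random effects, rows ~ MVN(0, tau K)
    u <- matrix(0, S, n)
    if (effects$tau_kinship > 0) {
      R <- chol(effects$tau_kinship * kinship + 1e-8 * diag(n))
      u <- matrix(stats::rnorm(S * n), S, n) %*% R
    }

    age_c <- individuals$age_months - mean(individuals$age_months)
    eta <- matrix(intercept, S, n) +
      outer(beta_site, individuals$x) +
      matrix(eff$meth_age * age_c, S, n, byrow = TRUE) + u
    p <- stats::plogis(eta)
    total <- matrix(1L + stats::rpois(S * n, config$mean_coverage - 1), S, n)
    meth <- matrix(stats::rbinom(S * n, total, p), S, n)
    dimnames(meth) <- dimnames(total) <- list(sites$site_id, individuals$id)
    counts <- meth_counts(meth, total, sites)

    # global %CCGG with maternal clustering
    mother <- if ("mother_id" %in% names(individuals))
      individuals$mother_id else individuals$id
    z_care <- if ("z_care" %in% names(individuals))
      individuals$z_care else rep(0, n)
    um <- unique(mother)
    b_mom <- stats::setNames(stats::rnorm(length(um), 0, effects$sigma_mom), um)
    ccgg <- eff$ccgg_intercept +
      effects$beta_care_on_ccgg * z_care +
      eff$ccgg_age * individuals$age_months +
      b_mom[mother] +
      stats::rnorm(n, 0, effects$sigma_res_ccgg)
    ccgg_df <- data.frame(id = individuals$id, ccgg = as.numeric(ccgg),
                          stringsAsFactors = FALSE)

    truth <- list(
      site = data.frame(site_id = sites$site_id, intercept = intercept,
                        beta_site = beta_site, is_true = beta_site != 0,
                        stringsAsFactors = FALSE),
      true_site_ids = sites$site_id[true_idx],
      u = u, b_mom = b_mom, x = stats::setNames(individuals$x, individuals$id))
    list(counts = counts, ccgg = ccgg_df, truth = truth)
  })
}

#' Draw synthetic EWAS test statistics with planted bias and inflation
#'
#' `z ~ N(z_bias, z_inflation^2)` null statistics for exercising the
#' empirical-null estimation and correction machinery against known truth.
#'
#' @param n number of statistics.
#' @param effects a [true_effects()] supplying `z_bias` and `z_inflation`.
#' @param seed integer seed.
#' @return numeric vector of z-scores.
#' @export
simulate_null_zscores <- function(n, effects = true_effects(), seed = 1L) {
  .with_seed(seed, stats::rnorm(n, effects$z_bias, effects$z_inflation))
}

#' Simulate a complete study with ground truth
#'
#' End-to-end generator: pedigree and kinship, behavioral records, realized
#' exposures computed with the package's own behavior module
#' ([maternal_care_proportions()], [window_network_metrics()]), fGCM samples
#' generated from the realized standardized exposures, %CCGG, and per-CpG
#' counts for a female methylation subsample whose stress phenotype `x` is
#' the standardized true individual fGCM intercept.  Individuals with
#' unobservable exposures (no qualifying care sessions, never seen in a
#' window) keep `NA` exposures for analysis and contribute at the exposure
#' mean to outcome generation.
#'
#' @param config a [sim_config()].
#' @return object of class `soc_study`: all raw tables, the merged
#'   per-individual table, the fGCM samples, methylation counts, and a
#'   `ground_truth` ledger holding every planted parameter and random draw.
#' @export
simulate_study <- function(config = sim_config()) {
  .assert(inherits(config, "sim_config"), "config must be sim_config()")
  ped <- simulate_pedigree(config)
  beh <- simulate_behavior(ped$pedigree, config)

  care <- maternal_care_proportions(beh$fas)
  metrics <- window_network_metrics(beh$sessions, beh$windows)
  mw <- stats::reshape(metrics, direction = "wide", idvar = "individual_id",
                       timevar = "label")
  names(mw) <- sub("^(degree|strength|betweenness)\\.(CD|DI)$", "\\2_\\1",
                   names(mw))
  names(mw) <- tolower(names(mw))
  names(mw)[names(mw) == "individual_id"] <- "id"

  ind <- beh$covariates
  ind <- merge(ind, care, by.x = "id", by.y = "cub_id", all.x = TRUE)
  names(ind)[names(ind) == "prop_close_proximity"] <- "prop_close"
  ind <- merge(ind, mw, by = "id", all.x = TRUE)
  ind <- ind[order(ind$id), ]
  rownames(ind) <- NULL

  zfill <- function(v) {
    z <- rep(0, length(v))
    ok <- is.finite(v)
    if (sum(ok) >= 2 && stats::sd(v[ok]) > 0)
      z[ok] <- (v[ok] - mean(v[ok])) / stats::sd(v[ok])
    z
  }
  ind$z_care <- zfill(ind$prop_close)
  ind$z_net <- zfill(ind$di_degree)

  fgcm <- simulate_fgcm(ind, config$effects, config)
  b_id <- attr(fgcm, "b_id")

  # stress phenotype driving methylation: standardized true individual
  # intercept (the quantity the analysis approximates with BLUPs)
  ind$x <- as.numeric(scale(b_id[ind$id]))
  meth_in <- ind[, c("id", "x", "age_dart_months", "mother_id", "z_care")]
  names(meth_in)[names(meth_in) == "age_dart_months"] <- "age_months"
  K <- ped$kinship[ind$id, ind$id]
  meth <- simulate_methylation(meth_in, K, config$effects, config)
  ind$ccgg <- meth$ccgg$ccgg[match(ind$id, meth$ccgg$id)]

  females <- ind$id[ind$sex == "F"]
  n_sub <- min(config$n_meth_individuals, length(females))
  meth_ids <- .with_seed(.sub_seeds(config$seed, "meth_sample"),
                         sort(sample(females, n_sub)))

  out <- list(
    config = config,
    pedigree = ped$pedigree,
    kinship = ped$kinship,
    fas = beh$fas,
    sessions = beh$sessions,
    windows = beh$windows,
    care = care,
    network_metrics = metrics,
    individuals = ind,
    fgcm = fgcm,
    meth = meth$counts,
    meth_sample_ids = meth_ids,
    ground_truth = list(effects = config$effects,
                        b_id = b_id,
                        traits = beh$traits,
                        site = meth$truth$site,
                        true_site_ids = meth$truth$true_site_ids,
                        u = meth$truth$u,
                        b_mom = meth$truth$b_mom,
                        x = meth$truth$x)
  )
  class(out) <- "soc_study"
  out
}

#' @export
print.soc_study <- function(x, ...) {
  cat("Synthetic early-social / methylation / stress study\n")
  cat(sprintf("  %d mothers, %d offspring, %d sessions, %d FAS records\n",
              sum(is.na(x$pedigree$mother_id)),
              sum(!is.na(x$pedigree$mother_id)),
              length(unique(x$sessions$session_id)), nrow(x$fas)))
  cat(sprintf("  %d fGCM samples over %d individuals; %d CpG sites x %d individuals\n",
              nrow(x$fgcm), length(unique(x$fgcm$id)),
              nrow(x$meth$sites), ncol(x$meth$meth)))
  cat(sprintf("  methylation subsample: %d females; seed %d\n",
              length(x$meth_sample_ids), x$config$seed))
  invisible(x)
}
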