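# Orchestration: the four analysis parts run end-to-end from one seeded
# config, on either a synthetic study or tabular inputs read from disk.
#
# Part 1: early-social exposures -> adult fGCMs (individual random
#         intercept, percent-change reporting).
# Part 2: exposures -> global %CCGG methylation under four covariate tiers
#         (maternal random intercept), the maternal-rank interaction screen,
#         and %CCGG -> fGCMs.
# Part 3: three-step mediation on the complete-case subsample.
# Part 4: BLUP consolidation -> count EWAS -> meet-in-the-middle screen.

.care_exposures <- c("prop_close", "prop_nursing", "prop_grooming")
.network_exposures <- c("cd_degree", "cd_strength", "cd_betweenness",
                        "di_degree", "di_strength", "di_betweenness")

#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `input_dir` (a
#' directory written by [write_study()]) must be supplied.
#'
#' @param simulation a [sim_config()] for simulation mode.
#' @param input_dir directory of study tables for file mode.
#' @param parts which analysis parts to run.
#' @param tiers covariate tiers for the Part-2 models.
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param fdr FDR level for DMS calls.
#' @param p_cut nominal threshold of the meet-in-the-middle screen.
#' @param alpha_interaction threshold for the maternal-rank interaction
#'   screen.
#' @param mediation_exposures exposures carried into Part 3.
#' @param seed integer seed governing every stochastic step.
#' @param outdir optional output directory for result tables.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = NULL, input_dir = NULL,
                       parts = c("part1", "part2", "part3", "part4"),
                       tiers = c("demographic", "social", "ecological", "all"),
                       n_boot = 2000, fdr = 0.05, p_cut = 0.1,
                       alpha_interaction = 0.10,
                       mediation_exposures = c("prop_close", "di_degree"),
                       seed = 1L, outdir = NULL) {
  .assert(xor(is.null(simulation), is.null(input_dir)),
          "supply exactly one of simulation or input_dir")
  .assert(!is.null(seed), "a seed is required")
  if (!is.null(simulation))
    .assert(inherits(simulation, "sim_config"), "simulation must be sim_config()")
  out <- list(simulation = simulation, input_dir = input_dir,
              parts = parts, tiers = tiers, n_boot = n_boot, fdr = fdr,
              p_cut = p_cut, alpha_interaction = alpha_interaction,
              mediation_exposures = mediation_exposures,
              seed = as.integer(seed), outdir = outdir)
  class(out) <- "run_config"
  out
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulation` block
#' is forwarded to [sim_config()] (with an `effects` sub-block forwarded to
#' [true_effects()]).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    sim <- y$simulation
    if (!is.null(sim$effects)) sim$effects <- do.call(true_effects, sim$effects)
    y$simulation <- do.call(sim_config, sim)
  }
  do.call(run_config, y)
}

# Standardize one exposure over individuals that have it, merge into the
# repeated-measures table, and fit unadjusted + adjusted mixed models with
# percentile-bootstrap CIs.
.part1_one <- function(exposure, individuals, samples, n_boot, seed) {
  ind <- individuals[is.finite(individuals[[exposure]]), c("id", exposure)]
  if (nrow(ind) < 3L || stats::sd(ind[[exposure]]) == 0) return(NULL)
  ind$.z <- standardize(ind[[exposure]])
  dat <- merge(samples, ind[, c("id", ".z")], by = "id")
  out <- lapply(c(unadjusted = FALSE, adjusted = TRUE), function(adj) {
    rhs <- if (adj) c(".z", "sex", "human_disturbance", "age_months",
                      "repro_state", "tod") else ".z"
    fml <- stats::reformulate(rhs, response = "log_fgcm")
    ci <- percentile_bootstrap_ci(fml, dat, "id", n_boot = n_boot, seed = seed)
    row <- ci[ci$term == ".z", ]
    data.frame(exposure = exposure, model = if (adj) "adjusted" else "unadjusted",
               n = length(unique(dat$id)), beta = row$estimate,
               lower = row$lower, upper = row$upper,
               percent_change = percent_change(row$estimate),
               pct_lower = percent_change(row$lower),
               pct_upper = percent_change(row$upper),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Part 1: early-social exposures and adult fGCMs
#'
#' Mixed-effects models of natural-log fGCM on each standardized exposure
#' with a random intercept per individual; unadjusted, and adjusted for
#' sex, human disturbance, age, reproductive state and time of day.
#' Estimates carry percentile-bootstrap CIs and percent-change translations.
#'
#' @param individuals per-individual table with exposures.
#' @param samples repeated fGCM measurements (`id`, `log_fgcm`, covariates).
#' @param exposures exposure column names.
#' @param n_boot,seed bootstrap settings.
#' @return data frame, one row per exposure x model.
#' @export
part1_fgcm_models <- function(individuals, samples,
                              exposures = c(.care_exposures, .network_exposures),
                              n_boot = 2000, seed = 1L) {
  seeds <- .sub_seeds(seed, exposures)
  res <- lapply(exposures, function(e)
    .part1_one(e, individuals, samples, n_boot, seeds[e]))
  do.call(rbind, res)
}

.part2_tier_covs <- function(tier, exposure) {
  social <- if (exposure %in% .network_exposures)
    c("litter_size", "clan_size", "maternal_rank")
  else c("litter_size", "parity", "maternal_rank")
  switch(tier,
         demographic = "sex",
         social = social,
         ecological = c("human_disturbance", "prey_abundance"),
         all = unique(c("sex", social, "human_disturbance", "prey_abundance")),
         stop("unknown tier: ", tier))
}

#' Part 2: exposures and global %CCGG methylation
#'
#' Linear mixed models of %CCGG on each standardized exposure with a random
#' intercept for maternal ID (siblings share a mother), age at darting
#' always included, under four covariate tiers (demographic / social /
#' ecological / all).  A maternal-rank interaction screen is run per
#' exposure at `alpha_interaction`.  Also fits the %CCGG -> fGCM model
#' (individual random intercept, Part-1 covariates).
#'
#' @param individuals per-individual table with exposures, `ccgg`,
#'   `mother_id`, covariates.
#' @param samples repeated fGCM measurements (for the %CCGG -> fGCM model).
#' @param exposures exposure column names.
#' @param tiers covariate tiers.
#' @param n_boot,seed bootstrap settings.
#' @param alpha_interaction interaction-screen threshold.
#' @return list with `ccgg_models` (tier estimates), `interactions`, and
#'   `ccgg_to_fgcm`.
#' @export
part2_ccgg_models <- function(individuals, samples,
                              exposures = c(.care_exposures, .network_exposures),
                              tiers = c("demographic", "social", "ecological",
                                        "all"),
                              n_boot = 2000, seed = 1L,
                              alpha_interaction = 0.10) {
  seeds <- .sub_seeds(seed, c(exposures, ".ccgg_fgcm"))
  rows <- list()
  inter <- list()
  for (e in exposures) {
    ind <- individuals[is.finite(individuals[[e]]) &
                         is.finite(individuals$ccgg), , drop = FALSE]
    if (nrow(ind) < 3L || stats::sd(ind[[e]]) == 0) next
    ind$.z <- standardize(ind[[e]])
    tier_seeds <- .sub_seeds(seeds[e], c(tiers, ".int"))
    for (tier in tiers) {
      covs <- .part2_tier_covs(tier, e)
      fml <- stats::reformulate(c(".z", "age_dart_months", covs),
                                response = "ccgg")
      ci <- tryCatch(
        percentile_bootstrap_ci(fml, ind, "mother_id", n_boot = n_boot,
                                seed = tier_seeds[tier]),
        error = function(err) NULL)
      if (is.null(ci)) next
      row <- ci[ci$term == ".z", ]
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = e, tier = tier, n = nrow(ind), beta = row$estimate,
        lower = row$lower, upper = row$upper, stringsAsFactors = FALSE)
    }
    fi <- tryCatch(
      fit_lmm(ccgg ~ .z * maternal_rank + age_dart_months, ind, "mother_id"),
      error = function(err) NULL)
    if (!is.null(fi)) {
      ti <- test_interaction(fi, ".z:maternal_rank", alpha = alpha_interaction)
      inter[[length(inter) + 1L]] <- data.frame(
        exposure = e, estimate = ti$estimate, p = ti$p, flag = ti$flag,
        stringsAsFactors = FALSE)
    }
  }
  # %CCGG -> fGCM
  cc <- individuals[is.finite(individuals$ccgg), c("id", "ccgg")]
  cc$.z <- standardize(cc$ccgg)
  dat <- merge(samples, cc[, c("id", ".z")], by = "id")
  ci <- percentile_bootstrap_ci(
    log_fgcm ~ .z + sex + human_disturbance + age_months + repro_state + tod,
    dat, "id", n_boot = n_boot, seed = seeds[".ccgg_fgcm"])
  row <- ci[ci$term == ".z", ]
  ccgg_to_fgcm <- data.frame(n = length(unique(dat$id)), beta = row$estimate,
                             lower = row$lower, upper = row$upper)
  list(ccgg_models = do.call(rbind, rows),
       interactions = do.call(rbind, inter),
       ccgg_to_fgcm = ccgg_to_fgcm)
}

#' Part 4: BLUP consolidation, EWAS and meet-in-the-middle screen
#'
#' Consolidates repeated log fGCMs into per-individual BLUPs, runs the
#' kinship-aware count EWAS over the methylation subsample, and screens the
#' resulting DMSs against maternal care and rank.
#'
#' @param study a `soc_study` (or compatible list with `fgcm`, `meth`,
#'   `individuals`, `kinship`, `meth_sample_ids`).
#' @param fdr,p_cut thresholds.
#' @param seed seed for the empirical-null restarts.
#' @return list with `blups`, `ewas` (the [run_ewas()] table), `dms`
#'   (DMS subset), and `mitm` (screen table).
#' @export
part4_ewas <- function(study, fdr = 0.05, p_cut = 0.1, seed = 1L) {
  blups <- extract_blups(study$fgcm)
  bl <- stats::setNames(blups$blup, blups$id)
  ids <- intersect(study$meth_sample_ids, names(bl))
  .assert(length(ids) >= 5, "too few methylation individuals with fGCM data")
  counts <- subset_meth(study$meth, individuals = ids)
  age <- stats::setNames(study$individuals$age_dart_months,
                         study$individuals$id)[ids]
  K <- study$kinship[ids, ids]
  ew <- run_ewas(counts, bl[ids], age = age, kinship = K, fdr = fdr,
                 null_seed = seed)
  dms <- ew[ew$is_dms %in% TRUE, , drop = FALSE]
  care <- study$individuals[study$individuals$id %in% ids,
                            c("id", "prop_close", "prop_nursing",
                              "prop_grooming", "maternal_rank")]
  mitm <- mitm_screen(
    data.frame(site_id = dms$site_id, beta_fgcm = dms$beta_corrected),
    counts, care, age = age, p_cut = p_cut)
  list(blups = blups, ewas = ew, dms = dms, mitm = mitm)
}

#' Run the full analysis pipeline
#'
#' Executes the requested parts in order on a simulated study (simulation
#' mode) or on study tables read from disk, with every stochastic step
#' seeded from the config.  Result tables are returned as a `run_report`
#' and, when `outdir` is set, written as TSV/JSON under it.
#'
#' @param config a [run_config()], or a path to a YAML file for
#'   [read_run_config()].
#' @return object of class `run_report`: per-part tables plus `provenance`
#'   (package version, seed, problem sizes).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  .assert(inherits(config, "run_config"), "config must be run_config()")
  seeds <- .sub_seeds(config$seed, c("part1", "part2", "part3", "part4"))

  study <- if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    simulate_study(sim)
  } else {
    read_study(config$input_dir)
  }

  report <- list(provenance = list(
    package = "socmethyl",
    version = as.character(utils::packageVersion("socmethyl")),
    seed = config$seed,
    n_individuals = nrow(study$individuals),
    n_fgcm_samples = nrow(study$fgcm),
    n_cpg = nrow(study$meth$sites),
    n_meth_individuals = length(study$meth_sample_ids),
    n_boot = config$n_boot))

  if ("part1" %in% config$parts) {
    report$part1 <- part1_fgcm_models(study$individuals, study$fgcm,
                                      n_boot = config$n_boot,
                                      seed = seeds["part1"])
  }
  if ("part2" %in% config$parts) {
    report$part2 <- part2_ccgg_models(study$individuals, study$fgcm,
                                      tiers = config$tiers,
                                      n_boot = config$n_boot,
                                      seed = seeds["part2"],
                                      alpha_interaction = config$alpha_interaction)
  }
  if ("part3" %in% config$parts) {
    med_seeds <- .sub_seeds(seeds["part3"], config$mediation_exposures)
    report$part3 <- lapply(stats::setNames(config$mediation_exposures,
                                           config$mediation_exposures),
                           function(e) {
      tryCatch(mediation_analysis(study$fgcm, study$individuals, exposure = e,
                                  covariates_y = c("sex", "human_disturbance",
                                                   "age_months", "repro_state",
                                                   "tod"),
                                  covariates_m = "age_dart_months",
                                  n_boot = config$n_boot,
                                  seed = med_seeds[e]),
               error = function(err) list(exposure = e,
                                          error = conditionMessage(err)))
    })
  }
  if ("part4" %in% config$parts) {
    report$part4 <- part4_ewas(study, fdr = config$fdr, p_cut = config$p_cut,
                               seed = seeds["part4"])
  }
  report$study <- study
  class(report) <- "run_report"
  if (!is.null(config$outdir)) .write_report(report, config$outdir)
  report
}

.write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) if (!is.null(x))
    data.table::fwrite(x, file.path(outdir, f), sep = "\t")
  w(report$part1, "part1_fgcm.tsv")
  if (!is.null(report$part2)) {
    w(report$part2$ccgg_models, "part2_ccgg.tsv")
    w(report$part2$interactions, "part2_interactions.tsv")
    w(report$part2$ccgg_to_fgcm, "part2_ccgg_to_fgcm.tsv")
  }
  if (!is.null(report$part3)) {
    jsonlite::write_json(
      lapply(report$part3, function(m) unclass(m)[setdiff(names(m), "fit")]),
      file.path(outdir, "part3_mediation.json"), auto_unbox = TRUE,
      digits = NA, force = TRUE)
  }
  if (!is.null(report$part4)) {
    w(as.data.frame(report$part4$ewas), "part4_ewas.tsv")
    w(report$part4$mitm, "part4_mitm.tsv")
    w(report$part4$blups, "part4_blups.tsv")
  }
  jsonlite::write_json(report$provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$provenance$seed, ")\n")
  if (!is.null(x$part1))
    cat(sprintf("  Part 1: %d exposure models\n", nrow(x$part1)))
  if (!is.null(x$part2))
    cat(sprintf("  Part 2: %d tier models, %d interaction screens\n",
                nrow(x$part2$ccgg_models), nrow(x$part2$interactions)))
  if (!is.null(x$part3))
    cat(sprintf("  Part 3: mediation for %s\n",
                paste(names(x$part3), collapse = ", ")))
  if (!is.null(x$part4))
    cat(sprintf("  Part 4: %d sites tested, %d DMS calls, %d mitm rows\n",
                sum(x$part4$ewas$converged, na.rm = TRUE),
                sum(x$part4$ewas$is_dms, na.rm = TRUE),
                nrow(x$part4$mitm)))
  invisible(x)
}

#' Read study tables written by [write_study()]
#'
#' @param dir directory containing the study files.
#' @return a list compatible with [run_pipeline()] file mode.
#' @export
read_study <- function(dir) {
  .assert(dir.exists(dir), paste0("no such directory: ", dir))
  ind <- as.data.frame(data.table::fread(file.path(dir, "covariates.csv")))
  for (col in c("human_disturbance", "prey_abundance"))
    if (col %in% names(ind))
      ind[[col]] <- factor(ind[[col]],
                           levels = if (col == "human_disturbance")
                             c("low", "medium", "high") else c("low", "high"))
  fgcm <- as.data.frame(data.table::fread(file.path(dir, "fgcm.csv")))
  fgcm$repro_state <- factor(fgcm$repro_state,
                             levels = c("nulliparous", "pregnant",
                                        "lactating", "other"))
  fgcm$tod <- factor(fgcm$tod, levels = c("am", "pm"))
  fgcm$human_disturbance <- factor(fgcm$human_disturbance,
                                   levels = c("low", "medium", "high"))
  ped <- as.data.frame(data.table::fread(file.path(dir, "pedigree.tsv")))
  names(ped) <- c("individual_id", "mother_id", "sex")
  ped$mother_id[ped$mother_id == ""] <- NA_character_
  meth <- read_meth_matrix(file.path(dir, "meth_matrix.tsv"))
  gt_path <- file.path(dir, "ground_truth.json")
  meth_ids <- if (file.exists(gt_path))
    unlist(jsonlite::read_json(gt_path)$meth_sample_ids)
  else intersect(ind$id[ind$sex == "F"], meth$individuals)
  list(individuals = ind, fgcm = fgcm, pedigree = ped,
       kinship = kinship_from_pedigree(ped), meth = meth,
       meth_sample_ids = meth_ids)
}

#' Screen a candidate-region percent-methylation table for invariance
#'
#' Candidate-gene panels sometimes return essentially unmethylated,
#' invariant CpGs (e.g. a putative glucocorticoid-receptor promoter in
#' leukocyte DNA); when every site's mean and range of percent methylation
#' fall below `epsilon`, downstream candidate-gene analysis is pointless
#' and is skipped with a notice.
#'
#' @param percent_table matrix or data frame, sites x individuals, of
#'   percent methylation values.
#' @param epsilon invariance threshold in percent.
#' @return list with `flag` and per-site `summary` (`mean`, `range`).
#' @export
detect_invariant_candidate_region <- function(percent_table, epsilon = 1.0) {
  m <- as.matrix(percent_table)
  .assert(length(m) > 0 && nrow(m) > 0, "percent table is empty")
  .assert(is.numeric(m), "percent table must be numeric")
  mu <- rowMeans(m)
  rg <- apply(m, 1L, function(v) diff(range(v)))
  flag <- all(mu < epsilon) && all(rg < epsilon)
  if (flag) {
    message("candidate region is invariant and near-zero methylated; ",
            "skipping candidate-gene analysis")
  }
  list(flag = flag,
       summary = data.frame(site = rownames(m) %||% seq_len(nrow(m)),
                            mean = mu, range = rg, row.names = NULL))
}
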