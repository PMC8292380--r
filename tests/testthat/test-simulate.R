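test_that("kinship matrix matches path-counting on small pedigrees", {
  # two unrelated founders
  ped2 <- data.frame(individual_id = c("a", "b"),
                     mother_id = NA_character_, sex = "F",
                     birth_date = as.Date("2000-01-01"))
  expect_equal(kinship_from_pedigree(ped2), diag(2),
               ignore_attr = TRUE)
  # mother with two cubs: mother-offspring 0.5, maternal sibs 0.25
  ped3 <- data.frame(individual_id = c("m", "c1", "c2"),
                     mother_id = c(NA, "m", "m"), sex = c("F", "F", "M"),
                     birth_date = as.Date(c("2000-01-01", "2005-01-01",
                                            "2005-01-01")))
  K <- kinship_from_pedigree(ped3)
  expect_equal(unname(diag(K)), rep(1, 3))
  expect_equal(K["m", "c1"], 0.5)
  expect_equal(K["m", "c2"], 0.5)
  expect_equal(K["c1", "c2"], 0.25)
  # grandmother chain: 0.25 across two generations
  ped4 <- data.frame(individual_id = c("g", "m", "c"),
                     mother_id = c(NA, "g", "m"), sex = "F",
                     birth_date = as.Date(c("1995-01-01", "2000-01-01",
                                            "2005-01-01")))
  expect_equal(kinship_from_pedigree(ped4)["g", "c"], 0.25)
})

test_that("simulated pedigrees give PSD unit-diagonal kinship, deterministically", {
  cfg <- sim_config(n_mothers = 10, seed = 7)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  K <- p1$kinship
  expect_equal(unname(diag(K)), rep(1, nrow(K)))
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # maternal sibs share 0.25
  sibs <- p1$pedigree[!is.na(p1$pedigree$mother_id), ]
  fam <- split(sibs$individual_id, sibs$mother_id)
  fam <- fam[lengths(fam) >= 2][[1]]
  expect_equal(K[fam[1], fam[2]], 0.25)
  expect_error(sim_config(n_mothers = 0), ">= 1")
  expect_error(sim_config(mean_coverage = 5), "mean_coverage")
})

test_that("behavioral records satisfy the care-minute orderings and window spans", {
  cfg <- sim_config(n_mothers = 10, n_sessions = 120, seed = 9)
  ped <- simulate_pedigree(cfg)
  beh <- simulate_behavior(ped$pedigree, cfg)
  expect_true(all(beh$fas$minutes_nursing <= beh$fas$minutes_close))
  expect_true(all(beh$fas$minutes_grooming <= beh$fas$minutes_close))
  expect_true(all(beh$fas$minutes_close <= beh$fas$minutes_together))
  # sessions span every offspring's CD and DI windows
  expect_lte(as.Date(min(beh$sessions$date)), min(as.Date(beh$windows$start)))
  expect_gte(as.Date(max(beh$sessions$date)), max(as.Date(beh$windows$end)) - 30)
  need <- c("sex", "maternal_rank", "litter_size", "parity", "clan_size",
            "human_disturbance", "prey_abundance")
  expect_true(all(need %in% names(beh$covariates)))
})

test_that("care-rate extremes force all-zero and all-one proportions", {
  cfg0 <- sim_config(n_mothers = 6, n_sessions = 60, seed = 2,
                     care_rates = list(p_close = 0, p_nurse = 0, p_groom = 0))
  beh0 <- simulate_behavior(simulate_pedigree(cfg0)$pedigree, cfg0)
  expect_true(all(beh0$fas$minutes_close == 0))
  cs0 <- maternal_care_proportions(beh0$fas)
  expect_true(all(cs0$prop_close_proximity == 0))
  cfg1 <- sim_config(n_mothers = 6, n_sessions = 60, seed = 2,
                     care_rates = list(p_close = 1))
  beh1 <- simulate_behavior(simulate_pedigree(cfg1)$pedigree, cfg1)
  expect_true(all(beh1$fas$minutes_close == beh1$fas$minutes_together))
  expect_true(all(maternal_care_proportions(beh1$fas)$prop_close_proximity == 1))
})

test_that("a planted gregariousness gradient shows up in realized co-occurrence", {
  cors <- sapply(1:8, function(r) {
    cfg <- sim_config(n_mothers = 15, n_sessions = 500, seed = 100 + r)
    ped <- simulate_pedigree(cfg)
    beh <- simulate_behavior(ped$pedigree, cfg)
    counts <- table(beh$sessions$id)
    tr <- beh$traits
    cor(tr$sociability, as.numeric(counts[tr$id]), method = "spearman",
        use = "complete.obs")
  })
  expect_true(all(cors > 0.5))
})

test_that("fGCM samples are positive, repeated 1-18 times, and collapse without noise", {
  cfg <- sim_config(n_mothers = 10, seed = 31)
  ind <- data.frame(id = sprintf("h%02d", 1:20), sex = rep(c("F", "M"), 10),
                    human_disturbance = factor(rep(c("low", "medium", "high"),
                                                   length.out = 20),
                                               levels = c("low", "medium",
                                                          "high")),
                    z_care = rnorm(20), z_net = rnorm(20))
  sam <- simulate_fgcm(ind, cfg$effects, cfg)
  expect_true(all(sam$fgcm > 0))
  reps <- table(sam$id)
  expect_true(all(reps >= 1 & reps <= 18))
  expect_equal(sam$log_fgcm, log(sam$fgcm))
  # no individual heterogeneity, no residual noise -> deterministic mean
  eff0 <- true_effects(sigma_id = 0, sigma_res_fgcm = 0)
  sam0 <- simulate_fgcm(ind, eff0, cfg)
  one <- sam0[sam0$id == "h01" & sam0$repro_state == "other" &
                sam0$tod == "am", ]
  if (nrow(one) >= 2) {
    mu <- one$log_fgcm - eff0$covariate_effects$fgcm_age * one$age_months
    expect_equal(diff(range(mu)), 0, tolerance = 1e-12)
  }
  succeed()
})

test_that("planted network effect is recovered by the adjusted mixed model", {
  est <- sapply(1:10, function(s) {
    st <- simulate_study(sim_config(seed = 300 + s))
    ind <- st$individuals
    ind$.z <- standardize(ind$di_degree)
    d <- merge(st$fgcm, ind[, c("id", ".z")], by = "id")
    fit <- suppressWarnings(fit_lmm(
      log_fgcm ~ .z + sex + human_disturbance + age_months + repro_state + tod,
      d, "id"))
    unname(fit$beta[".z"])
  })
  expect_lt(abs(mean(est) - (-0.12)), 0.06)
})

test_that("null exposure effects are estimated as zero on average", {
  cfg <- sim_config(seed = 1, effects = true_effects(
    beta_care_on_logfgcm = 0, beta_network_on_logfgcm = 0))
  est <- sapply(1:40, function(s) {
    set.seed(s)
    n <- 80
    ind <- data.frame(id = sprintf("h%02d", 1:n), sex = "F",
                      human_disturbance = factor("low", levels = c("low",
                                                                   "medium",
                                                                   "high")),
                      z_care = rnorm(n), z_net = rnorm(n))
    cfg2 <- cfg; cfg2$seed <- s
    sam <- simulate_fgcm(ind, cfg2$effects, cfg2)
    d <- merge(sam, ind[, c("id", "z_net")], by = "id")
    unname(suppressWarnings(fit_lmm(log_fgcm ~ z_net + age_months, d,
                                    "id"))$beta["z_net"])
  })
  expect_lt(abs(mean(est)), 0.02)
})

test_that("methylation counts respect bounds, ledger bookkeeping and binomial dispersion", {
  setup <- ewas_sim_inputs(n = 25, seed = 3)
  ind <- data.frame(id = setup$ids, x = unname(setup$x),
                    age_months = unname(setup$age))
  cfg <- sim_config(n_cpg = 2000, seed = 3,
                    effects = true_effects(frac_true_dms = 0.1))
  sm <- simulate_methylation(ind, setup$kinship, cfg$effects, cfg)
  expect_true(all(sm$counts$meth <= sm$counts$total))
  expect_true(all(sm$counts$total >= 1))
  # exactly frac * n_cpg sites flagged true
  expect_equal(sum(sm$truth$site$is_true), 200L)
  expect_length(sm$truth$true_site_ids, 200L)
  # dimension mismatch is a shape error
  expect_error(simulate_methylation(ind, setup$kinship[1:10, 1:10],
                                    cfg$effects, cfg), "dimension")
  # pure binomial regime: variance of site fractions matches binomial
  cfg0 <- sim_config(n_cpg = 1000, seed = 5,
                     effects = true_effects(tau_kinship = 0,
                                            frac_true_dms = 0))
  sm0 <- simulate_methylation(ind, setup$kinship, cfg0$effects, cfg0)
  frac <- sm0$counts$meth / sm0$counts$total
  phat <- rowMeans(frac)
  vobs <- apply(frac, 1, var)
  vbin <- rowMeans(phat * (1 - phat) / sm0$counts$total)
  ratio <- mean(vobs / pmax(vbin, 1e-12))
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("the container accepts zero-total cells and the coverage filter removes them", {
  meth <- matrix(5L, 4, 3); total <- matrix(20L, 4, 3)
  meth[2, 1] <- 0L; total[2, 1] <- 0L
  counts <- make_counts(meth, total)
  expect_s3_class(counts, "meth_counts")
  fc <- filter_cpgs(counts, low_var_drop = 0)
  expect_false(counts$sites$site_id[2] %in% fc$sites$site_id)
})

test_that("a fixed seed reproduces the full study byte-identically", {
  cfg <- sim_config(n_mothers = 8, n_sessions = 80, n_cpg = 100,
                    n_meth_individuals = 8, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$fgcm, s2$fgcm)
  expect_identical(s1$meth$meth, s2$meth$meth)
  expect_identical(s1$ground_truth$b_id, s2$ground_truth$b_id)
})

test_that("study files round-trip through the writers and readers", {
  cfg <- sim_config(n_mothers = 6, n_sessions = 60, n_cpg = 50,
                    n_meth_individuals = 6, seed = 15)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "covariates.csv", "fas_records.csv", "sessions.csv", "fgcm.csv",
    "pedigree.tsv", "meth_matrix.tsv", "ground_truth.json")))))
  back <- read_study(dir)
  expect_equal(back$meth$meth, st$meth$meth)
  expect_equal(back$meth$total, st$meth$total)
  expect_setequal(back$meth_sample_ids, st$meth_sample_ids)
  expect_equal(nrow(back$fgcm), nrow(st$fgcm))
  # bismark per-individual files round-trip too
  bis <- read_bismark_cov(list.files(file.path(dir, "bismark"),
                                     full.names = TRUE))
  expect_equal(sort(colnames(bis$meth)), sort(colnames(st$meth$meth)))
  id <- colnames(st$meth$meth)[1]
  expect_equal(bis$meth[rownames(st$meth$meth), id], st$meth$meth[, id])
  # sessions CSV parses back to the long format
  sess <- read_sessions_csv(file.path(dir, "sessions.csv"))
  expect_setequal(unique(sess$session_id), unique(st$sessions$session_id))
})
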