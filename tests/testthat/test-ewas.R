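test_that("meth_counts validates its count invariants", {
  expect_error(make_counts(matrix(5L, 2, 2), matrix(3L, 2, 2)),
               "methylated <= total")
  expect_error(make_counts(matrix(-1L, 2, 2), matrix(3L, 2, 2)))
  counts <- make_counts(matrix(2L, 3, 2), matrix(10L, 3, 2))
  sub <- subset_meth(counts, sites = 1:2, individuals = "i01")
  expect_equal(dim(sub$meth), c(2L, 1L))
})

test_that("CpG filters apply coverage, mean bounds and variance drop in order", {
  set.seed(1)
  n <- 10
  mk_site <- function(p, cov = 30L) {
    tot <- rep(cov, n)
    list(meth = rbinom(n, tot, p), total = tot)
  }
  sites <- list(
    hyper = mk_site(0.95),          # removed by mean bounds
    hypo = mk_site(0.03),           # removed by mean bounds
    lowcov = {s <- mk_site(0.5); s$total[3] <- 8L
              s$meth[3] <- min(s$meth[3], 8L); s},  # removed by coverage
    keep1 = mk_site(0.5), keep2 = mk_site(0.4), keep3 = mk_site(0.6))
  meth <- do.call(rbind, lapply(sites, `[[`, "meth"))
  total <- do.call(rbind, lapply(sites, `[[`, "total"))
  counts <- make_counts(meth, total)
  fc <- filter_cpgs(counts, low_var_drop = 0)
  log <- attr(fc, "filter_log")
  expect_equal(log$removed, c(0L, 1L, 2L, 0L))
  expect_equal(nrow(fc$meth), 3L)
  # a site with mean 0.95 is out; one low-coverage individual kills a site
  expect_equal(log$remaining, c(6L, 5L, 3L, 3L))
})

test_that("the variance drop removes exactly floor(frac*n) sites, ties by site order", {
  n <- 8
  meth <- matrix(rep(c(5L, 10L), each = n, times = 50), nrow = 100,
                 ncol = n, byrow = TRUE)
  # make all 100 sites identical (equal variance)
  row <- rep(c(5L, 10L), length.out = n)
  meth <- matrix(rep(row, 100), nrow = 100, byrow = TRUE)
  total <- matrix(20L, 100, n)
  counts <- make_counts(meth, total)
  fc <- filter_cpgs(counts, mean_bounds = c(0, 1), low_var_drop = 0.05)
  expect_equal(nrow(fc$meth), 95L)
  # the five dropped are the first five in site order
  expect_identical(fc$sites$site_id, counts$sites$site_id[-(1:5)])
  # coverage and mean-bound stages are idempotent
  fc2 <- filter_cpgs(fc, mean_bounds = c(0, 1), low_var_drop = 0)
  expect_identical(fc2$sites$site_id, fc$sites$site_id)
})

test_that("filtering everything is an explicit error", {
  counts <- make_counts(matrix(1L, 3, 4), matrix(5L, 3, 4))
  expect_error(filter_cpgs(counts, min_coverage = 10), "coverage")
})

test_that("with tau fixed at zero the site model reduces to logistic regression", {
  set.seed(2)
  n <- 25
  x <- rnorm(n); age <- runif(n, 11, 27)
  tot <- 1L + rpois(n, 29)
  y <- rbinom(n, tot, plogis(-0.3 + 0.4 * x))
  fit <- fit_site_model(y, tot, x, age = age, tau = 0)
  ref <- glm(cbind(y, tot - y) ~ x + age, family = binomial())
  expect_equal(fit$beta, unname(coef(ref)["x"]), tolerance = 1e-4)
  expect_equal(fit$se, unname(summary(ref)$coefficients["x", 2]),
               tolerance = 1e-4)
  expect_equal(fit$family, "binomial_pql")
  expect_error(fit_site_model(y, tot, rep(1, n)), "constant")
})

test_that("the site model recovers a planted effect under kinship", {
  setup <- ewas_sim_inputs(n = 25, seed = 5)
  K <- setup$kinship
  R <- chol(0.3 * K + 1e-8 * diag(25))
  set.seed(10)
  est <- replicate(100, {
    x <- rnorm(25)
    u <- as.numeric(crossprod(R, rnorm(25)))
    tot <- 1L + rpois(25, 29)
    y <- rbinom(25, tot, plogis(0.2 + 0.8 * x + u))
    fit_site_model(y, tot, x, kinship = K)$beta
  })
  expect_lt(abs(mean(est) - 0.8), 0.1)
})

test_that("the boundary fallback is a beta-binomial fit matching logistic estimates", {
  set.seed(3)
  n <- 30
  x <- rnorm(n)
  tot <- 1L + rpois(n, 29)
  y <- rbinom(n, tot, plogis(0.1 + 0.3 * x))   # no extra-binomial noise
  fit <- fit_site_model(y, tot, x, kinship = diag(n))
  if (fit$boundary) {
    expect_equal(fit$family, "betabinomial")
    ref <- glm(cbind(y, tot - y) ~ x, family = binomial())
    expect_equal(fit$beta, unname(coef(ref)["x"]), tolerance = 1e-2)
  }
  succeed()
})

test_that("empirical null recovers standard-normal statistics", {
  z <- simulate_null_zscores(6000, true_effects(), seed = 4)
  e <- estimate_empirical_null(z)
  expect_lt(abs(e$bias), 0.05)
  expect_gt(e$inflation, 0.95)
  expect_lt(e$inflation, 1.05)
  expect_gt(e$null_proportion, 0.9)
  expect_warning(estimate_empirical_null(rnorm(100)), "fewer than 500")
})

test_that("empirical null stays on the null despite a planted signal component", {
  res <- t(sapply(1:6, function(r) {
    set.seed(r)
    z <- c(rnorm(4500, 0.2, 1.1), rnorm(500, 3, 1))
    e <- estimate_empirical_null(z, seed = r)
    c(e$bias, e$inflation)
  }))
  expect_lt(abs(mean(res[, 1]) - 0.2), 0.05)
  expect_lt(abs(mean(res[, 2]) - 1.1), 0.05)
})

test_that("the null correction is identity at (0,1) and round-trips its own null", {
  betas <- c(-0.2, 0.1, 0.4)
  ses <- c(0.1, 0.2, 0.1)
  id <- apply_null_correction(betas, ses, list(bias = 0, inflation = 1))
  expect_equal(id$beta_corrected, betas)
  expect_equal(id$se_corrected, ses)
  expect_equal(id$p_corrected, 2 * pnorm(-abs(betas / ses)))
  # z' = 1.96 maps to p = 0.05
  p196 <- apply_null_correction(1.96, 1, list(bias = 0, inflation = 1))
  expect_equal(p196$p_corrected, 0.05, tolerance = 1e-3)
  expect_error(apply_null_correction(1, 0, list(bias = 0, inflation = 1)),
               "> 0")
  # round-trip: correcting draws from N(0.3, 1.2^2) renormalizes them
  set.seed(9)
  z <- rnorm(6000, 0.3, 1.2)
  co <- apply_null_correction(z, rep(1, 6000),
                              list(bias = 0.3, inflation = 1.2))
  expect_lt(abs(mean(co$z_corrected)), 0.05)
  expect_gt(sd(co$z_corrected), 0.95)
  expect_lt(sd(co$z_corrected), 1.05)
})

test_that("EWAS results are invariant to a consistent permutation of individuals", {
  setup <- ewas_sim_inputs(n = 20, seed = 8)
  cfg <- sim_config(n_cpg = 150, seed = 8,
                    effects = true_effects(frac_true_dms = 0.05))
  ind <- data.frame(id = setup$ids, x = unname(setup$x),
                    age_months = unname(setup$age))
  sm <- simulate_methylation(ind, setup$kinship, cfg$effects, cfg)
  run <- function(perm) {
    cc <- subset_meth(sm$counts, individuals = perm)
    run_ewas(cc, setup$x[perm], age = setup$age[perm],
             kinship = setup$kinship[perm, perm], null_seed = 1)
  }
  r1 <- run(setup$ids)
  r2 <- run(rev(setup$ids))
  expect_equal(r1$beta_raw, r2$beta_raw, tolerance = 1e-6)
  expect_equal(r1$p_corrected, r2$p_corrected, tolerance = 1e-5)
  expect_identical(r1$is_dms, r2$is_dms)
  # q_bh dominates p_corrected; is_dms corresponds to q <= fdr
  ok <- !is.na(r1$q_bh)
  expect_true(all(r1$q_bh[ok] >= r1$p_corrected[ok] - 1e-12))
  expect_identical(r1$is_dms[ok], r1$q_bh[ok] <= 0.05)
})

test_that("sites are labeled by interval precedence with enrichment output", {
  cpg <- data.frame(chrom = "s1", start = c(100L, 50L), end = c(200L, 400L),
                    label = c("island", "shore"))
  genic <- data.frame(chrom = "s1", start = c(0L, 120L), end = c(300L, 160L),
                      label = c("intron", "exon"))
  sites <- data.frame(chrom = "s1",
                      pos = c(150L, 250L, 500L, 130L, 10L),
                      is_dms = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  ann <- annotate_sites(sites, cpg, genic)
  # hand enumeration: 150 in island+shore -> island; 250 shore only;
  # 500 no track -> open_sea; 130 island+exon; 10 outside cpg tracks
  expect_equal(ann$cpg_context,
               c("island", "shore", "open_sea", "island", "open_sea"))
  expect_equal(ann$genic_context,
               c("exon", "intron", "intergenic", "exon", "intron"))
  enr <- attr(ann, "enrichment")
  expect_true(all(c("frac_all", "frac_dms") %in% names(enr)))
  expect_equal(sum(enr$frac_all[enr$track == "cpg_context"]), 1)
  # malformed intervals error
  bad <- data.frame(chrom = "s1", start = 10L, end = 10L, label = "island")
  expect_error(annotate_sites(sites, bad), "malformed")
})
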