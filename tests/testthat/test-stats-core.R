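test_that("standardize yields exact z-scores and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  z <- standardize(rnorm(50, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "distinct")
})

test_that("REML fit agrees with lme4 on estimates, SEs, variances and logLik", {
  skip_if_not_installed("lme4")
  set.seed(3)
  G <- 30; ni <- 4
  d <- data.frame(g = rep(seq_len(G), each = ni), x = rnorm(G * ni),
                  f = factor(sample(c("u", "v"), G * ni, TRUE)))
  b <- rnorm(G, 0, 0.5)
  d$y <- 2 + 0.7 * d$x - 0.4 * (d$f == "v") + b[d$g] + rnorm(nrow(d), 0, 0.6)
  fit <- fit_lmm(y ~ x + f, d, "g")
  ref <- lme4::lmer(y ~ x + f + (1 | g), d, REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(as.matrix(vcov(ref))))), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(ref))$vcov
  expect_equal(c(fit$sigma2_id, fit$sigma2_res), vc, tolerance = 1e-5)
  expect_equal(fit$logLik_reml, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$blups), lme4::ranef(ref)$g[, 1], tolerance = 1e-5)
})

test_that("noise-free linear data is recovered to machine precision", {
  d <- data.frame(g = rep(1:6, each = 3), x = seq_len(18))
  d$y <- 3 + 2 * d$x
  fit <- suppressWarnings(fit_lmm(y ~ x, d, "g"))
  expect_equal(unname(fit$beta), c(3, 2), tolerance = 1e-10)
})

test_that("simulation recovers a planted slope and a truly-zero group variance", {
  set.seed(11)
  est <- replicate(200, {
    G <- 80; ni <- 3
    x <- rnorm(G)
    b <- rnorm(G, 0, 0.3)
    d <- data.frame(g = rep(seq_len(G), each = ni), x = rep(x, each = ni))
    d$y <- 0.5 * d$x + b[d$g] + rnorm(G * ni, 0, 0.5)
    unname(fit_lmm(y ~ x, d, "g")$beta["x"])
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
  # constructed data with identical per-group response patterns: the
  # between-group variance component must collapse to (numerical) zero
  d0 <- data.frame(g = rep(1:10, each = 4), x = rep(1:4, 10))
  d0$y <- 2 * d0$x + rep(c(0.1, -0.1, 0.2, -0.2), 10)
  fit0 <- suppressWarnings(fit_lmm(y ~ x, d0, "g"))
  expect_lte(fit0$sigma2_id, 1e-6)
  expect_warning(fit_lmm(y ~ x, d0, "g"), "boundary")
})

test_that("rank-deficient designs fail with the collinear term named", {
  d <- data.frame(g = rep(1:5, each = 2), x = rnorm(10))
  d$x2 <- 2 * d$x
  d$y <- rnorm(10)
  expect_error(fit_lmm(y ~ x + x2, d, "g"), "x2")
})

test_that("bootstrap CIs are deterministic under a seed and degenerate on noise-free data", {
  set.seed(5)
  G <- 25
  d <- data.frame(g = rep(seq_len(G), each = 3), x = rnorm(3 * G))
  b <- rnorm(G, 0, 0.4)
  d$y <- 1 + 0.6 * d$x + b[d$g] + rnorm(nrow(d), 0, 0.5)
  ci1 <- percentile_bootstrap_ci(y ~ x, d, "g", n_boot = 200, seed = 99)
  ci2 <- percentile_bootstrap_ci(y ~ x, d, "g", n_boot = 200, seed = 99)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower <= ci1$estimate & ci1$estimate <= ci1$upper))
  # zero-noise data: every refit identical, CI width zero
  d$y <- 1 + 0.6 * d$x
  ci0 <- percentile_bootstrap_ci(y ~ x, d, "g", n_boot = 100, seed = 1)
  expect_equal(ci0$upper - ci0$lower, c(0, 0), tolerance = 1e-10)
})

test_that("BLUPs equal the balanced-design closed form and shrink raw deviations", {
  set.seed(8)
  G <- 20; ni <- 4
  samples <- data.frame(id = rep(sprintf("h%02d", seq_len(G)), each = ni),
                        log_fgcm = rnorm(G * ni, 4, 0.6) +
                          rep(rnorm(G, 0, 0.4), each = ni))
  bl <- extract_blups(samples)
  fit <- fit_lmm(log_fgcm ~ 1, samples, "id")
  shrink <- ni * fit$sigma2_id / (ni * fit$sigma2_id + fit$sigma2_res)
  ybar <- tapply(samples$log_fgcm, samples$id, mean)
  closed <- shrink * (ybar - unname(fit$beta[1]))
  expect_equal(bl$blup, as.numeric(closed[bl$id]), tolerance = 1e-6)
  expect_true(all(abs(bl$blup) <= abs(ybar[bl$id] - mean(samples$log_fgcm)) + 1e-8))
  # precision-weighted BLUPs sum to ~0 (balanced: plain sum)
  expect_lt(abs(sum(bl$blup)), 1e-6)
  # all-identical individuals give zero BLUPs
  flat <- data.frame(id = rep(c("a", "b", "c"), each = 3),
                     log_fgcm = rep(4, 9))
  expect_equal(extract_blups(flat)$blup, c(0, 0, 0))
  expect_error(extract_blups(flat[flat$id == "a", ]), "2 individuals")
})

test_that("individuals with more repeats are shrunk less", {
  set.seed(13)
  ids <- rep(c("a", "b"), times = c(2, 12))
  dev <- 1    # both individuals deviate by +1 raw units
  base <- rnorm(60, 4, 0.5)
  samples <- data.frame(
    id = c(ids, rep(sprintf("f%02d", 1:15), each = 3)),
    log_fgcm = c(4 + dev + rnorm(2, 0, 1e-6), 4 + dev + rnorm(12, 0, 1e-6),
                 rnorm(45, 4, 0.5)))
  bl <- extract_blups(samples)
  expect_lt(abs(bl$blup[bl$id == "a"]), abs(bl$blup[bl$id == "b"]))
})

test_that("percent change reproduces log-scale arithmetic and is monotone", {
  expect_equal(percent_change(-0.12), -11)
  expect_equal(percent_change(-0.14), -13)
  expect_equal(percent_change(0), 0)
  x <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(percent_change(x, round = FALSE)) > 0))
})

test_that("interaction screen flags at strict p < alpha", {
  set.seed(4)
  G <- 80
  x <- rnorm(G); r <- rnorm(G)
  b <- rnorm(G, 0, 0.3)
  d <- data.frame(g = rep(seq_len(G), each = 3), x = rep(x, each = 3),
                  r = rep(r, each = 3))
  d$y <- 0.3 * d$x + 0.5 * d$x * d$r + b[d$g] + rnorm(nrow(d), 0, 0.5)
  fit <- fit_lmm(y ~ x * r, d, "g")
  ti <- test_interaction(fit, "x:r", alpha = 0.10)
  expect_true(ti$flag)
  expect_error(test_interaction(fit, "nope"), "not in fit")
  # boundary convention: p exactly at alpha is not flagged
  fake <- fit
  fake$p["x:r"] <- 0.10
  expect_false(test_interaction(fake, "x:r", alpha = 0.10)$flag)
})

test_that("interaction screen holds its nominal size and has power", {
  set.seed(6)
  sim_flag <- function(gamma) {
    G <- 80
    x <- rnorm(G); r <- rnorm(G); b <- rnorm(G, 0, 0.3)
    d <- data.frame(g = rep(seq_len(G), each = 3), x = rep(x, each = 3),
                    r = rep(r, each = 3))
    d$y <- 0.3 * d$x + gamma * d$x * d$r + b[d$g] + rnorm(nrow(d), 0, 0.5)
    fit <- suppressWarnings(fit_lmm(y ~ x * r, d, "g"))
    test_interaction(fit, "x:r", alpha = 0.10)$flag
  }
  size <- mean(replicate(400, sim_flag(0)))
  expect_lt(abs(size - 0.10), 0.035)
  power <- mean(replicate(100, sim_flag(0.5)))
  expect_gte(power, 0.9)
})

test_that("BH adjustment matches the step-up oracle and is monotone in q", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.5)
  res <- bh_fdr(p, q = 0.05)
  expect_equal(res$reject, bh_oracle(p, 0.05))
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(res$q_bh >= res$p))
  expect_true(bh_fdr(0.01, q = 0.05)$reject)
  expect_false(any(bh_fdr(rep(1, 10))$reject))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # rejections only grow with q
  set.seed(2)
  pv <- runif(50)^2
  r1 <- bh_fdr(pv, q = 0.01)$reject
  r2 <- bh_fdr(pv, q = 0.05)$reject
  r3 <- bh_fdr(pv, q = 0.20)$reject
  expect_true(all(r2[r1]) && all(r3[r2]))
})
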