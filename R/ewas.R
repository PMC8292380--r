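# Site-level differential-methylation analysis on bisulfite count data:
# CpG filtering, a per-site binomial mixed model with pedigree-derived
# relatedness covariance (penalized quasi-likelihood with a one-dimensional
# profile over the kinship variance), empirical-null correction of the
# resulting test statistics, and FDR calling.

#' Methylation count container
#'
#' Per-CpG, per-individual methylated and total read counts.
#'
#' @param meth integer matrix (sites x individuals) of methylated reads.
#' @param total integer matrix of total reads, same shape; `0 <= meth <=
#'   total` cell-wise (zero totals are permitted and handled by the coverage
#'   filter).
#' @param sites data frame with `chrom`, `pos` (0-based) and `site_id`
#'   matching the matrix rows.
#' @return object of class `meth_counts`.
#' @export
meth_counts <- function(meth, total, sites) {
  .assert(is.matrix(meth) && is.matrix(total) &&
            all(dim(meth) == dim(total)), "meth/total must be equal-shape matrices")
  .assert(nrow(sites) == nrow(meth), "sites must match matrix rows")
  .assert(all(c("chrom", "pos", "site_id") %in% names(sites)),
          "sites needs chrom, pos, site_id")
  .assert(all(meth >= 0) && all(total >= 0) && all(meth <= total),
          "need 0 <= methylated <= total at every cell")
  rownames(meth) <- rownames(total) <- sites$site_id
  out <- list(meth = meth, total = total, sites = sites,
              individuals = colnames(meth))
  class(out) <- "meth_counts"
  out
}

#' @export
print.meth_counts <- function(x, ...) {
  cat(sprintf("Methylation counts: %d sites x %d individuals (mean coverage %.1f)\n",
              nrow(x$meth), ncol(x$meth), mean(x$total)))
  invisible(x)
}

#' Subset a meth_counts object
#'
#' @param x a [meth_counts()] object.
#' @param sites optional site index/logical/id vector.
#' @param individuals optional individual index or id vector.
#' @return a `meth_counts` object.
#' @export
subset_meth <- function(x, sites = NULL, individuals = NULL) {
  .assert(inherits(x, "meth_counts"), "need a meth_counts object")
  si <- sites %||% seq_len(nrow(x$meth))
  if (is.character(si)) si <- match(si, x$sites$site_id)
  ii <- individuals %||% seq_len(ncol(x$meth))
  if (is.character(ii)) ii <- match(ii, x$individuals)
  .assert(!anyNA(si) && !anyNA(ii), "unknown site or individual ids")
  meth_counts(x$meth[si, , drop = FALSE][, ii, drop = FALSE],
              x$total[si, , drop = FALSE][, ii, drop = FALSE],
              x$sites[si, , drop = FALSE])
}

#' Filter CpG sites before the EWAS
#'
#' Three stages, applied in a fixed order: (1) coverage — drop any site with
#' fewer than `min_coverage` total reads in any individual; (2) mean bounds —
#' drop sites whose mean methylation fraction lies outside `mean_bounds`
#' (hyper- and hypomethylated sites carry little interindividual signal);
#' (3) variance — drop the `low_var_drop` fraction of surviving sites with
#' the lowest interindividual variance of methylation fractions (ties broken
#' by site order).  Counts removed at each stage are attached as attribute
#' `"filter_log"`.
#'
#' @param counts a [meth_counts()] object.
#' @param min_coverage minimum per-cell total reads.
#' @param mean_bounds keep sites with mean fraction strictly inside
#'   `(lower, upper)` boundaries inclusive of values within the bounds.
#' @param low_var_drop fraction of lowest-variance survivors to drop.
#' @return filtered `meth_counts` with a `"filter_log"` attribute.
#' @export
filter_cpgs <- function(counts, min_coverage = 10, mean_bounds = c(0.10, 0.90),
                        low_var_drop = 0.05) {
  .assert(inherits(counts, "meth_counts"), "need a meth_counts object")
  .assert(nrow(counts$meth) > 0, "counts is empty")
  n0 <- nrow(counts$meth)
  keep_cov <- rowSums(counts$total < min_coverage) == 0
  c1 <- subset_meth(counts, sites = which(keep_cov))
  n1 <- nrow(c1$meth)
  if (n1 == 0L) stop("all sites removed by the coverage filter", call. = FALSE)

  frac <- c1$meth / c1$total
  mean_f <- rowMeans(frac)
  keep_mean <- mean_f >= mean_bounds[1] & mean_f <= mean_bounds[2]
  c2 <- subset_meth(c1, sites = which(keep_mean))
  n2 <- nrow(c2$meth)
  if (n2 == 0L) stop("all sites removed by the mean-methylation filter",
                     call. = FALSE)

  v <- apply(c2$meth / c2$total, 1L, stats::var)
  k <- floor(low_var_drop * n2)
  drop_idx <- if (k > 0) order(v, seq_along(v))[seq_len(k)] else integer()
  c3 <- subset_meth(c2, sites = setdiff(seq_len(n2), drop_idx))
  n3 <- nrow(c3$meth)
  if (n3 == 0L) stop("all sites removed by the variance filter", call. = FALSE)

  attr(c3, "filter_log") <- data.frame(
    stage = c("input", "coverage", "mean_bounds", "low_variance"),
    removed = c(0L, n0 - n1, n1 - n2, n2 - n3),
    remaining = c(n0, n1, n2, n3))
  c3
}

# ---- per-site binomial mixed model (PQL with profiled kinship variance) ----

# Working-model GLS at fixed tau: V = diag(1/w) + tau K.
.pql_gls <- function(z, X, w, K, tau) {
  V <- tau * K
  diag(V) <- diag(V) + 1 / w
  Rv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(Rv)) return(NULL)
  A <- backsolve(Rv, X, transpose = TRUE)      # Rv^-T X
  zz <- backsolve(Rv, z, transpose = TRUE)
  XtViX <- crossprod(A)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  beta <- backsolve(Rx, backsolve(Rx, crossprod(A, zz), transpose = TRUE))
  r <- z - as.numeric(X %*% beta)
  Vinv_r <- backsolve(Rv, backsolve(Rv, r, transpose = TRUE))
  u <- if (tau > 0) tau * as.numeric(K %*% Vinv_r) else numeric(length(z))
  crit <- 2 * sum(log(diag(Rv))) + 2 * sum(log(diag(Rx))) + sum(r * Vinv_r)
  list(beta = as.numeric(beta), u = u, crit = crit,
       cov_beta = chol2inv(Rx), eta = as.numeric(X %*% beta) + u)
}

.pql_profile_tau <- function(z, X, w, K) {
  f <- function(logtau) {
    g <- .pql_gls(z, X, w, K, exp(logtau))
    if (is.null(g)) Inf else g$crit
  }
  g0 <- .pql_gls(z, X, w, K, 0)
  c0 <- if (is.null(g0)) Inf else g0$crit
  opt <- tryCatch(stats::optimize(f, interval = c(-8, 3), tol = 1e-4),
                  error = function(e) NULL)
  if (!is.null(opt) && opt$objective < c0 - 1e-9) exp(opt$minimum) else 0
}

# Beta-binomial maximum likelihood without kinship (boundary fallback).
.fit_betabinom <- function(y, m, X) {
  p <- ncol(X)
  g0 <- tryCatch(
    stats::glm.fit(X, cbind(y, m - y), family = stats::binomial()),
    error = function(e) NULL)
  start <- c(if (!is.null(g0)) g0$coefficients else rep(0, p),
             stats::qlogis(0.01))
  nll <- function(par) {
    beta <- par[seq_len(p)]
    rho <- stats::plogis(par[p + 1L])
    pr <- stats::plogis(pmin(pmax(as.numeric(X %*% beta), -30), 30))
    s <- (1 - rho) / rho
    a <- pr * s
    b <- (1 - pr) * s
    ll <- lchoose(m, y) + lbeta(y + a, m - y + b) - lbeta(a, b)
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }
  opt <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B",
                 lower = c(rep(-Inf, p), -15), upper = c(rep(Inf, p), 5),
                 hessian = TRUE),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  H <- opt$hessian[seq_len(p), seq_len(p), drop = FALSE]
  cov_beta <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov_beta)) return(NULL)
  list(beta = opt$par[seq_len(p)], cov_beta = cov_beta,
       rho = stats::plogis(opt$par[p + 1L]), converged = opt$convergence == 0)
}

#' Kinship-aware binomial mixed model for one CpG site
#'
#' Logit-scale model for methylated counts out of totals:
#' `logit(p_i) = b0 + b1 * exposure_i (+ b2 * age_i) + u_i`, with
#' `u ~ N(0, tau K)` where `K` is the pedigree relatedness matrix.  Fit by
#' penalized quasi-likelihood with the kinship variance `tau` profiled in
#' one dimension at each update.  When the profiled `tau` hits the zero
#' boundary the model falls back to a beta-binomial fit without kinship
#' (flagged), which absorbs residual overdispersion; with `tau` fixed at 0
#' the fit reduces exactly to ordinary logistic regression.
#'
#' @param methylated,totals integer count vectors over individuals.
#' @param exposure numeric explanatory variable (must vary).
#' @param age optional precision covariate (age in months).
#' @param kinship optional PSD relatedness matrix; identity when `NULL`.
#' @param tau fix the kinship variance instead of profiling (e.g. `tau = 0`
#'   for the plain logistic reduction).
#' @param boundary_fallback use the beta-binomial fallback at the boundary?
#' @param max_outer,tol PQL control.
#' @return list with `beta`, `se`, `p` (Wald, for the exposure), full
#'   coefficient vector `coef`, `tau`, `family`, `boundary`, `converged`.
#' @export
fit_site_model <- function(methylated, totals, exposure, age = NULL,
                           kinship = NULL, tau = NULL,
                           boundary_fallback = TRUE,
                           max_outer = 4, tol = 1e-5) {
  n <- length(methylated)
  .assert(length(totals) == n && length(exposure) == n,
          "methylated, totals and exposure must have equal length")
  .assert(all(totals >= 1), "all totals must be >= 1 (filter zero-coverage cells)")
  .assert(all(methylated >= 0 & methylated <= totals),
          "need 0 <= methylated <= totals")
  .assert(stats::sd(exposure) > 0, "exposure is constant: slope not identifiable")
  X <- cbind("(Intercept)" = 1, exposure = exposure)
  if (!is.null(age)) {
    .assert(length(age) == n, "age length mismatch")
    X <- cbind(X, age = age)
  }
  K <- kinship %||% diag(n)
  .assert(nrow(K) == n && ncol(K) == n, "kinship dimension mismatch")

  y <- methylated; m <- totals
  mu <- (y + 0.5) / (m + 1)
  eta <- stats::qlogis(mu)
  fixed_tau <- !is.null(tau)
  tau_hat <- if (fixed_tau) tau else 0.1
  beta_old <- rep(Inf, ncol(X))
  converged <- FALSE
  sol <- NULL
  for (outer in seq_len(max_outer)) {
    # inner IRLS rounds at the current tau
    for (inner in 1:3) {
      pr <- stats::plogis(eta)
      w <- pmax(m * pr * (1 - pr), 1e-8)
      z <- eta + (y - m * pr) / w
      s <- .pql_gls(z, X, w, K, tau_hat)
      if (is.null(s)) {
        return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                    coef = rep(NA_real_, ncol(X)), tau = tau_hat,
                    family = "binomial_pql", boundary = FALSE,
                    converged = FALSE))
      }
      sol <- s
      eta <- pmin(pmax(sol$eta, -30), 30)
    }
    if (!fixed_tau) {
      pr <- stats::plogis(eta)
      w <- pmax(m * pr * (1 - pr), 1e-8)
      z <- eta + (y - m * pr) / w
      tau_hat <- .pql_profile_tau(z, X, w, K)
    }
    if (max(abs(sol$beta - beta_old)) < tol) { converged <- TRUE; break }
    beta_old <- sol$beta
  }
  if (!converged && max(abs(sol$beta - beta_old)) < 1e-2) converged <- TRUE

  boundary <- !fixed_tau && tau_hat <= 1e-6
  if (boundary && boundary_fallback) {
    bb <- .fit_betabinom(y, m, X)
    if (!is.null(bb)) {
      se <- sqrt(pmax(diag(bb$cov_beta), 0))
      zv <- unname(bb$beta[2L]) / se[2L]
      return(list(beta = unname(bb$beta[2L]), se = unname(se[2L]),
                  p = 2 * stats::pnorm(-abs(zv)),
                  coef = stats::setNames(bb$beta, colnames(X)),
                  tau = 0, family = "betabinomial", boundary = TRUE,
                  converged = bb$converged))
    }
  }
  se <- sqrt(pmax(diag(sol$cov_beta), 0))
  zv <- sol$beta[2L] / se[2L]
  list(beta = sol$beta[2L], se = se[2L], p = 2 * stats::pnorm(-abs(zv)),
       coef = stats::setNames(sol$beta, colnames(X)),
       tau = tau_hat, family = "binomial_pql", boundary = boundary,
       converged = converged)
}

# ---- empirical null ----

.tnm_loglik <- function(z, par) {
  d <- par$pi[1] * stats::dnorm(z, par$mu[1], par$sd[1]) +
    par$pi[2] * stats::dnorm(z, par$mu[2], par$sd[2]) +
    par$pi[3] * stats::dnorm(z, par$mu[3], par$sd[3])
  sum(log(pmax(d, 1e-300)))
}

# Constrained EM: component 1 = central null, 2 = left alternative,
# 3 = right alternative.  Side means are kept at least delta_min away from
# the null mean and side SDs at least the null SD, so that with no signal
# the side components cannot eat the null's tails.
.tnm_em <- function(z, init, delta_min, max_iter, tol) {
  par <- init
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- cbind(par$pi[1] * stats::dnorm(z, par$mu[1], par$sd[1]),
               par$pi[2] * stats::dnorm(z, par$mu[2], par$sd[2]),
               par$pi[3] * stats::dnorm(z, par$mu[3], par$sd[3]))
    rs <- pmax(rowSums(D), 1e-300)
    G <- D / rs
    w <- colSums(G)
    pi_new <- w / length(z)
    mu0 <- sum(G[, 1] * z) / w[1]
    sd0 <- sqrt(pmax(sum(G[, 1] * (z - mu0)^2) / w[1], 1e-4))
    mul <- min(sum(G[, 2] * z) / max(w[2], 1e-12), mu0 - delta_min)
    mur <- max(sum(G[, 3] * z) / max(w[3], 1e-12), mu0 + delta_min)
    sdl <- sqrt(pmax(sum(G[, 2] * (z - mul)^2) / max(w[2], 1e-12), sd0^2))
    sdr <- sqrt(pmax(sum(G[, 3] * (z - mur)^2) / max(w[3], 1e-12), sd0^2))
    par <- list(pi = pi_new, mu = c(mu0, mul, mur), sd = c(sd0, sdl, sdr))
    ll <- .tnm_loglik(z, par)
    # EM near a weight boundary creeps geometrically; an absolute
    # per-iteration log-likelihood increment is the practical stop rule
    if (it > 5 && is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(par = par, loglik = ll_old, converged = converged, n_iter = it)
}

#' Estimate bias and inflation of test statistics from an empirical null
#'
#' Fits a three-component normal mixture to a vector of z-scores by
#' expectation-maximization: a central null component `N(bias, inflation^2)`
#' flanked by one left and one right alternative component.  The null
#' component is constrained to carry the largest weight; side components are
#' kept away from the null mean and at least as wide as the null, so pure
#' noise is absorbed by the null component.  Initialization is
#' method-of-moments (median/MAD) plus `n_restarts` jittered restarts;
#' deterministic given `seed`.
#'
#' @param z_scores numeric z statistics (>= 500 recommended; warns below).
#' @param delta_min minimum separation of alternative means from the null
#'   mean (z units).
#' @param n_restarts number of jittered EM restarts.
#' @param max_iter,tol EM control.
#' @param seed seed for the restart jitter.
#' @return object of class `empirical_null` with `bias`, `inflation`,
#'   `null_proportion`, full mixture parameters, `loglik`, `converged`.
#' @export
estimate_empirical_null <- function(z_scores, delta_min = 2,
                                    n_restarts = 10, max_iter = 2000,
                                    tol = 1e-3, seed = 1L) {
  z <- z_scores[is.finite(z_scores)]
  .assert(length(z) >= 10, "need at least 10 finite z-scores")
  if (length(z) < 500) {
    warning("fewer than 500 z-scores; empirical-null estimates may be unstable",
            call. = FALSE)
  }
  m0 <- stats::median(z)
  s0 <- stats::mad(z)
  if (s0 <= 0) s0 <- stats::sd(z)
  inits <- list(list(pi = c(0.90, 0.05, 0.05),
                     mu = c(m0, m0 - max(delta_min, 2 * s0),
                            m0 + max(delta_min, 2 * s0)),
                     sd = c(s0, s0, s0)))
  .with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      p0 <- stats::runif(1, 0.6, 0.95)
      dl <- stats::runif(1, delta_min, 4)
      dr <- stats::runif(1, delta_min, 4)
      inits[[r + 1L]] <- list(
        pi = c(p0, (1 - p0) / 2, (1 - p0) / 2),
        mu = c(m0 + stats::rnorm(1, 0, 0.2 * s0), m0 - dl, m0 + dr),
        sd = c(s0 * stats::runif(1, 0.8, 1.2), s0, s0))
    }
    fits <- lapply(inits, function(ini)
      .tnm_em(z, ini, delta_min = delta_min, max_iter = max_iter, tol = tol))
    conv <- vapply(fits, `[[`, logical(1), "converged")
    if (!any(conv)) {
      trace <- vapply(fits, `[[`, numeric(1), "loglik")
      stop("empirical-null EM failed to converge in any restart; ",
           "log-likelihood trace: ", paste(round(trace, 2), collapse = ", "),
           call. = FALSE)
    }
    fits <- fits[conv]
    nullok <- vapply(fits, function(f)
      f$par$pi[1] >= max(f$par$pi[2:3]), logical(1))
    if (any(nullok)) fits <- fits[nullok]
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    out <- list(bias = best$par$mu[1], inflation = best$par$sd[1],
                null_proportion = best$par$pi[1],
                weights = best$par$pi, means = best$par$mu, sds = best$par$sd,
                loglik = best$loglik, converged = best$converged,
                n_iter = best$n_iter, n = length(z))
    class(out) <- "empirical_null"
    out
  })
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("Empirical null (3-component normal mixture, n = %d)\n", x$n))
  cat(sprintf("  bias = %.4f, inflation = %.4f, null proportion = %.3f\n",
              x$bias, x$inflation, x$null_proportion))
  invisible(x)
}

#' Correct per-site estimates for empirical-null bias and inflation
#'
#' Rescales z-scores as `z' = (beta/se - bias) / inflation`, with corrected
#' two-sided normal p-values and a consistent coefficient rescaling
#' (`beta' = beta - bias * se`, `se' = se * inflation`, so `beta'/se' = z'`).
#'
#' @param betas,ses raw per-site estimates and standard errors (`ses > 0`).
#' @param null_estimate an [estimate_empirical_null()] object (or any list
#'   with `bias` and `inflation`).
#' @return data frame `beta_corrected`, `se_corrected`, `z_corrected`,
#'   `p_corrected`.
#' @export
apply_null_correction <- function(betas, ses, null_estimate) {
  .assert(length(betas) == length(ses), "betas/ses length mismatch")
  .assert(all(ses > 0), "all standard errors must be > 0")
  .assert(is.numeric(null_estimate$inflation) && null_estimate$inflation > 0,
          "invalid null estimate")
  zc <- (betas / ses - null_estimate$bias) / null_estimate$inflation
  data.frame(beta_corrected = betas - null_estimate$bias * ses,
             se_corrected = ses * null_estimate$inflation,
             z_corrected = zc,
             p_corrected = 2 * stats::pnorm(-abs(zc)))
}

#' Run the count-based EWAS
#'
#' Pipeline for associating a per-individual stress phenotype (fGCM BLUPs)
#' with CpG methylation: filter sites ([filter_cpgs()]), fit the
#' kinship-aware binomial mixed model at every site ([fit_site_model()]),
#' estimate and apply the empirical-null bias/inflation correction, and call
#' differentially methylated sites (DMSs) at a Benjamini-Hochberg FDR on the
#' corrected p-values.  Sites that fail to converge are excluded from the
#' null estimation and carry `NA` calls.
#'
#' @param counts a [meth_counts()] object.
#' @param blups named numeric phenotype vector (names = individual ids
#'   matching `counts$individuals`).
#' @param age optional named age vector (months).
#' @param kinship optional relatedness matrix with matching dimnames.
#' @param fdr FDR level for DMS calls.
#' @param min_coverage,mean_bounds,low_var_drop passed to [filter_cpgs()].
#' @param null_seed seed for the empirical-null EM restarts.
#' @return data frame of class `ewas_result` with per-site raw and corrected
#'   estimates, `q_bh` and `is_dms`; stage counts in attribute
#'   `"stage_log"`, the null fit in attribute `"null_estimate"`.
#' @export
run_ewas <- function(counts, blups, age = NULL, kinship = NULL, fdr = 0.05,
                     min_coverage = 10, mean_bounds = c(0.10, 0.90),
                     low_var_drop = 0.05, null_seed = 1L) {
  .assert(inherits(counts, "meth_counts"), "need a meth_counts object")
  ids <- counts$individuals
  .assert(!is.null(names(blups)) && all(ids %in% names(blups)),
          "blups must be named and cover all individuals in counts")
  x <- as.numeric(blups[ids])
  a <- if (!is.null(age)) {
    .assert(all(ids %in% names(age)), "age must be named and cover individuals")
    as.numeric(age[ids])
  } else NULL
  K <- if (!is.null(kinship)) {
    .assert(all(ids %in% rownames(kinship)), "kinship must cover individuals")
    kinship[ids, ids]
  } else NULL

  fc <- filter_cpgs(counts, min_coverage = min_coverage,
                    mean_bounds = mean_bounds, low_var_drop = low_var_drop)
  S <- nrow(fc$meth)
  fits <- vector("list", S)
  for (s in seq_len(S)) {
    fits[[s]] <- tryCatch(
      fit_site_model(fc$meth[s, ], fc$total[s, ], x, age = a, kinship = K),
      error = function(e) list(beta = NA_real_, se = NA_real_, p = NA_real_,
                               tau = NA_real_, family = "failed",
                               boundary = FALSE, converged = FALSE))
  }
  res <- data.frame(
    site_id = fc$sites$site_id, chrom = fc$sites$chrom, pos = fc$sites$pos,
    beta_raw = vapply(fits, `[[`, numeric(1), "beta"),
    se_raw = vapply(fits, `[[`, numeric(1), "se"),
    p_raw = vapply(fits, `[[`, numeric(1), "p"),
    tau = vapply(fits, `[[`, numeric(1), "tau"),
    family = vapply(fits, `[[`, character(1), "family"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  usable <- res$converged & is.finite(res$beta_raw) & is.finite(res$se_raw) &
    res$se_raw > 0
  .assert(sum(usable) >= 10, "too few converged site models")

  nullfit <- estimate_empirical_null(res$beta_raw[usable] / res$se_raw[usable],
                                     seed = null_seed)
  corr <- apply_null_correction(res$beta_raw[usable], res$se_raw[usable],
                                nullfit)
  res$beta_corrected <- res$se_corrected <- res$p_corrected <- NA_real_
  res$beta_corrected[usable] <- corr$beta_corrected
  res$se_corrected[usable] <- corr$se_corrected
  res$p_corrected[usable] <- corr$p_corrected
  res$q_bh <- NA_real_
  bh <- bh_fdr(res$p_corrected[usable], q = fdr)
  res$q_bh[usable] <- bh$q_bh
  res$is_dms <- NA
  res$is_dms[usable] <- bh$reject

  flog <- attr(fc, "filter_log")
  attr(res, "stage_log") <- rbind(
    flog,
    data.frame(stage = c("fitted", "corrected"),
               removed = c(S - sum(usable), 0L),
               remaining = c(sum(usable), sum(usable))))
  attr(res, "null_estimate") <- nullfit
  class(res) <- c("ewas_result", "data.frame")
  res
}
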