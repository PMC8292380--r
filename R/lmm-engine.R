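# Internal profiled-REML engine for linear mixed models with a single random
# intercept, y = X beta + Z b + e, b ~ N(0, sigma_b^2 I) over one grouping
# factor.  The variance ratio lambda = sigma_b^2 / sigma_e^2 is profiled in one
# dimension; for a fixed lambda the marginal precision is block diagonal, so
# every quantity needed by REML reduces to per-cluster sufficient statistics
# (cluster sizes, cluster sums of X and y, and cluster cross products).  That
# makes a single fit O(G p^2) per criterion evaluation and, crucially, makes a
# cluster-bootstrap refit a re-aggregation of precomputed per-cluster
# statistics rather than a pass over the raw data.

# Build design, response and grouping from a fixed-effects formula.
# Complete-case: rows with NA in any model variable or the group are dropped
# and the count recorded.
.lmm_design <- function(formula, data, group) {
  .assert(is.character(group) && length(group) == 1L && group %in% names(data),
          "`group` must name a column of `data`")
  vars <- unique(c(all.vars(formula), group))
  missing_vars <- setdiff(vars, names(data))
  .assert(length(missing_vars) == 0L,
          paste0("variables not found in data: ", paste(missing_vars, collapse = ", ")))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  n_excluded <- sum(!cc)
  data <- data[cc, , drop = FALSE]
  .assert(nrow(data) > 0L, "no complete cases left")
  mf <- stats::model.frame(formula, data = data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- factor(data[[group]])
  .assert(nlevels(g) >= 2L, "need at least 2 grouping-factor levels")
  # rank check with named collinear columns
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(X = X, y = y, g = g, n_excluded = n_excluded, formula = formula, group = group)
}

# Per-cluster sufficient statistics.
.lmm_group_stats <- function(X, y, g) {
  p <- ncol(X)
  XX <- X[, rep(seq_len(p), times = p), drop = FALSE] *
        X[, rep(seq_len(p), each  = p), drop = FALSE]
  list(
    p     = p,
    terms = colnames(X),
    G     = nlevels(g),
    XtX_g = rowsum(XX, g),              # G x p^2
    Xty_g = rowsum(X * y, g),           # G x p
    yty_g = rowsum(y * y, g)[, 1L],
    S     = rowsum(X, g),               # G x p   cluster column sums
    sy    = rowsum(y, g)[, 1L],
    n_g   = as.vector(table(g)),
    levels = levels(g)
  )
}

# Aggregate sufficient statistics over a cluster index vector (with
# replacement for the bootstrap; each sampled cluster counts as its own
# cluster in the random-intercept structure).
.lmm_aggregate <- function(gs, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(gs$G)
  p <- gs$p
  list(
    p   = p,
    XtX = matrix(colSums(gs$XtX_g[idx, , drop = FALSE]), p, p),
    Xty = colSums(gs$Xty_g[idx, , drop = FALSE]),
    yty = sum(gs$yty_g[idx]),
    S   = gs$S[idx, , drop = FALSE],
    sy  = gs$sy[idx],
    n_g = gs$n_g[idx]
  )
}

# Minus twice the profiled REML log likelihood (up to an additive constant)
# at variance ratio `lam`, plus the GLS solution at that lam.
.lmm_crit <- function(agg, lam) {
  N <- sum(agg$n_g)
  p <- agg$p
  ci <- if (lam <= 0) numeric(length(agg$n_g)) else lam / (1 + agg$n_g * lam)
  A <- agg$XtX - crossprod(agg$S, agg$S * ci)
  b <- agg$Xty - colSums(agg$S * (ci * agg$sy))
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(ok = FALSE, crit = Inf))
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  rWr <- max(agg$yty - sum(ci * agg$sy^2) - sum(b * beta), 0)
  crit <- (N - p) * log(max(rWr, .Machine$double.xmin)) +
    sum(log1p(agg$n_g * lam)) + 2 * sum(log(diag(R)))
  list(ok = TRUE, crit = crit, beta = beta, R = R, rWr = rWr, ci = ci,
       lam = lam, N = N, p = p)
}

# Fit from aggregated statistics.  Returns NULL when the design collapses
# (e.g. a bootstrap resample in which a covariate is constant).
.lmm_fit_agg <- function(agg) {
  f0 <- .lmm_crit(agg, 0)
  obj <- function(loglam) .lmm_crit(agg, exp(loglam))$crit
  opt <- tryCatch(stats::optimize(obj, interval = c(-10, 10), tol = 1e-7),
                  error = function(e) NULL)
  best <- f0
  if (!is.null(opt) && is.finite(opt$objective) && opt$objective < f0$crit - 1e-9) {
    best <- .lmm_crit(agg, exp(opt$minimum))
  }
  if (!best$ok || is.null(best$beta) || anyNA(best$beta)) return(NULL)
  sigma_e2 <- best$rWr / (best$N - best$p)
  sigma_b2 <- best$lam * sigma_e2
  cov_beta <- sigma_e2 * chol2inv(best$R)
  reml_dev <- best$crit + (best$N - best$p) * (1 + log(2 * pi / (best$N - best$p)))
  list(beta = as.numeric(best$beta), cov_beta = cov_beta,
       se = sqrt(pmax(diag(cov_beta), 0)),
       sigma_e2 = sigma_e2, sigma_b2 = sigma_b2, lambda = best$lam,
       logLik_reml = -0.5 * reml_dev, N = best$N, p = best$p,
       ci = best$ci)
}

# Empirical BLUPs of the cluster intercepts given a fitted engine object:
# shrinkage n_i lambda / (1 + n_i lambda) applied to cluster mean residuals.
.lmm_blups <- function(fit, gs) {
  resid_sum <- gs$sy - as.vector(gs$S %*% fit$beta)
  blup <- fit$ci * resid_sum   # lambda/(1 + n_g lambda) * sum of residuals
  stats::setNames(blup, gs$levels)
}
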