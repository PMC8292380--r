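# Independent oracles and small fixture builders used across test files.

# Build an assoc_network object directly from a weight matrix.
net_from_adj <- function(adj, nodes = paste0("n", seq_len(nrow(adj)))) {
  dimnames(adj) <- list(nodes, nodes)
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  structure(list(nodes = nodes,
                 edges = data.frame(a = nodes[ut[, 1L]], b = nodes[ut[, 2L]],
                                    weight = adj[ut],
                                    stringsAsFactors = FALSE),
                 adj = adj, n_sessions = 0L),
            class = "assoc_network")
}

# Brute-force network metrics by exhaustive enumeration of simple paths.
# Degree/strength read straight off the matrix; betweenness sums, over all
# source-target pairs, the fraction of minimum-distance simple paths
# (distance = 1/weight) that pass through each intermediate node, then
# normalizes by (n-1)(n-2)/2.
bf_network_metrics <- function(adj, tol = 1e-9) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1 / adj, NA_real_)
  btw <- rep(0, n)
  if (n >= 3) {
    paths_between <- function(s, t) {
      out <- list()
      visit <- function(path, len) {
        last <- path[length(path)]
        if (last == t) {
          out[[length(out) + 1L]] <<- list(path = path, len = len)
          return(invisible())
        }
        for (v in seq_len(n)) {
          if (!is.na(d[last, v]) && !(v %in% path)) {
            visit(c(path, v), len + d[last, v])
          }
        }
      }
      visit(s, 0)
      out
    }
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        ps <- paths_between(s, t)
        if (!length(ps)) next
        lens <- vapply(ps, `[[`, numeric(1), "len")
        sh <- ps[lens <= min(lens) + tol]
        mids <- setdiff(seq_len(n), c(s, t))
        for (v in mids) {
          btw[v] <- btw[v] +
            mean(vapply(sh, function(p) v %in% p$path, logical(1)))
        }
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  list(degree = as.integer(colSums(adj > 0)), strength = colSums(adj),
       betweenness = btw)
}

# Random connected-ish weighted graph on n nodes; continuous weights avoid
# accidental shortest-path ties.
random_graph <- function(n, p_edge = 0.6) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p_edge) {
        adj[i, j] <- adj[j, i] <- stats::runif(1, 0.1, 1)
      }
    }
  }
  adj
}

# Independent Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k q / m and reject the k smallest p-values.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  reject <- rep(FALSE, m)
  if (is.finite(k) && k >= 1) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Synthetic mediation chain: X per individual, mediator M, repeated outcome
# Y with an individual random intercept.  `kind` selects a fully mediated
# chain (no direct effect), a global null, or an independent mediator.
make_mediation_data <- function(n = 60, reps = 3, kind = c("full", "null",
                                                           "indep_m"),
                                seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  X <- stats::rnorm(n)
  M <- switch(kind,
              full = 0.8 * X + stats::rnorm(n, 0, 0.6),
              null = stats::rnorm(n),
              indep_m = stats::rnorm(n))
  b <- stats::rnorm(n, 0, 0.3)
  y_mu <- switch(kind,
                 full = 0.5 * M,
                 null = rep(0, n),
                 indep_m = 0.4 * X)
  ind <- data.frame(id = sprintf("i%03d", seq_len(n)), x = X, ccgg = M,
                    mother_id = sprintf("m%03d", rep(seq_len(ceiling(n / 2)),
                                                     each = 2)[seq_len(n)]),
                    stringsAsFactors = FALSE)
  sam <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = ind$id[i],
               log_fgcm = y_mu[i] + b[i] + stats::rnorm(reps, 0, 0.5),
               stringsAsFactors = FALSE)
  }))
  list(individuals = ind, samples = sam)
}

# Minimal meth_counts builder from explicit matrices.
make_counts <- function(meth, total) {
  S <- nrow(meth)
  sites <- data.frame(chrom = "scaffold_1", pos = seq_len(S) * 100L,
                      site_id = paste0("scaffold_1:", seq_len(S) * 100L),
                      stringsAsFactors = FALSE)
  colnames(meth) <- colnames(total) <-
    colnames(meth) %||% sprintf("i%02d", seq_len(ncol(meth)))
  socmethyl::meth_counts(meth, total, sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small kinship + individuals setup for EWAS simulations.
ewas_sim_inputs <- function(n = 25, seed = 1) {
  cfg <- sim_config(n_mothers = ceiling(n / 2), offspring_per_mother = 2,
                    seed = seed)
  ped <- simulate_pedigree(cfg)
  ids <- ped$pedigree$individual_id[!is.na(ped$pedigree$mother_id)][seq_len(n)]
  set.seed(seed + 5000)
  list(ids = ids, kinship = ped$kinship[ids, ids],
       x = stats::setNames(stats::rnorm(n), ids),
       age = stats::setNames(stats::runif(n, 11, 27), ids))
}
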