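# Exposure construction from raw observation records: maternal-care
# proportions out of focal animal surveys (FAS), matched developmental
# windows, and association networks with per-individual centrality metrics.

#' Maternal-care proportions from focal animal survey records
#'
#' Summarizes per-minute care indicators into per-cub proportions.  A session
#' qualifies only when the mother-cub pair was co-observed for at least
#' `min_minutes` minutes, the cub was younger than `max_cub_age_months`
#' months, and the mother was lactating; non-qualifying sessions contribute
#' nothing.  Proportions are pooled over qualifying sessions: summed behavior
#' minutes divided by summed minutes co-observed.  The three behaviors
#' (close proximity within 1 m, nursing, grooming) are the classic FAS care
#' metrics; nursing and grooming occur within close proximity, so their
#' minutes can never exceed the close-proximity minutes.
#'
#' @param fas data frame with columns `cub_id`, `minutes_together`,
#'   `minutes_close`, `minutes_nursing`, `minutes_grooming`,
#'   `cub_age_months`, `mother_lactating`.
#' @param max_cub_age_months cubs at or beyond this age are excluded.
#' @param min_minutes minimum minutes co-observed for a session to qualify.
#' @return data frame with one row per cub that had qualifying observation
#'   time: `cub_id`, `prop_close_proximity`, `prop_nursing`,
#'   `prop_grooming`, `minutes_observed`, `n_sessions`.  Cubs with zero
#'   qualifying minutes are excluded; their ids are attached as attribute
#'   `"excluded"`.
#' @export
maternal_care_proportions <- function(fas, max_cub_age_months = 13,
                                      min_minutes = 5) {
  need <- c("cub_id", "minutes_together", "minutes_close", "minutes_nursing",
            "minutes_grooming", "cub_age_months", "mother_lactating")
  .assert(all(need %in% names(fas)),
          paste0("fas must contain: ", paste(need, collapse = ", ")))
  ok <- fas$minutes_together >= min_minutes &
    fas$cub_age_months < max_cub_age_months &
    as.logical(fas$mother_lactating)
  all_cubs <- unique(fas$cub_id)
  q <- fas[ok, , drop = FALSE]
  if (nrow(q) == 0L) {
    res <- data.frame(cub_id = character(), prop_close_proximity = numeric(),
                      prop_nursing = numeric(), prop_grooming = numeric(),
                      minutes_observed = numeric(), n_sessions = integer())
    attr(res, "excluded") <- all_cubs
    return(res)
  }
  f <- factor(q$cub_id)
  tot <- rowsum(q$minutes_together, f)[, 1L]
  res <- data.frame(
    cub_id = levels(f),
    prop_close_proximity = rowsum(q$minutes_close, f)[, 1L] / tot,
    prop_nursing = rowsum(q$minutes_nursing, f)[, 1L] / tot,
    prop_grooming = rowsum(q$minutes_grooming, f)[, 1L] / tot,
    minutes_observed = tot,
    n_sessions = as.integer(table(f)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "excluded") <- setdiff(all_cubs, res$cub_id)
  res
}

#' Matched communal-den and den-independent developmental windows
#'
#' The den-independent (DI) window starts the day after the communal-den (CD)
#' window ends and spans exactly the CD duration, so the two windows are
#' duration-matched at day resolution.  Both windows are inclusive of their
#' endpoints.
#'
#' @param cd_start,cd_end CD window dates (coerced with [as.Date()]);
#'   vectorized, `cd_end` must be strictly after `cd_start`.
#' @param individual_id optional id(s) carried through to the output.
#' @return data frame with columns `individual_id`, `label` (`"CD"`/`"DI"`),
#'   `start`, `end`.
#' @export
define_windows <- function(cd_start, cd_end, individual_id = NA_character_) {
  cd_start <- as.Date(cd_start)
  cd_end <- as.Date(cd_end)
  .assert(length(cd_start) == length(cd_end), "date vectors differ in length")
  .assert(all(cd_end > cd_start), "cd_end must be after cd_start")
  dur <- as.integer(cd_end - cd_start)
  di_start <- cd_end + 1L
  di_end <- di_start + dur
  n <- length(cd_start)
  id <- rep_len(individual_id, n)
  data.frame(
    individual_id = rep(id, 2L),
    label = rep(c("CD", "DI"), each = n),
    start = c(cd_start, di_start),
    end = c(cd_end, di_end),
    row.names = NULL
  )
}

#' Simple ratio association index
#'
#' `x / (x + y_a + y_b)`: sessions in which two individuals co-occurred over
#' sessions in which at least one of them was seen.  The default edge weight
#' of the association-network literature; lies in `[0, 1]`.
#'
#' @param n_together sessions with both present.
#' @param n_a_only,n_b_only sessions with only one of the pair present.
#' @return association index in `[0, 1]`; vectorized.
#' @export
association_index <- function(n_together, n_a_only, n_b_only) {
  .assert(all(n_together >= 0) && all(n_a_only >= 0) && all(n_b_only >= 0),
          "counts must be non-negative")
  denom <- n_together + n_a_only + n_b_only
  .assert(all(denom > 0),
          "association index undefined when all counts are zero")
  n_together / denom
}

#' Build an association network from co-occurrence sessions in a window
#'
#' Nodes are individuals observed in at least one session inside the window;
#' edge weights are simple ratio association indices over window sessions;
#' pairs never seen together carry no edge.  The result is independent of
#' session order.
#'
#' @param sessions long-format data frame with columns `session_id`, `date`,
#'   `id` (one row per individual per session).
#' @param window list or one-row data frame with `start` and `end` dates
#'   (inclusive).
#' @return object of class `assoc_network`: `nodes`, `edges` (`a`, `b`,
#'   `weight`), adjacency matrix `adj`, and `n_sessions`.
#' @export
build_network <- function(sessions, window) {
  .assert(all(c("session_id", "date", "id") %in% names(sessions)),
          "sessions must have session_id, date, id")
  start <- as.Date(window$start)
  end <- as.Date(window$end)
  .assert(length(start) == 1L && length(end) == 1L && end >= start,
          "window must have scalar start <= end")
  d <- as.Date(sessions$date)
  s <- sessions[d >= start & d <= end, , drop = FALSE]
  s <- unique(s[, c("session_id", "id")])
  if (nrow(s) == 0L) {
    warning("no sessions fall inside the window; returning empty network",
            call. = FALSE)
    net <- list(nodes = character(),
                edges = data.frame(a = character(), b = character(),
                                   weight = numeric()),
                adj = matrix(numeric(), 0, 0), n_sessions = 0L)
    class(net) <- "assoc_network"
    return(net)
  }
  inc <- table(s$session_id, s$id) > 0
  inc <- matrix(as.numeric(inc), nrow(inc), ncol(inc),
                dimnames = dimnames(inc))
  together <- crossprod(inc)              # pairwise co-occurrence counts
  seen <- diag(together)                  # per-id session counts
  denom <- outer(seen, seen, "+") - together
  adj <- together / denom
  diag(adj) <- 0
  adj[together == 0] <- 0                 # zero-weight pairs carry no edge
  nodes <- colnames(inc)
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(a = nodes[ut[, 1L]], b = nodes[ut[, 2L]],
                      weight = adj[ut], stringsAsFactors = FALSE)
  net <- list(nodes = nodes, edges = edges, adj = adj,
              n_sessions = nrow(inc))
  class(net) <- "assoc_network"
  net
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("Association network: %d nodes, %d edges, %d sessions\n",
              length(x$nodes), nrow(x$edges), x$n_sessions))
  invisible(x)
}

#' Individual centrality metrics from an association network
#'
#' Degree is the unweighted count of associates (nonzero-weight neighbors);
#' strength is the sum of incident edge weights; betweenness is weighted
#' shortest-path betweenness with edge distance `1/weight` (stronger
#' association = shorter path), ties among equal-length paths split evenly,
#' normalized by `(n-1)(n-2)/2` so it lies in `[0, 1]`.  Isolated nodes get
#' `(0, 0, 0)`; with fewer than 3 nodes betweenness is 0 by convention.
#'
#' @param network an [build_network()] object.
#' @param focal_id optional: restrict output to one individual (error if not
#'   a node).
#' @return data frame `individual_id`, `degree`, `strength`, `betweenness`.
#' @export
network_metrics <- function(network, focal_id = NULL) {
  .assert(inherits(network, "assoc_network"), "need an assoc_network")
  nodes <- network$nodes
  if (!is.null(focal_id)) {
    .assert(focal_id %in% nodes,
            paste0("focal individual not in network: ", focal_id))
  }
  n <- length(nodes)
  if (n == 0L) {
    return(data.frame(individual_id = character(), degree = integer(),
                      strength = numeric(), betweenness = numeric()))
  }
  adj <- network$adj
  degree <- as.integer(colSums(adj > 0))
  strength <- colSums(adj)
  betw <- rep(0, n)
  if (n >= 3L && nrow(network$edges) > 0L) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = nodes)
    raw <- igraph::betweenness(g, directed = FALSE,
                               weights = 1 / network$edges$weight)
    betw <- as.numeric(raw[nodes]) / ((n - 1) * (n - 2) / 2)
  }
  out <- data.frame(individual_id = nodes, degree = degree,
                    strength = strength, betweenness = betw,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(focal_id)) out <- out[out$individual_id == focal_id, ]
  rownames(out) <- NULL
  out
}

#' Window-specific network metrics for a cohort
#'
#' Builds one association network per individual per developmental window
#' (each individual's own CD/DI dates) and extracts that individual's
#' metrics.  Individuals never observed inside a window get `NA` metrics,
#' mirroring the varying analytical sample sizes of field data.
#'
#' @param sessions long-format session data frame (see [build_network()]).
#' @param windows data frame from [define_windows()] with real
#'   `individual_id`s.
#' @return data frame `individual_id`, `label`, `degree`, `strength`,
#'   `betweenness`.
#' @export
window_network_metrics <- function(sessions, windows) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    net <- suppressWarnings(build_network(sessions, w))
    if (w$individual_id %in% net$nodes) {
      m <- network_metrics(net, focal_id = w$individual_id)
      data.frame(individual_id = w$individual_id, label = w$label,
                 degree = m$degree, strength = m$strength,
                 betweenness = m$betweenness, stringsAsFactors = FALSE)
    } else {
      data.frame(individual_id = w$individual_id, label = w$label,
                 degree = NA_integer_, strength = NA_real_,
                 betweenness = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
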