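#' Distance-weighted gene network
#'
#' Container for an undirected, positively weighted graph G = (V, E, W) in
#' which edge weights are distances (typically reciprocal mutual
#' information).  Nodes with no incident edge are kept in V: the network
#' size N always counts every gene.
#'
#' @param nodes character vector of node identifiers (unique).
#' @param edges data frame with columns `source`, `target`, `weight`; one row
#'   per undirected edge, no self-loops, weights positive and finite.
#' @param threshold optional similarity threshold the network was built at.
#' @return object of class `distance_network`.
#' @export
distance_network <- function(nodes, edges, threshold = NA_real_) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (!all(c("source", "target", "weight") %in% names(edges)))
    stop("`edges` must have columns source, target, weight")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (nrow(edges)) {
    if (!all(edges$source %in% nodes) || !all(edges$target %in% nodes))
      stop("edge endpoints must be listed in `nodes`")
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be positive and finite")
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "distance_network")
}

#' @export
print.distance_network <- function(x, ...) {
  cat(sprintf("distance_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "distance_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "weight")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Weighted betweenness-centrality load
#'
#' For every node v, the load g(v) is the sum over unordered node pairs
#' \{s, t\} (s, t distinct from v) of the fraction of minimum-distance paths
#' between s and t that pass through v.  Pairs in different components
#' contribute nothing; endpoints are excluded; values are unnormalized.
#'
#' @param net a [distance_network()].
#' @return named numeric vector of loads over all nodes (isolated nodes get
#'   load 0).
#' @export
weighted_betweenness <- function(net) {
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  if (length(w) && any(w < 0)) stop("negative edge weights")
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = if (length(w)) w else NULL)
  stats::setNames(as.numeric(b), igraph::V(g)$name)[net$nodes]
}

#' Fixed node capacities proportional to initial load
#'
#' C_j = (1 + alpha) L_j, where alpha >= 0 is the tolerance parameter.
#' Capacities are computed once, from the intact network, and are never
#' updated while a cascade runs.
#'
#' @param loads named numeric vector of initial loads (betweenness).
#' @param alpha tolerance parameter, >= 0 (default 0).
#' @return object of class `load_profile` with elements `load`, `capacity`,
#'   `alpha`.
#' @export
initial_capacities <- function(loads, alpha = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single value >= 0")
  if (any(loads < 0)) stop("loads must be non-negative")
  structure(list(load = loads, capacity = (1 + alpha) * loads, alpha = alpha),
            class = "load_profile")
}

# Shared cascade kernel.  g: igraph of the intact network; cap: capacity
# vector indexed by vertex; iso0: nodes isolated in the intact network
# (excluded from the isolation failure criterion -- only nodes that BECOME
# isolated during a cascade fail by isolation).  Failure is strict
# (load > capacity), with a small relative tolerance guarding recomputed
# floating-point loads.
cascade_kernel <- function(g, cap, iso0, seed_idx, tol = 1e-9) {
  n <- igraph::vcount(g)
  alive <- setdiff(seq_len(n), seed_idx)
  rounds <- list(seed_idx)
  repeat {
    if (!length(alive)) break
    sg <- igraph::induced_subgraph(g, alive)
    deg <- igraph::degree(sg)
    if (any(deg > 0)) {
      w <- igraph::E(sg)$weight
      ld <- igraph::betweenness(sg, directed = FALSE, weights = w)
    } else {
      ld <- numeric(length(alive))
    }
    over <- ld > cap[alive] + tol * pmax(1, cap[alive])
    iso <- deg == 0 & !iso0[alive]
    newly <- alive[over | iso]
    if (!length(newly)) break
    rounds[[length(rounds) + 1L]] <- newly
    alive <- setdiff(alive, newly)
  }
  list(rounds = rounds, failed = sort(unlist(rounds)), alive = alive)
}

#' Simulate one cascading failure seeded at a single node
#'
#' The seed node and its incident edges are removed; loads are recomputed on
#' the surviving subgraph; every surviving node whose new load strictly
#' exceeds its fixed capacity fails, as does every surviving node left with
#' no incident edge (isolation criterion); failed nodes are removed and the
#' process iterates until no further node fails.  Nodes that were already
#' isolated in the intact network never fail by isolation and, as seeds,
#' produce a cascade of size 1.
#'
#' @param net a [distance_network()].
#' @param profile a [initial_capacities()] profile computed on `net`.
#' @param seed node identifier to remove first.
#' @return object of class `cascade_event`: list with `seed`, `rounds`
#'   (list of character vectors, disjoint), `failed` (includes the seed),
#'   `s` (= number failed) and `d` (= s / N).
#' @export
cascade_from_node <- function(net, profile, seed) {
  stopifnot(inherits(net, "distance_network"),
            inherits(profile, "load_profile"))
  if (!seed %in% net$nodes) stop(sprintf("seed node '%s' not in network", seed))
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  cap <- profile$capacity[nm]
  iso0 <- igraph::degree(g) == 0
  k <- cascade_kernel(g, cap, iso0, match(seed, nm))
  N <- length(net$nodes)
  structure(list(seed = seed,
                 rounds = lapply(k$rounds, function(i) nm[i]),
                 failed = nm[k$failed],
                 s = length(k$failed),
                 d = length(k$failed) / N),
            class = "cascade_event")
}

#' Cascading failures from every seed node
#'
#' Runs [cascade_from_node()] for every node of the network against the same
#' intact-network capacities, and summarises robustness as
#' P (fraction of seeds whose size-ratio d_i reaches the collapse threshold
#' `t_cf`, inclusive) and R (mean size-ratio).
#'
#' @param net a [distance_network()].
#' @param alpha tolerance parameter (default 0).
#' @param t_cf collapse threshold on the size-ratio (default 0.5).
#' @param keep_events if TRUE, the per-seed `cascade_event`s are retained.
#' @return object of class `cascade_result`: list with `N`, `alpha`, `t_cf`,
#'   named vectors `s` and `d`, `collapse` flags (d_i >= t_cf), `P`, `R`,
#'   `n_edges`, and optionally `events`.
#' @export
cascade_all <- function(net, alpha = 0, t_cf = 0.5, keep_events = FALSE) {
  stopifnot(inherits(net, "distance_network"))
  N <- length(net$nodes)
  if (N < 2L) stop("network must have at least 2 nodes")
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  loads <- weighted_betweenness(net)
  profile <- initial_capacities(loads, alpha)
  cap <- profile$capacity[nm]
  iso0 <- igraph::degree(g) == 0
  s <- integer(N)
  events <- if (keep_events) vector("list", N) else NULL
  for (i in seq_len(N)) {
    k <- cascade_kernel(g, cap, iso0, i)
    s[i] <- length(k$failed)
    if (keep_events)
      events[[i]] <- structure(
        list(seed = nm[i], rounds = lapply(k$rounds, function(x) nm[x]),
             failed = nm[k$failed], s = s[i], d = s[i] / N),
        class = "cascade_event")
  }
  d <- s / N
  names(s) <- names(d) <- nm
  ord <- match(net$nodes, nm)
  s <- s[ord]; d <- d[ord]
  collapse <- d >= t_cf
  structure(list(N = N, alpha = alpha, t_cf = t_cf,
                 s = s, d = d, collapse = collapse,
                 P = mean(collapse), R = mean(d),
                 n_edges = nrow(net$edges),
                 load = loads, capacity = profile$capacity,
                 events = if (keep_events) stats::setNames(events, nm)[net$nodes]),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("cascade_result: N=%d edges=%d alpha=%g t_cf=%g P=%.3f R=%.3f\n",
              x$N, x$n_edges, x$alpha, x$t_cf, x$P, x$R))
  invisible(x)
}

#' Cumulative size-ratio curve P(d' >= d)
#'
#' At each grid value d, the fraction of seed nodes whose cascade size-ratio
#' d_i is at least d (inclusive).  The curve is non-increasing, equals 1 at
#' d = 0, and equals P at d = t_cf.
#'
#' @param result a [cascade_all()] result.
#' @param grid numeric vector of d values in \[0, 1\]
#'   (default `seq(0, 1, 0.01)`).
#' @return data frame with columns `d` and `cum_prob`, class
#'   `cumulative_curve`.
#' @export
cumulative_curve <- function(result, grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(result, "cascade_result"))
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  cum <- vapply(grid, function(g) mean(result$d >= g), numeric(1))
  structure(data.frame(d = grid, cum_prob = cum),
            class = c("cumulative_curve", "data.frame"))
}

#' Cascade simulation across a similarity-threshold sweep
#'
#' For each threshold T, builds the distance network with
#' [threshold_and_distance()] and runs [cascade_all()].  The default
#' threshold list is the standard 18-value sweep of
#' [default_thresholds()].
#'
#' @param net an `mi_network`.
#' @param thresholds numeric vector of thresholds in \[0, 1).
#' @param alpha tolerance parameter (default 0).
#' @param t_cf collapse threshold (default 0.5).
#' @param weight_on passed to [threshold_and_distance()].
#' @return object of class `threshold_sweep`: list with `thresholds`,
#'   `results` (one `cascade_result` per threshold), `gene_ids`, `d` (gene x
#'   threshold size-ratio matrix) and `summary` (data frame with threshold,
#'   N, n_edges, P, R).
#' @export
threshold_sweep <- function(net, thresholds = default_thresholds(),
                            alpha = 0, t_cf = 0.5, weight_on = "nmi") {
  stopifnot(inherits(net, "mi_network"))
  if (!length(thresholds)) stop("`thresholds` must be non-empty")
  if (any(thresholds < 0 | thresholds >= 1))
    stop("thresholds must lie in [0, 1)")
  results <- lapply(thresholds, function(T) {
    dn <- threshold_and_distance(net, T, weight_on = weight_on)
    cascade_all(dn, alpha = alpha, t_cf = t_cf)
  })
  names(results) <- vapply(thresholds, format, character(1))
  d <- vapply(results, function(r) r$d, numeric(length(net$gene_ids)))
  dimnames(d) <- list(net$gene_ids, names(results))
  summary <- data.frame(
    threshold = thresholds,
    N = vapply(results, function(r) r$N, numeric(1)),
    n_edges = vapply(results, function(r) r$n_edges, numeric(1)),
    P = vapply(results, function(r) r$P, numeric(1)),
    R = vapply(results, function(r) r$R, numeric(1)))
  structure(list(thresholds = thresholds, results = results,
                 gene_ids = net$gene_ids, d = d, summary = summary,
                 alpha = alpha, t_cf = t_cf),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold_sweep: %d thresholds, %d genes\n",
              length(x$thresholds), length(x$gene_ids)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
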