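# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: betweenness by exhaustive simple-path
# enumeration, mutual information from the joint frequency table.

# Exhaustive shortest-path betweenness: enumerates every simple path between
# every unordered node pair, keeps the minimum-length ones (grouping lengths
# equal up to 1e-12 relative tolerance), and accredits each interior node
# its fraction of shortest paths.
oracle_betweenness <- function(net, tol = 1e-12) {
  nodes <- net$nodes
  n <- length(nodes)
  W <- matrix(Inf, n, n)
  if (nrow(net$edges)) {
    i <- match(net$edges$source, nodes)
    j <- match(net$edges$target, nodes)
    W[cbind(i, j)] <- W[cbind(j, i)] <- net$edges$weight
  }
  adj <- lapply(seq_len(n), function(v) which(is.finite(W[v, ])))
  g <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    paths <- list()
    best <- Inf
    dfs <- function(cur, visited, len) {
      if (len > best * (1 + tol)) return()    # positive weights: safe prune
      if (cur == t) {
        paths[[length(paths) + 1L]] <<- list(v = visited, len = len)
        if (len < best) best <<- len
        return()
      }
      for (nb in adj[[cur]])
        if (!(nb %in% visited)) dfs(nb, c(visited, nb), len + W[cur, nb])
    }
    dfs(s, s, 0)
    if (!length(paths)) next
    keep <- Filter(function(p) p$len <= best * (1 + tol), paths)
    sigma <- length(keep)
    interior <- unlist(lapply(keep, function(p) setdiff(p$v, c(s, t))))
    if (length(interior)) {
      cnt <- table(interior)
      idx <- as.integer(names(cnt))
      g[idx] <- g[idx] + as.numeric(cnt) / sigma
    }
  }
  stats::setNames(g, nodes)
}

# Mutual information straight from the joint frequency table:
# sum p(x,y) log2( p(x,y) / (p(x) p(y)) ).
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0)
      tot <- tot + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  as.numeric(tot)
}

# Random connected weighted graph: random recursive tree plus extra edges,
# continuous weights (exact shortest-path ties have probability ~0).
random_connected_graph <- function(n, p_extra = 0.35, wmin = 0.5, wmax = 2) {
  nodes <- paste0("g", seq_len(n))
  tree <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1L, 1L), 0L))
  pairs <- t(utils::combn(n, 2L))
  in_tree <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
  extra <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% in_tree) &
                   stats::runif(nrow(pairs)) < p_extra, , drop = FALSE]
  ij <- rbind(cbind(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2])),
              extra)
  edges <- data.frame(source = nodes[ij[, 1]], target = nodes[ij[, 2]],
                      weight = stats::runif(nrow(ij), wmin, wmax),
                      stringsAsFactors = FALSE)
  distance_network(nodes, edges)
}

# Nodes that become isolated when `node` is removed (degree-1 neighbours
# whose only edge goes to `node`).
isolation_count <- function(net, node) {
  e <- net$edges
  deg <- table(c(e$source, e$target))
  nb <- c(e$target[e$source == node], e$source[e$target == node])
  sum(deg[nb] == 1)
}
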