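# Independent oracles: deliberately simple, loop-based implementations kept
# separate from the package's vectorized code paths.

# Step-by-step running-sum enrichment score. Tracks the positive and
# negative extrema separately and applies the package's stated tie rule
# (equal magnitudes report the positive extremum).
oracle_es <- function(metric_sorted, hit, weight_p = 1) {
  N <- length(metric_sorted)
  k <- sum(hit)
  tot <- sum(abs(metric_sorted[hit])^weight_p)
  running <- 0
  hi <- 0; lo <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      inc <- if (tot > 0) abs(metric_sorted[i])^weight_p / tot else 1 / k
      running <- running + inc
    } else {
      running <- running - 1 / (N - k)
    }
    hi <- max(hi, running)
    lo <- min(lo, running)
  }
  if (hi >= -lo) hi else lo
}

# Moderated t computed gene-by-gene with plain arithmetic.
oracle_rvm_t <- function(x1, x2, a, b, paired) {
  vapply(seq_len(nrow(x1)), function(g) {
    if (paired) {
      d <- x2[g, ] - x1[g, ]
      n <- length(d)
      s2 <- if (n > 1) var(d) else 0
      shr <- ((n - 1) * s2 + 2 * b) / ((n - 1) + 2 * a)
      mean(d) / sqrt(shr / n)
    } else {
      n1 <- length(x1[g, ]); n2 <- length(x2[g, ])
      s2 <- ((n1 - 1) * var(x1[g, ]) + (n2 - 1) * var(x2[g, ])) /
        (n1 + n2 - 2)
      shr <- ((n1 + n2 - 2) * s2 + 2 * b) / ((n1 + n2 - 2) + 2 * a)
      (mean(x2[g, ]) - mean(x1[g, ])) / sqrt(shr * (1 / n1 + 1 / n2))
    }
  }, 0)
}

# Exhaustive unpaired permutation p-values (label splits via combn).
oracle_perm_p_unpaired <- function(x1, x2, a, b) {
  pool <- cbind(x1, x2)
  n1 <- ncol(x1); n <- ncol(pool)
  t_obs <- abs(oracle_rvm_t(x1, x2, a, b, paired = FALSE)) * (1 - 1e-12)
  splits <- combn(n, n1)
  count <- numeric(nrow(pool))
  for (j in seq_len(ncol(splits))) {
    tb <- oracle_rvm_t(pool[, splits[, j], drop = FALSE],
                       pool[, -splits[, j], drop = FALSE], a, b,
                       paired = FALSE)
    count <- count + (abs(tb) >= t_obs)
  }
  count / ncol(splits)
}

# Exhaustive paired permutation p-values (all sign flips).
oracle_perm_p_paired <- function(x1, x2, a, b) {
  d <- x2 - x1
  n <- ncol(d)
  t_obs <- abs(oracle_rvm_t(x1, x2, a, b, paired = TRUE)) * (1 - 1e-12)
  count <- numeric(nrow(d))
  for (mask in 0:(2^n - 1)) {
    sgn <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1, 1)
    ds <- sweep(d, 2, sgn, `*`)
    tb <- oracle_rvm_t(matrix(0, nrow(d), n), ds, a, b, paired = TRUE)
    count <- count + (abs(tb) >= t_obs)
  }
  count / 2^n
}

# Bottleneck scores by explicit per-root tree construction over a distance
# matrix, counting each node's subtree by walking parent chains.
oracle_bottleneck <- function(graph) {
  nodes <- sort(igraph::V(graph)$name, method = "radix")
  dmat <- igraph::distances(graph)[nodes, nodes, drop = FALSE]
  nbr <- lapply(nodes, function(v)
    sort(names(igraph::neighbors(graph, v)), method = "radix"))
  names(nbr) <- nodes
  bn <- stats::setNames(integer(length(nodes)), nodes)
  for (root in nodes) {
    tree <- nodes[is.finite(dmat[root, ])]
    parent <- list()
    for (v in setdiff(tree, root)) {
      ups <- nbr[[v]][dmat[root, nbr[[v]]] == dmat[root, v] - 1]
      parent[[v]] <- ups[1]
    }
    # subtree of v = number of tree nodes whose parent chain contains v
    for (v in setdiff(tree, root)) {
      size <- 0
      for (u in tree) {
        w <- u
        repeat {
          if (w == v) { size <- size + 1; break }
          if (w == root) break
          w <- parent[[w]]
        }
      }
      if (size > length(tree) / 4) bn[v] <- bn[v] + 1L
    }
  }
  bn
}

# Random connected graph on <= n_max nodes (edges sampled until connected).
random_connected_graph <- function(n_max = 12) {
  n <- sample(3:n_max, 1)
  nodes <- sprintf("N%02d", seq_len(n))
  repeat {
    m <- sample(n - 1:0, 1) + sample(0:n, 1)
    pairs <- t(combn(nodes, 2))
    sel <- pairs[sample(nrow(pairs), min(nrow(pairs), max(n - 1, m))), ,
                 drop = FALSE]
    g <- igraph::graph_from_edgelist(sel, directed = FALSE)
    g <- igraph::simplify(g)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) return(g)
  }
}
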