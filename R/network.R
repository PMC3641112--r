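# Interaction-network construction for pattern gene lists and focus-hub
# ranking with the bottleneck score (counts of rooted shortest-path trees in
# which a node's subtree exceeds a quarter of the tree).

#' Build the interaction network for a pattern gene list
#'
#' Induced subgraph of the reference network on the input genes. With
#' `expand_neighbors`, reference first neighbors that connect two or more
#' input genes are added as connectors. Input genes absent from the reference
#' are ignored; isolated input genes are retained as singletons with a
#' logged count.
#'
#' @param genes Character gene identifiers (matched exactly).
#' @param reference Undirected [igraph::igraph] reference interactome.
#' @param expand_neighbors Include connector neighbors (default FALSE).
#' @return Undirected simple igraph.
#' @export
build_pattern_network <- function(genes, reference, expand_neighbors = FALSE) {
  nodes <- intersect(unique(genes), igraph::V(reference)$name)
  if (!length(nodes)) stop("no input gene matches a reference network node")
  keep <- nodes
  if (expand_neighbors) {
    cand <- setdiff(unique(unlist(lapply(nodes, function(v)
      names(igraph::neighbors(reference, v))))), nodes)
    if (length(cand)) {
      links <- vapply(cand, function(v)
        length(intersect(names(igraph::neighbors(reference, v)), nodes)), 0L)
      keep <- c(nodes, cand[links >= 2])
    }
  }
  g <- igraph::induced_subgraph(reference, keep)
  iso <- sum(igraph::degree(g)[nodes] == 0)
  if (iso) message(iso, " isolated input gene(s) retained as singletons")
  g
}

# sorted adjacency structure: nodes in identifier order, neighbor lists as
# sorted integer indices, so "smallest identifier" tie-breaks are index order.
.sorted_adjacency <- function(network) {
  nodes <- .id_sort(igraph::V(network)$name)
  el <- igraph::as_edgelist(network)
  adj <- vector("list", length(nodes))
  if (nrow(el)) {
    a <- match(el[, 1], nodes); b <- match(el[, 2], nodes)
    for (i in seq_along(a)) {
      adj[[a[i]]] <- c(adj[[a[i]]], b[i])
      adj[[b[i]]] <- c(adj[[b[i]]], a[i])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  list(nodes = nodes, adj = adj)
}

#' Bottleneck scores for every node
#'
#' For every root `s`, the breadth-first shortest-path tree is built with a
#' deterministic parent rule (parent = neighbor one level closer with the
#' smallest identifier). A non-root node is a bottleneck of that tree when
#' its subtree, itself included, holds strictly more than a quarter of the
#' tree's nodes; `BN(v)` counts the rooted trees in which `v` is a
#' bottleneck. Computed per connected component (the tree spans the root's
#' component).
#'
#' @param network Undirected simple [igraph::igraph].
#' @return Named integer vector of BN scores (identifier order).
#' @export
bottleneck_scores <- function(network) {
  sa <- .sorted_adjacency(network)
  n <- length(sa$nodes)
  bn <- setNames(integer(n), sa$nodes)
  if (!n) return(bn)
  for (root in seq_len(n)) {
    depth <- rep(NA_integer_, n)
    parent <- rep(NA_integer_, n)
    order_visited <- integer(0)
    depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in sa$adj[[v]]) {
        if (is.na(depth[w])) {
          depth[w] <- depth[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    tree_nodes <- order_visited
    # parent = smallest-identifier neighbor at depth - 1
    for (v in tree_nodes) {
      if (v == root) next
      up <- sa$adj[[v]][depth[sa$adj[[v]]] == depth[v] - 1L]
      parent[v] <- up[1]  # adjacency is sorted
    }
    size <- rep(1L, n)
    for (v in rev(tree_nodes)) {
      if (v == root) next
      size[parent[v]] <- size[parent[v]] + size[v]
    }
    thr <- length(tree_nodes) / 4
    hit <- tree_nodes[tree_nodes != root & size[tree_nodes] > thr]
    bn[hit] <- bn[hit] + 1L
  }
  bn
}

#' Rank the top focus hubs
#'
#' Nodes ordered by decreasing bottleneck score, ties by identifier; the top
#' `k` receive ranks 1..k (smaller rank = higher confidence). Asking for more
#' hubs than nodes returns all nodes.
#'
#' @param scores Named BN vector from [bottleneck_scores()].
#' @param k Number of focus hubs (default 20).
#' @param network Optional graph used to annotate component membership.
#' @return data.frame of class `hub_ranking`: `node`, `bn`, `rank`,
#'   `component`.
#' @export
rank_top_hubs <- function(scores, k = 20, network = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (!length(scores)) stop("need at least one scored node")
  ord <- order(-scores, names(scores), method = "radix")
  top <- head(ord, min(k, length(scores)))
  comp <- rep(NA_integer_, length(top))
  if (!is.null(network)) {
    membership <- igraph::components(network)$membership
    comp <- as.integer(membership[match(names(scores)[top],
                                        igraph::V(network)$name)])
  }
  structure(data.frame(node = names(scores)[top],
                       bn = as.integer(scores[top]),
                       rank = seq_along(top), component = comp,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("hub_ranking", "data.frame"))
}

#' Merge interaction networks
#'
#' Node and edge union with duplicate edges collapsed.
#'
#' @param networks List of two or more undirected igraphs.
#' @return Undirected simple igraph.
#' @export
merge_networks <- function(networks) {
  if (length(networks) < 2) stop("need at least two networks")
  nodes <- .id_sort(unique(unlist(lapply(networks, function(g)
    igraph::V(g)$name))))
  els <- do.call(rbind, lapply(networks, igraph::as_edgelist))
  g <- igraph::graph_from_data_frame(
    data.frame(from = els[, 1], to = els[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  igraph::simplify(g)
}
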