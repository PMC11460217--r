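# Community detection and (bridge) centralities on a symptom network.
# Graph conventions follow the network-psychometrics software family: edge
# weights are absolute partial correlations, shortest-path distances are
# their reciprocals 1/|w|.

network_igraph <- function(network, distances = FALSE) {
  w <- abs(network$weights)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (distances) igraph::E(g)$dist <- 1 / igraph::E(g)$weight
  g
}

walktrap_on_adjacency <- function(w, steps = 4L, method = "walktrap") {
  p <- nrow(w)
  nm <- colnames(w)
  if (is.null(nm)) nm <- as.character(seq_len(p))
  deg <- rowSums(abs(w)) - abs(diag(w))
  isolated <- which(deg == 0)
  active <- setdiff(seq_len(p), isolated)
  labels <- integer(p)
  if (length(active) >= 2L) {
    g <- igraph::graph_from_adjacency_matrix(
      abs(w[active, active, drop = FALSE]),
      mode = "undirected", weighted = TRUE, diag = FALSE
    )
    wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                   steps = steps)
    labels[active] <- igraph::membership(wt)
  } else if (length(active) == 1L) {
    labels[active] <- 1L
  }
  # isolated nodes become singleton communities
  if (length(isolated)) {
    labels[isolated] <- max(labels, 0L) + seq_along(isolated)
  }
  names(labels) <- nm
  cluster_assignment(labels, method = method)
}

#' Walktrap symptom communities
#'
#' Runs the walktrap agglomerative community-detection procedure on the
#' graph whose edge weights are absolute partial correlations, taking the
#' modularity-maximizing cut of the merge dendrogram. Isolated nodes are
#' assigned singleton communities.
#'
#' @param network a [symptom_network()] with at least one edge.
#' @param steps random-walk length (default 4, the igraph convention).
#' @return A [cluster_assignment()] over the network's nodes.
#' @export
walktrap_communities <- function(network, steps = 4L) {
  stopifnot(inherits(network, "symptom_network"))
  if (n_edges(network) == 0L) {
    stop("network has no edges: community detection is undefined (sparse/unstable network)")
  }
  walktrap_on_adjacency(network$weights, steps = steps)
}

zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Node centralities
#'
#' Strength (sum of absolute edge weights), closeness (reciprocal of the
#' total shortest-path distance to the other nodes of the same connected
#' component, with edge lengths `1/|w|`), and betweenness (number of
#' shortest paths passing through the node, ties split fractionally).
#' Cross-component distances are excluded rather than treated as infinite so
#' that closeness stays finite on disconnected graphs; fully isolated nodes
#' get closeness 0. Z-scores across nodes are appended for each measure.
#'
#' @param network a [symptom_network()].
#' @return data.frame with one row per node: `node`, `strength`,
#'   `closeness`, `betweenness` and their `_z` columns.
#' @export
node_centralities <- function(network) {
  stopifnot(inherits(network, "symptom_network"))
  w <- abs(network$weights)
  strength <- rowSums(w)
  g <- network_igraph(network, distances = TRUE)
  d <- igraph::distances(g, weights = igraph::E(g)$dist)
  diag(d) <- NA
  closeness <- apply(d, 1L, function(row) {
    tot <- sum(row[is.finite(row)], na.rm = TRUE)
    if (tot == 0) 0 else 1 / tot
  })
  betweenness <- igraph::betweenness(g, weights = igraph::E(g)$dist)
  data.frame(
    node = network$nodes,
    strength = unname(strength),
    closeness = unname(closeness),
    betweenness = unname(betweenness),
    strength_z = zscore(unname(strength)),
    closeness_z = zscore(unname(closeness)),
    betweenness_z = zscore(unname(betweenness)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bridge centralities
#'
#' The same three measures restricted to cross-community structure: bridge
#' strength sums absolute weights of edges to other communities; bridge
#' closeness is the reciprocal of the total shortest-path distance to all
#' nodes outside the node's own community; bridge betweenness counts the
#' shortest paths between node pairs in *different* communities that pass
#' through the node (fractional for tied paths).
#'
#' @param network a [symptom_network()].
#' @param assignment a [cluster_assignment()] with at least 2 communities.
#' @return data.frame per node: `bridge_strength`, `bridge_closeness`,
#'   `bridge_betweenness` plus `_z` columns.
#' @export
bridge_centralities <- function(network, assignment) {
  stopifnot(inherits(network, "symptom_network"),
            inherits(assignment, "cluster_assignment"))
  comm <- assignment$labels
  if (length(comm) != length(network$nodes)) {
    stop("assignment must label every network node")
  }
  if (assignment$n_communities < 2L) {
    stop("bridge centralities require at least 2 communities")
  }
  p <- length(network$nodes)
  w <- abs(network$weights)
  cross <- outer(comm, comm, "!=")
  bridge_strength <- rowSums(w * cross)

  g <- network_igraph(network, distances = TRUE)
  d <- igraph::distances(g, weights = igraph::E(g)$dist)
  bridge_closeness <- vapply(seq_len(p), function(i) {
    di <- d[i, comm != comm[i]]
    tot <- sum(di[is.finite(di)])
    if (tot == 0) 0 else 1 / tot
  }, 1)

  # Brandes-style fractional counting restricted to cross-community pairs
  bridge_betweenness <- numeric(p)
  for (s in seq_len(p)) {
    targets <- which(comm != comm[s] & seq_len(p) > s)
    targets <- targets[is.finite(d[s, targets])]
    for (t in targets) {
      paths <- igraph::all_shortest_paths(
        g, from = s, to = t, weights = igraph::E(g)$dist
      )$vpaths
      npaths <- length(paths)
      if (npaths == 0L) next
      for (pa in paths) {
        interior <- as.integer(pa)
        interior <- interior[-c(1L, length(interior))]
        if (length(interior)) {
          bridge_betweenness[interior] <- bridge_betweenness[interior] + 1 / npaths
        }
      }
    }
  }

  data.frame(
    node = network$nodes,
    bridge_strength = unname(bridge_strength),
    bridge_closeness = unname(bridge_closeness),
    bridge_betweenness = bridge_betweenness,
    bridge_strength_z = zscore(unname(bridge_strength)),
    bridge_closeness_z = zscore(unname(bridge_closeness)),
    bridge_betweenness_z = zscore(bridge_betweenness),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Full centrality table
#'
#' Convenience wrapper joining [node_centralities()] and, when the
#' assignment has at least two communities, [bridge_centralities()].
#'
#' @param network a [symptom_network()].
#' @param assignment optional [cluster_assignment()].
#' @return data.frame with one row per node.
#' @export
centrality_table <- function(network, assignment = NULL) {
  out <- node_centralities(network)
  if (!is.null(assignment) && assignment$n_communities >= 2L) {
    out <- merge(out, bridge_centralities(network, assignment),
                 by = "node", sort = FALSE)
  }
  out
}
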