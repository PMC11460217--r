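# Shared fixture builders (everything generated in code, nothing on disk).

three_block_spec <- function(seed, n = 1000, between = 0) {
  cohort_spec(
    n_patients = n, p = 12, symptom_blocks = list(1:4, 5:8, 9:12),
    within_block_corr = 0.4, between_block_corr = between, seed = seed
  )
}

# hand-built symmetric partial-correlation matrix from an edge list
weights_from_edges <- function(p, edges, nodes = sprintf("n%02d", seq_len(p))) {
  w <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (e in edges) {
    w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
  }
  w
}

# two 4-cliques with optional bridging edge
two_clique_network <- function(within = 0.5, bridge = 0) {
  edges <- list()
  for (cl in list(1:4, 5:8)) {
    for (i in cl) for (j in cl) if (i < j) {
      edges[[length(edges) + 1]] <- list(i, j, within)
    }
  }
  if (bridge > 0) edges[[length(edges) + 1]] <- list(4, 5, bridge)
  symptom_network(weights_from_edges(8, edges))
}
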