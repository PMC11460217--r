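test_that("disconnected cliques are recovered as separate communities", {
  net <- two_clique_network(within = 0.5, bridge = 0)
  cl <- walktrap_communities(net)
  expect_equal(cl$n_communities, 2L)
  expect_equal(unname(cl$labels[1:4]), rep(1L, 4))
  expect_equal(unname(cl$labels[5:8]), rep(2L, 4))
})

test_that("a weak bridging edge does not merge the cliques", {
  net <- two_clique_network(within = 0.5, bridge = 0.05)
  cl <- walktrap_communities(net)
  expect_equal(cl$n_communities, 2L)
  expect_equal(ari_partition(cl$labels, rep(1:2, each = 4)), 1)
})

test_that("isolated nodes become singleton communities", {
  w <- weights_from_edges(5, list(list(1, 2, 0.5), list(2, 3, 0.5),
                                  list(1, 3, 0.5)))
  cl <- walktrap_communities(symptom_network(w))
  expect_equal(unname(cl$labels[1:3]), rep(1L, 3))
  expect_equal(length(unique(cl$labels[4:5])), 2L)
  expect_error(
    walktrap_communities(symptom_network(matrix(0, 3, 3))),
    "no edges"
  )
})

test_that("star centre dominates all three centralities", {
  edges <- lapply(2:6, function(j) list(1, j, 0.3))
  net <- symptom_network(weights_from_edges(6, edges))
  ct <- node_centralities(net)
  expect_equal(which.max(ct$strength), 1L)
  expect_equal(which.max(ct$closeness), 1L)
  expect_equal(which.max(ct$betweenness), 1L)
  # z-scores are standardized across nodes
  expect_equal(mean(ct$strength_z), 0, tolerance = 1e-9)
  expect_equal(sd(ct$strength_z), 1, tolerance = 1e-9)
})

test_that("path-graph betweenness counts the single through node", {
  w <- weights_from_edges(3, list(list(1, 2, 0.5), list(2, 3, 0.5)))
  ct <- node_centralities(symptom_network(w))
  expect_equal(ct$betweenness, c(0, 1, 0))
})

test_that("centralities agree with the brute-force shortest-path oracle", {
  set.seed(29)
  for (trial in 1:3) {
    # random sparse 8-node weighted graph
    w <- matrix(0, 8, 8)
    for (i in 1:7) for (j in (i + 1):8) {
      if (runif(1) < 0.4) w[i, j] <- w[j, i] <- runif(1, 0.1, 0.6)
    }
    if (sum(w) == 0) w[1, 2] <- w[2, 1] <- 0.5
    net <- symptom_network(w)
    ct <- node_centralities(net)
    expect_equal(ct$strength, rowSums(abs(w)), tolerance = 1e-10)
    expect_equal(ct$closeness, brute_closeness(w), tolerance = 1e-10)
    expect_equal(ct$betweenness, brute_betweenness(w), tolerance = 1e-10)
  }
})

test_that("centralities are equivariant under node relabeling", {
  set.seed(31)
  w <- matrix(0, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  for (i in 1:6) for (j in (i + 1):7) {
    if (runif(1) < 0.5) w[i, j] <- w[j, i] <- runif(1, 0.1, 0.5)
  }
  perm <- sample(7)
  ct <- node_centralities(symptom_network(w))
  ctp <- node_centralities(symptom_network(w[perm, perm]))
  reordered <- ctp[match(ct$node, ctp$node), ]
  expect_equal(reordered$strength, ct$strength, tolerance = 1e-10)
  expect_equal(reordered$closeness, ct$closeness, tolerance = 1e-10)
  expect_equal(reordered$betweenness, ct$betweenness, tolerance = 1e-10)
})

test_that("bridge centralities respect their definitions on a 6-node fixture", {
  # communities {1,2,3} and {4,5,6}; node 3 carries all the cross traffic
  w <- weights_from_edges(6, list(
    list(1, 2, 0.5), list(1, 3, 0.4), list(2, 3, 0.4),
    list(3, 4, 0.3),
    list(4, 5, 0.5), list(4, 6, 0.4), list(5, 6, 0.4)
  ))
  net <- symptom_network(w)
  asg <- cluster_assignment(rep(1:2, each = 3))
  bc <- bridge_centralities(net, asg)
  comm <- rep(1:2, each = 3)
  cross <- outer(comm, comm, "!=")
  expect_equal(bc$bridge_strength, unname(rowSums(abs(w) * cross)),
               tolerance = 1e-12)
  expect_equal(bc$bridge_closeness, brute_closeness(w, comm), tolerance = 1e-10)
  expect_equal(bc$bridge_betweenness, brute_betweenness(w, comm),
               tolerance = 1e-10)
  # node 4's only in-community edges: bridge strength is its single cross edge
  expect_equal(bc$bridge_strength[3], 0.3)
  # nodes 1, 2 have all edges inside their community except via 3
  expect_equal(bc$bridge_strength[1], 0)
})

test_that("bridge strength never exceeds strength", {
  set.seed(37)
  for (trial in 1:3) {
    w <- matrix(0, 8, 8)
    for (i in 1:7) for (j in (i + 1):8) {
      if (runif(1) < 0.5) w[i, j] <- w[j, i] <- runif(1, 0.1, 0.5)
    }
    net <- symptom_network(w)
    asg <- cluster_assignment(sample(1:2, 8, replace = TRUE))
    if (asg$n_communities < 2) next
    ct <- node_centralities(net)
    bc <- bridge_centralities(net, asg)
    expect_true(all(bc$bridge_strength <= ct$strength + 1e-12))
  }
})

test_that("bridge centralities require at least two communities", {
  net <- two_clique_network()
  expect_error(bridge_centralities(net, cluster_assignment(rep(1, 8))),
               "2 communities")
})

test_that("a planted hub symptom attains the top strength z-score", {
  # hub: symptom 1 coupled to every other symptom in the latent precision
  p <- 10
  k <- diag(p)
  k[1, 2:p] <- k[2:p, 1] <- -0.25
  sigma <- stats::cov2cor(solve(k))
  sp <- cohort_spec(2000, p, list(1:p), within_block_corr = 0.1,
                    latent_corr = sigma, seed = 43)
  co <- generate_cohort(sp)
  sel <- select_network(nonparanormal_transform(co$severity))
  ct <- node_centralities(sel$network)
  expect_equal(which.max(ct$strength_z), 1L)
})

test_that("synthetic three-block networks recover the planted communities", {
  hits <- 0L
  for (s in 1:6) {
    co <- generate_cohort(three_block_spec(seed = 100 + s))
    sel <- select_network(nonparanormal_transform(co$severity))
    cl <- walktrap_communities(sel$network)
    if (ari_partition(cl, co$true_symptom_clusters) == 1) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})
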