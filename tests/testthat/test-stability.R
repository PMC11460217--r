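test_that("a single resample is reproducible under a fixed seed", {
  co <- generate_cohort(three_block_spec(seed = 3, n = 300))
  x <- nonparanormal_transform(co$severity)
  a <- resample_networks(x, B = 1, seed = 99, n_lambdas = 30)
  b <- resample_networks(x, B = 1, seed = 99, n_lambdas = 30)
  expect_identical(a[[1]]$weights, b[[1]]$weights)
})

test_that("identical resampled networks give zero-width intervals", {
  w <- weights_from_edges(4, list(list(1, 2, 0.4), list(3, 4, 0.3)))
  net <- symptom_network(w)
  nets <- structure(rep(list(net), 25), class = "network_resamples")
  es <- edge_significance(nets, net, conf = 0.95)
  expect_true(all(es$edge_ci$hi - es$edge_ci$lo == 0))
  expect_equal(sum(es$edge_ci$significant), 2L)
  # zero edges everywhere are never significant
  zero_rows <- es$edge_ci$ref_weight == 0
  expect_false(any(es$edge_ci$significant[zero_rows]))
})

test_that("looser confidence yields a superset of significant edges", {
  co <- generate_cohort(three_block_spec(seed = 7, n = 400))
  x <- nonparanormal_transform(co$severity)
  ref <- select_network(x, n_lambdas = 30)$network
  nets <- resample_networks(x, B = 40, seed = 11, n_lambdas = 30)
  sig95 <- edge_significance(nets, ref, conf = 0.95)$edge_ci$significant
  sig50 <- edge_significance(nets, ref, conf = 0.50)$edge_ci$significant
  expect_true(all(sig50[sig95]))
})

test_that("resampled edge means agree with a large-B oracle run", {
  co <- generate_cohort(cohort_spec(250, 6, list(1:3, 4:6),
                                    within_block_corr = 0.4, seed = 13))
  x <- nonparanormal_transform(co$severity)
  small <- resample_networks(x, B = 20, seed = 21, n_lambdas = 25)
  big <- resample_networks(x, B = 400, seed = 22, n_lambdas = 25)
  get_w <- function(nets) sapply(nets, function(n) n$weights[upper.tri(n$weights)])
  ws <- get_w(small)
  wb <- get_w(big)
  mc_se <- apply(wb, 1, sd) / sqrt(20)
  diff_ok <- abs(rowMeans(ws) - rowMeans(wb)) <= 2 * mc_se + 1e-3
  # a couple of edges may straddle the selection boundary; most must agree
  expect_gte(mean(diff_ok), 0.85)
})

test_that("planted strong edges are detected as significant", {
  hits <- 0L
  for (s in 1:10) {
    sp <- cohort_spec(1000, 6, list(1:2), within_block_corr = 0.4,
                      seed = 300 + s)
    co <- generate_cohort(sp)
    x <- nonparanormal_transform(co$severity)
    ref <- select_network(x, n_lambdas = 25)$network
    nets <- resample_networks(x, B = 60, seed = s, n_lambdas = 25)
    es <- edge_significance(nets, ref)
    sig <- es$edge_ci$significant[es$edge_ci$a == "S01" & es$edge_ci$b == "S02"]
    if (isTRUE(sig)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("greedy Jaccard matching follows the hand-walked example", {
  # reference {a,b},{c,d}; resample {a,b,c},{d}: {a,b,c} maps to {a,b}
  # (Jaccard 2/3) first, then {d} maps to {c,d} (1/2) -> a, b, d stable
  ref <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  res <- c(a = 1L, b = 1L, c = 1L, d = 2L)
  mapping <- symptomnet:::match_clusters_jaccard(ref, res)
  expect_equal(unname(mapping[c("1", "2")]), c(1L, 2L))
  mapped <- mapping[as.character(res)]
  stable <- !is.na(mapped) & mapped == ref
  expect_equal(unname(stable), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("matching is invariant to cluster id relabeling", {
  set.seed(41)
  ref <- sample(1:3, 12, replace = TRUE)
  res <- sample(1:3, 12, replace = TRUE)
  m1 <- symptomnet:::match_clusters_jaccard(ref, res)
  relab <- c(3L, 1L, 2L)[res]   # permute resample ids
  m2 <- symptomnet:::match_clusters_jaccard(ref, relab)
  stable1 <- m1[as.character(res)] == ref
  stable2 <- m2[as.character(relab)] == ref
  expect_equal(unname(stable1), unname(stable2))
})

test_that("resamples identical to the reference give perfect stability", {
  w <- weights_from_edges(6, list(
    list(1, 2, 0.5), list(1, 3, 0.5), list(2, 3, 0.5),
    list(4, 5, 0.5), list(4, 6, 0.5), list(5, 6, 0.5)
  ))
  net <- symptom_network(w)
  ref <- walktrap_communities(net)
  nets <- structure(rep(list(net), 15), class = "network_resamples")
  cs <- cluster_stability(nets, ref)
  expect_true(all(cs$per_symptom_same_cluster_prop == 1))
  expect_equal(cs$cluster_count_distribution, c("2" = 1))
  expect_true(all(cs$exact_cluster_replication_prop == 1))
})

test_that("empty resampled networks count as zero-cluster outcomes", {
  w <- weights_from_edges(4, list(list(1, 2, 0.5)))
  net <- symptom_network(w)
  empty <- symptom_network(matrix(0, 4, 4))
  ref <- walktrap_communities(net)
  nets <- structure(list(net, empty), class = "network_resamples")
  cs <- cluster_stability(nets, ref)
  expect_equal(unname(cs$cluster_count_distribution["0"]), 0.5)
  expect_true(all(cs$per_symptom_same_cluster_prop <= 0.5))
})

test_that("well-separated blocks are stable under resampling", {
  co <- generate_cohort(three_block_spec(seed = 51))
  x <- nonparanormal_transform(co$severity)
  sel <- select_network(x)
  ref <- walktrap_communities(sel$network)
  st <- assess_stability(x, sel$network, ref, B = 60, seed = 61)
  expect_true(all(st$per_symptom_same_cluster_prop >= 0.9))
})
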