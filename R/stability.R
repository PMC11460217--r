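# Resampling-based accuracy/stability assessment: per-edge percentile
# intervals, symptom-cluster stability under re-estimation, and cluster
# replication rates relative to the full-data reference.

#' Re-estimate the network on case resamples
#'
#' Draws `B` patient-level resamples (with replacement by default, keeping
#' the original sample size) and re-runs the full penalty-path/EBIC network
#' selection on each. Resamples that produce a constant column are redrawn
#' (at most 10 retries each).
#'
#' @param x transformed data matrix (patients x symptoms).
#' @param B number of resamples (at least 100 recommended for intervals).
#' @param seed integer seed; the whole stream is reproducible.
#' @param replace draw rows with replacement (bootstrap, default) or without
#'   (subsampling of `floor(0.9 n)` rows).
#' @param gamma,n_lambdas,lambda_min_ratio passed to [select_network()].
#' @return List of [symptom_network()] objects of class `network_resamples`,
#'   with attributes `B`, `seed`, `replace`, `n_redraws`.
#' @export
resample_networks <- function(x, B = 1000L, seed = 1L, replace = TRUE,
                              gamma = 0.5, n_lambdas = 100L,
                              lambda_min_ratio = 0.01) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(B >= 1)
  set.seed(seed)
  m <- if (replace) n else floor(0.9 * n)
  nets <- vector("list", B)
  n_redraws <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(10L)) {
      idx <- sample.int(n, m, replace = replace)
      xb <- x[idx, , drop = FALSE]
      if (all(apply(xb, 2L, sd) > 0)) {
        ok <- TRUE
        break
      }
      n_redraws <- n_redraws + 1L
    }
    if (!ok) stop(sprintf("resample %d: constant column after 10 redraws", b))
    nets[[b]] <- suppressWarnings(
      select_network(xb, gamma = gamma, n_lambdas = n_lambdas,
                     lambda_min_ratio = lambda_min_ratio)$network
    )
  }
  structure(nets, class = "network_resamples", B = B, seed = seed,
            replace = replace, n_redraws = n_redraws)
}

#' Edge accuracy: percentile intervals and significance
#'
#' Percentile interval per edge across the resampled networks; an edge is
#' deemed significant when its interval excludes zero and its weight in the
#' reference network is nonzero.
#'
#' @param resamples a `network_resamples` list.
#' @param reference the full-data [symptom_network()].
#' @param conf confidence level in `(0, 1)` (default 0.95).
#' @return List with `edge_ci` (data.frame: `a`, `b`, `ref_weight`, `lo`,
#'   `hi`, `prop_nonzero`, `significant`) and `significant_edges` (the
#'   significant subset).
#' @export
edge_significance <- function(resamples, reference, conf = 0.95) {
  stopifnot(inherits(reference, "symptom_network"), conf > 0, conf < 1)
  p <- length(reference$nodes)
  ut <- which(upper.tri(reference$weights), arr.ind = TRUE)
  wmat <- vapply(resamples, function(net) net$weights[ut], numeric(nrow(ut)))
  if (is.null(dim(wmat))) wmat <- matrix(wmat, nrow = nrow(ut))
  alpha <- (1 - conf) / 2
  lo <- apply(wmat, 1L, quantile, probs = alpha, names = FALSE)
  hi <- apply(wmat, 1L, quantile, probs = 1 - alpha, names = FALSE)
  ref_w <- reference$weights[ut]
  edge_ci <- data.frame(
    a = reference$nodes[ut[, 1L]],
    b = reference$nodes[ut[, 2L]],
    ref_weight = ref_w,
    lo = lo,
    hi = hi,
    prop_nonzero = rowMeans(wmat != 0),
    significant = (lo > 0 | hi < 0) & ref_w != 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(edge_ci = edge_ci,
       significant_edges = edge_ci[edge_ci$significant, , drop = FALSE])
}

# Greedy one-to-one matching of resample clusters to reference clusters by
# maximal Jaccard overlap (largest overlap first; ties broken by reference
# then resample id for determinism).
match_clusters_jaccard <- function(reference_labels, resample_labels) {
  ref_ids <- sort(unique(reference_labels))
  res_ids <- sort(unique(resample_labels))
  grid <- expand.grid(ref = ref_ids, res = res_ids)
  grid$jaccard <- mapply(function(r, s) {
    a <- which(reference_labels == r)
    b <- which(resample_labels == s)
    length(intersect(a, b)) / length(union(a, b))
  }, grid$ref, grid$res)
  grid <- grid[order(-grid$jaccard, grid$ref, grid$res), , drop = FALSE]
  mapping <- setNames(rep(NA_integer_, length(res_ids)), res_ids)
  used_ref <- integer()
  for (k in seq_len(nrow(grid))) {
    r <- grid$ref[k]
    s <- grid$res[k]
    if (grid$jaccard[k] == 0) break
    if (r %in% used_ref || !is.na(mapping[as.character(s)])) next
    mapping[as.character(s)] <- r
    used_ref <- c(used_ref, r)
  }
  mapping
}

#' Symptom-cluster stability across resamples
#'
#' Re-runs walktrap community detection on every resampled network and
#' scores, per symptom, the proportion of resamples in which it lands in
#' the cluster that maps to its reference cluster (resample clusters are
#' matched to reference clusters greedily by maximal Jaccard overlap). Also
#' reports the distribution of the number of clusters found and, per
#' reference cluster, how often it is replicated exactly as a set.
#' Resamples whose network has no edges count as a 0-cluster outcome and
#' score no symptom as stable.
#'
#' @param resamples a `network_resamples` list.
#' @param reference a [cluster_assignment()] from the full-data network.
#' @param steps walktrap random-walk length.
#' @return List with `n_resamples`, `per_symptom_same_cluster_prop` (named),
#'   `cluster_count_distribution` (named proportions), and
#'   `exact_cluster_replication_prop` (per reference cluster id).
#' @export
cluster_stability <- function(resamples, reference, steps = 4L) {
  stopifnot(inherits(reference, "cluster_assignment"))
  ref <- reference$labels
  p <- length(ref)
  B <- length(resamples)
  same <- numeric(p)
  k_counts <- integer(0)
  exact <- setNames(numeric(reference$n_communities),
                    seq_len(reference$n_communities))
  ref_sets <- lapply(seq_len(reference$n_communities),
                     function(r) unname(which(ref == r)))
  for (net in resamples) {
    if (n_edges(net) == 0L) {
      k_counts <- c(k_counts, 0L)
      next
    }
    asg <- walktrap_communities(net, steps = steps)$labels
    k_counts <- c(k_counts, max(asg))
    mapping <- match_clusters_jaccard(ref, asg)
    mapped <- mapping[as.character(asg)]
    same <- same + as.numeric(!is.na(mapped) & mapped == ref)
    sets <- split(seq_len(p), asg)
    for (r in seq_along(ref_sets)) {
      if (any(vapply(sets, function(s) identical(unname(s), ref_sets[[r]]), TRUE))) {
        exact[r] <- exact[r] + 1
      }
    }
  }
  kc <- table(factor(k_counts, levels = sort(unique(k_counts))))
  list(
    n_resamples = B,
    per_symptom_same_cluster_prop = setNames(same / B, names(ref)),
    cluster_count_distribution = setNames(as.numeric(kc) / B, names(kc)),
    exact_cluster_replication_prop = exact / B
  )
}

#' Full stability report
#'
#' Convenience wrapper: resamples the data, then computes edge accuracy and
#' cluster stability against the supplied full-data reference.
#'
#' @param x transformed data matrix.
#' @param reference_network full-data [symptom_network()].
#' @param reference_assignment full-data [cluster_assignment()].
#' @param B,seed,replace,conf,gamma,n_lambdas,lambda_min_ratio,steps see the
#'   underlying functions.
#' @return A `stability_report`: list combining [edge_significance()] and
#'   [cluster_stability()] output plus `n_resamples`.
#' @export
assess_stability <- function(x, reference_network, reference_assignment,
                             B = 1000L, seed = 1L, replace = TRUE,
                             conf = 0.95, gamma = 0.5, n_lambdas = 100L,
                             lambda_min_ratio = 0.01, steps = 4L) {
  nets <- resample_networks(x, B = B, seed = seed, replace = replace,
                            gamma = gamma, n_lambdas = n_lambdas,
                            lambda_min_ratio = lambda_min_ratio)
  edges <- edge_significance(nets, reference_network, conf = conf)
  clusters <- cluster_stability(nets, reference_assignment, steps = steps)
  structure(
    c(list(n_resamples = B, conf = conf, replace = replace), edges, clusters),
    class = "stability_report"
  )
}
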