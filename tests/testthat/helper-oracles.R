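# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the package implementations they check.

# wTO by definition, double loop
brute_wto <- function(x) {
  w <- cor(x)
  diag(w) <- 0
  p <- ncol(w)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      num <- abs(sum(w[i, ] * w[j, ]) + w[i, j])
      den <- min(sum(abs(w[i, ])), sum(abs(w[j, ]))) + 1 - abs(w[i, j])
      out[i, j] <- num / den
    }
  }
  out
}

# pair-counting ARI: loop over all item pairs and classify agreement
brute_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  tot <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) {
    # degenerate (both constant, or both all-singletons): defined as 1 only
    # for identical labelings
    return(if (identical(as.vector(a), as.vector(b))) 1 else 0)
  }
  (n11 - expected) / (maxidx - expected)
}

# severity vector -> cell labeling of the upper triangle incl. diagonal
brute_cells <- function(x) {
  p <- length(x)
  out <- integer(0)
  for (j in seq_len(p)) {
    for (i in seq_len(j)) {
      out <- c(out, x[i] * x[j])
    }
  }
  out
}

# all-pairs shortest-path distances by Floyd-Warshall on lengths 1/|w|
brute_distances <- function(weights) {
  p <- nrow(weights)
  d <- matrix(Inf, p, p)
  diag(d) <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j && weights[i, j] != 0) d[i, j] <- 1 / abs(weights[i, j])
    }
  }
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# enumerate every simple path between s and t by depth-first search, return
# the shortest ones (list of vertex sequences); feasible for p <= 8
brute_shortest_paths <- function(weights, s, t) {
  p <- nrow(weights)
  best <- list(len = Inf, paths = list())
  recurse <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      if (len < best$len - 1e-12) {
        best$len <<- len
        best$paths <<- list(path)
      } else if (abs(len - best$len) <= 1e-12) {
        best$paths <<- c(best$paths, list(path))
      }
      return()
    }
    for (u in seq_len(p)) {
      if (weights[v, u] != 0 && !(u %in% path)) {
        recurse(c(path, u), len + 1 / abs(weights[v, u]))
      }
    }
  }
  recurse(s, 0)
  best
}

# betweenness by exhaustive path enumeration, optionally restricted to
# endpoint pairs in different communities
brute_betweenness <- function(weights, comm = NULL) {
  p <- nrow(weights)
  out <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      if (!is.null(comm) && comm[s] == comm[t]) next
      sp <- brute_shortest_paths(weights, s, t)
      if (!length(sp$paths)) next
      for (pa in sp$paths) {
        interior <- pa[-c(1, length(pa))]
        out[interior] <- out[interior] + 1 / length(sp$paths)
      }
    }
  }
  out
}

# closeness within components (cross-component distances excluded)
brute_closeness <- function(weights, comm = NULL) {
  p <- nrow(weights)
  d <- brute_distances(weights)
  vapply(seq_len(p), function(i) {
    js <- setdiff(seq_len(p), i)
    if (!is.null(comm)) js <- js[comm[js] != comm[i]]
    tot <- sum(d[i, js][is.finite(d[i, js])])
    if (tot == 0) 0 else 1 / tot
  }, 1)
}
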