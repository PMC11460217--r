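# Pre-network steps: redundancy detection via weighted topological overlap,
# consolidation of redundant symptom pairs through a tau-equivalent
# two-indicator factor model, and the rank-based nonparanormal transform.

check_severity_matrix <- function(severity, min_patients = 10L) {
  if (!is.matrix(severity)) severity <- as.matrix(severity)
  if (ncol(severity) < 2L) stop("need at least 2 symptoms")
  if (nrow(severity) < min_patients) {
    stop(sprintf("need at least %d patients", min_patients))
  }
  const <- which(apply(severity, 2L, function(x) length(unique(x)) < 2L))
  if (length(const)) {
    nm <- colnames(severity)[const]
    if (is.null(nm)) nm <- as.character(const)
    stop("constant symptom column(s): ", paste(nm, collapse = ", "))
  }
  severity
}

#' Weighted topological overlap of symptoms
#'
#' Computes, for every symptom pair, the weighted topological overlap (wTO)
#' of the Pearson association matrix of the severities:
#' `wTO_ij = |sum_k w_ik w_jk + w_ij| / (min(sum_k |w_ik|, sum_k |w_jk|) + 1 - |w_ij|)`
#' with `w` the zero-diagonal correlation matrix. Symptom pairs that share
#' essentially all of their neighbourhood (candidate redundant pairs
#' measuring the same underlying construct) score close to 1.
#'
#' @param severity patients x symptoms matrix (ordinal 0-4 or numeric).
#' @return Symmetric `p x p` matrix of overlap values in `[0, 1]` with zero
#'   diagonal.
#' @export
weighted_topological_overlap <- function(severity) {
  severity <- check_severity_matrix(severity)
  w <- cor(severity)
  diag(w) <- 0
  a <- w %*% w                      # sum_k w_ik w_jk (diagonal of w is 0)
  conn <- rowSums(abs(w))
  denom <- outer(conn, conn, pmin) + 1 - abs(w)
  wto <- abs(a + w) / denom
  diag(wto) <- 0
  wto[wto > 1] <- 1                 # guard against rounding at the boundary
  dimnames(wto) <- dimnames(w)
  wto
}

#' Flag redundant symptom pairs
#'
#' Candidate pairs at or above the overlap threshold are selected greedily
#' in descending overlap order so that no symptom appears in two flagged
#' pairs (the highest-overlap pair wins).
#'
#' @param overlap symmetric overlap matrix from
#'   [weighted_topological_overlap()].
#' @param threshold overlap cutoff in `(0, 1)`; 0.25 by convention.
#' @return A `redundancy_report`: list with `pairwise_overlap`,
#'   `flagged_pairs` (data.frame `a`, `b`, `overlap`, sorted by descending
#'   overlap) and `threshold_used`.
#' @export
detect_redundant_pairs <- function(overlap, threshold = 0.25) {
  stopifnot(is.matrix(overlap), nrow(overlap) == ncol(overlap))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  p <- nrow(overlap)
  nm <- colnames(overlap)
  if (is.null(nm)) nm <- as.character(seq_len(p))
  ut <- which(upper.tri(overlap), arr.ind = TRUE)
  vals <- overlap[ut]
  keep <- vals >= threshold
  ut <- ut[keep, , drop = FALSE]
  vals <- vals[keep]
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  used <- logical(p)
  rows <- list()
  for (k in ord) {
    i <- ut[k, 1L]
    j <- ut[k, 2L]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      a = nm[i], b = nm[j], overlap = vals[k], stringsAsFactors = FALSE
    )
  }
  flagged <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(a = character(), b = character(), overlap = numeric())
  }
  structure(
    list(
      pairwise_overlap = overlap, flagged_pairs = flagged,
      threshold_used = threshold
    ),
    class = "redundancy_report"
  )
}

#' Consolidate a redundant symptom pair
#'
#' Fits the minimal identified one-factor model to the standardized pair —
#' two indicators with equal (tau-equivalent) loadings, estimated by maximum
#' likelihood, under which the loading is `sqrt(r)` for sample correlation
#' `r` and the regression-method factor score is proportional to
#' `z_a + z_b` — and returns the factor score rescaled affinely onto the
#' 0-4 severity scale.
#'
#' @param x_a,x_b ordinal 0-4 severity columns, positively correlated.
#' @return Numeric severity-scale vector in `[0, 4]`, with attributes
#'   `loading` and `correlation`.
#' @export
consolidate_pair <- function(x_a, x_b) {
  stopifnot(length(x_a) == length(x_b))
  if (any(x_a != round(x_a)) || any(x_b != round(x_b)) ||
      any(c(x_a, x_b) < 0) || any(c(x_a, x_b) > 4)) {
    stop("severity columns must be ordinal 0-4")
  }
  if (sd(x_a) == 0 || sd(x_b) == 0) stop("constant severity column")
  r <- cor(x_a, x_b)
  if (r <= 0) {
    stop(sprintf(
      "columns correlate non-positively (r = %.3f); consolidation is not advised",
      r
    ))
  }
  z <- scale(x_a)[, 1L] + scale(x_b)[, 1L]
  score <- 4 * (z - min(z)) / (max(z) - min(z))
  attr(score, "loading") <- sqrt(r)
  attr(score, "correlation") <- r
  score
}

#' Apply a redundancy report to a severity matrix
#'
#' Replaces each flagged pair by its consolidated column (named `"a+b"`),
#' dropping the originals.
#'
#' Pairs whose columns correlate non-positively are left unmerged (the
#' factor model would be ill-posed there) and recorded under `skipped`.
#'
#' @param severity patients x symptoms matrix.
#' @param report a `redundancy_report` from [detect_redundant_pairs()].
#' @return List with `severity` (the consolidated matrix) and `map` (a
#'   `consolidation_map`: `merged` list of `(a, b, name)`, `skipped` list,
#'   and `resulting_symptom_count`).
#' @export
consolidate_redundant <- function(severity, report) {
  stopifnot(inherits(report, "redundancy_report"))
  severity <- as.matrix(severity)
  merged <- list()
  skipped <- list()
  drop <- character()
  new_cols <- list()
  fp <- report$flagged_pairs
  for (k in seq_len(nrow(fp))) {
    a <- fp$a[k]
    b <- fp$b[k]
    if (!a %in% colnames(severity) || !b %in% colnames(severity)) next
    if (sd(severity[, a]) == 0 || sd(severity[, b]) == 0) {
      skipped[[length(skipped) + 1L]] <-
        list(a = a, b = b, reason = "constant column")
      next
    }
    if (cor(severity[, a], severity[, b]) <= 0) {
      skipped[[length(skipped) + 1L]] <-
        list(a = a, b = b, reason = "non-positive correlation")
      next
    }
    nm <- paste0(a, "+", b)
    new_cols[[nm]] <- consolidate_pair(severity[, a], severity[, b])
    drop <- c(drop, a, b)
    merged[[length(merged) + 1L]] <- list(a = a, b = b, name = nm)
  }
  out <- severity[, setdiff(colnames(severity), drop), drop = FALSE]
  if (length(new_cols)) {
    out <- cbind(out, do.call(cbind, lapply(new_cols, as.numeric)))
    colnames(out)[(ncol(out) - length(new_cols) + 1L):ncol(out)] <- names(new_cols)
  }
  map <- structure(
    list(merged = merged, skipped = skipped,
         resulting_symptom_count = ncol(out)),
    class = "consolidation_map"
  )
  list(severity = out, map = map)
}

#' Nonparanormal (rank-based Gaussian) transform
#'
#' Maps each column through its average ranks to normal quantiles,
#' `Phi^-1(r_i / (n + 1))`, then rescales to unit sample variance. Ties —
#' ubiquitous in 0-4 ordinal data — share the average rank, so the transform
#' depends on the data only through the within-column ordering and is
#' invariant to any strictly monotone per-column recoding.
#'
#' @param severity patients x symptoms matrix with no constant column.
#' @return Real-valued matrix of the same shape, each column mean-centred on
#'   the rank scale with unit sample variance.
#' @export
nonparanormal_transform <- function(severity) {
  severity <- as.matrix(severity)
  const <- which(apply(severity, 2L, function(x) length(unique(x)) < 2L))
  if (length(const)) {
    nm <- colnames(severity)[const]
    if (is.null(nm)) nm <- as.character(const)
    stop("constant symptom column(s): ", paste(nm, collapse = ", "))
  }
  n <- nrow(severity)
  out <- apply(severity, 2L, function(x) {
    q <- qnorm(rank(x, ties.method = "average") / (n + 1))
    q / sd(q)
  })
  dimnames(out) <- dimnames(severity)
  out
}

#' Shapiro-Wilk normality screen
#'
#' Per-column Shapiro-Wilk statistic and p-value, reported for description
#' only: the nonparanormal transform is applied unconditionally regardless
#' of the outcome. For columns longer than 5000 (the test's implementation
#' limit) an evenly spaced deterministic subsample of 5000 is used.
#'
#' @param severity patients x symptoms matrix.
#' @return data.frame with `symptom`, `W`, `p_value`.
#' @export
shapiro_screen <- function(severity) {
  severity <- as.matrix(severity)
  n <- nrow(severity)
  idx <- if (n > 5000L) unique(round(seq(1L, n, length.out = 5000L))) else seq_len(n)
  res <- apply(severity[idx, , drop = FALSE], 2L, function(x) {
    s <- shapiro.test(x)
    c(W = unname(s$statistic), p_value = s$p.value)
  })
  nm <- colnames(severity)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(severity)))
  data.frame(symptom = nm, W = res["W", ], p_value = res["p_value", ],
             row.names = NULL, stringsAsFactors = FALSE)
}
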