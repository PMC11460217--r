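# Second-order patient clustering: each patient's symptom co-severity is
# summarized by the concordance matrix X X^T / 100 of their severity vector;
# patients are compared by the Adjusted Rand Index between the discrete
# labelings their concordance matrices induce on the symptom-pair cells; the
# resulting similarity matrix is clustered with walktrap.

#' Per-patient concordance matrix
#'
#' The outer product of a patient's severity vector divided by 100,
#' encoding the co-severity of every symptom pair for that patient. With
#' severities in 0-4, entries lie in `[0, 0.16]`.
#'
#' @param x integer severity vector (values 0-4).
#' @return Symmetric `p x p` matrix `x %o% x / 100`.
#' @export
concordance_matrix <- function(x) {
  if (any(x != round(x)) || any(x < 0) || any(x > 4)) {
    stop("severities must be integers in 0..4")
  }
  outer(x, x) / 100
}

# Upper triangle (including the diagonal) of a concordance matrix read as
# integer cell labels 0..16 (the severity products, exact after undoing the
# /100 scaling).
concordance_cells <- function(m, scaled = TRUE) {
  v <- m[upper.tri(m, diag = TRUE)]
  if (scaled) v <- v * 100
  lab <- as.integer(round(v))
  if (max(abs(v - lab)) > 1e-8) {
    stop("concordance entries are not severity products on the expected grid")
  }
  lab
}

#' Adjusted Rand Index between two concordance matrices
#'
#' Reads the upper triangle (including the diagonal) of each matrix as a
#' labeling of the `p(p+1)/2` symptom-pair cells by its discrete value —
#' severity products are integers 0-16 scaled by 1/100, so the labels are
#' exact — and applies the standard pair-counting ARI formula to the two
#' labelings. When both labelings are constant (e.g. two all-zero severity
#' vectors) the raw formula is 0/0; this degenerate case is defined as 1 for
#' identical labelings and 0 otherwise.
#'
#' @param a,b concordance matrices of equal dimension (from
#'   [concordance_matrix()]).
#' @return ARI value in `[-1, 1]`.
#' @export
ari_between_matrices <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b))) stop("concordance matrices differ in dimension")
  la <- concordance_cells(a)
  lb <- concordance_cells(b)
  # recode to 0..K-1 (ARI depends only on label identity, so this also makes
  # the result invariant to the /100 scaling)
  lev <- unique(c(la, lb))
  ari_labels_cpp(match(la, lev) - 1L, match(lb, lev) - 1L, length(lev))
}

#' Patient similarity matrix
#'
#' All pairwise ARI values between patients' concordance matrices. The
#' per-patient cell labelings are computed once and the pairwise ARI is
#' evaluated in compiled code, so the cost is `O(n^2 p^2)` with a small
#' constant.
#'
#' @param severity patients x symptoms integer severity matrix (0-4).
#' @return Symmetric `n x n` matrix of ARI values with unit diagonal and
#'   patient ids as dimnames.
#' @export
patient_similarity <- function(severity) {
  severity <- as.matrix(severity)
  n <- nrow(severity)
  if (n < 3L) stop("need at least 3 patients")
  if (any(severity != round(severity)) || any(severity < 0) || any(severity > 4)) {
    stop("severities must be integers in 0..4")
  }
  p <- ncol(severity)
  ut <- upper.tri(matrix(0, p, p), diag = TRUE)
  labels <- apply(severity, 1L, function(x) {
    m <- outer(as.integer(x), as.integer(x))
    as.integer(m[ut])
  })
  sim <- ari_pairwise_cpp(labels, 17L)
  ids <- rownames(severity)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Detect patient subgroups from the similarity matrix
#'
#' Floors negative similarities at zero, uses the similarity matrix as the
#' weighted adjacency of a complete graph, and runs walktrap community
#' detection `runs` times under permuted node orderings (the merge procedure
#' is deterministic given the node order, so order permutation is the
#' natural randomization). The final labels come from the first run (on the
#' original ordering); the consistency report is the matrix of pairwise ARI
#' values between the runs' labelings.
#'
#' @param similarity symmetric patient-similarity matrix.
#' @param runs number of clustering runs (default 11).
#' @param seed integer seed for the order permutations.
#' @param steps walktrap random-walk length.
#' @return List with `assignment` (a [cluster_assignment()] over patients)
#'   and `consistency` (`runs x runs` ARI matrix).
#' @export
detect_patient_subgroups <- function(similarity, runs = 11L, seed = 1L,
                                     steps = 4L) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity),
            runs >= 1)
  w <- similarity
  w[w < 0] <- 0
  diag(w) <- 0
  if (all(w == 0)) stop("similarity matrix has no positive entries: no structure to cluster")
  n <- nrow(w)
  set.seed(seed)
  labelings <- vector("list", runs)
  for (r in seq_len(runs)) {
    perm <- if (r == 1L) seq_len(n) else sample.int(n)
    asg <- walktrap_on_adjacency(w[perm, perm, drop = FALSE], steps = steps,
                                 method = "walktrap")
    lab <- integer(n)
    lab[perm] <- asg$labels
    labelings[[r]] <- lab
  }
  consistency <- matrix(1, runs, runs)
  if (runs > 1L) {
    for (i in seq_len(runs - 1L)) {
      for (j in (i + 1L):runs) {
        v <- ari_partition(labelings[[i]], labelings[[j]])
        consistency[i, j] <- v
        consistency[j, i] <- v
      }
    }
  }
  labels <- setNames(labelings[[1L]], rownames(similarity))
  list(
    assignment = cluster_assignment(labels, method = "walktrap"),
    consistency = consistency
  )
}

#' Per-subgroup symptom severity profiles
#'
#' Mean severity per symptom within each subgroup with a normal-approximation
#' 95% interval (`mean +/- 1.96 sd / sqrt(n_g)`), plus the cohort mean for
#' reference. Subgroups of size 1 get missing intervals.
#'
#' @param severity patients x symptoms matrix.
#' @param labels a [cluster_assignment()] over patients (or a label vector).
#' @return Long data.frame: `subgroup`, `symptom`, `n`, `mean`, `ci_lo`,
#'   `ci_hi`, `cohort_mean`.
#' @export
subgroup_profiles <- function(severity, labels) {
  severity <- as.matrix(severity)
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  if (length(labels) != nrow(severity)) {
    stop("one label per patient required")
  }
  syms <- colnames(severity)
  if (is.null(syms)) syms <- as.character(seq_len(ncol(severity)))
  cohort_mean <- colMeans(severity)
  out <- lapply(sort(unique(labels)), function(g) {
    rows <- severity[labels == g, , drop = FALSE]
    ng <- nrow(rows)
    if (ng == 0L) stop(sprintf("subgroup %s is empty", g))
    m <- colMeans(rows)
    if (ng > 1L) {
      se <- apply(rows, 2L, sd) / sqrt(ng)
      lo <- m - 1.96 * se
      hi <- m + 1.96 * se
    } else {
      lo <- hi <- rep(NA_real_, ncol(rows))
    }
    data.frame(
      subgroup = g, symptom = syms, n = ng, mean = unname(m),
      ci_lo = unname(lo), ci_hi = unname(hi),
      cohort_mean = unname(cohort_mean),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
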