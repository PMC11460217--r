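#' Cluster assignment container
#'
#' A named integer vector of community labels together with the method that
#' produced it. Labels are always recoded to contiguous ids 1..k in order of
#' first appearance, so that two assignments can be compared by
#' [ari_partition()] without worrying about arbitrary id choices.
#'
#' @param labels integer (or coercible) vector of community ids, one per
#'   node/patient; names are kept if present.
#' @param method character tag recording how the assignment was produced.
#' @param sort_levels recode in sorted label order instead of order of first
#'   appearance (used for planted ground truth, where ids carry meaning).
#' @return An object of class `cluster_assignment`: a list with `labels`
#'   (named integer vector, ids contiguous from 1), `n_communities`, `method`.
#' @export
cluster_assignment <- function(labels, method = "manual", sort_levels = FALSE) {
  if (length(labels) == 0L) stop("empty label vector")
  if (anyNA(labels)) stop("labels must not contain NA")
  lev <- if (sort_levels) sort(unique(labels)) else unique(labels)
  ids <- as.integer(factor(labels, levels = lev))
  names(ids) <- names(labels)
  structure(
    list(labels = ids, n_communities = max(ids), method = method),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %d items in %d communities (method: %s)\n",
    length(x$labels), x$n_communities, x$method
  ))
  print(table(x$labels))
  invisible(x)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, via
#' the standard pair-counting contingency-table formula. Returns 1 for
#' identical partitions and values near 0 for independent ones. The
#' degenerate case in which both labelings put every item in a single group
#' (the raw formula is 0/0) is defined as 1 when the labelings are identical
#' and 0 otherwise.
#'
#' @param a,b label vectors of equal length, or `cluster_assignment` objects.
#' @return A single numeric ARI value in `[-1, 1]`.
#' @export
ari_partition <- function(a, b) {
  if (inherits(a, "cluster_assignment")) a <- a$labels
  if (inherits(b, "cluster_assignment")) b <- b$labels
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) == 0L) stop("empty label vectors")
  # canonicalize each labeling separately: partitions compare by structure,
  # not by the arbitrary ids attached to the groups
  x <- match(a, unique(a)) - 1L
  y <- match(b, unique(b)) - 1L
  ari_labels_cpp(x, y, max(length(unique(a)), length(unique(b))))
}
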