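# Regularized Gaussian graphical model: graphical lasso over a log-spaced
# penalty path, model selection by the Extended Bayesian Information
# Criterion, edges reported as partial correlations.

#' Sample correlation matrix
#'
#' @param x numeric matrix (patients x symptoms), typically the
#'   nonparanormal-transformed severities.
#' @return Symmetric correlation matrix with unit diagonal. Warns when
#'   `n <= p` (the estimator is still defined but unstable) and when two
#'   columns are exactly collinear.
#' @export
sample_correlation <- function(x) {
  x <- as.matrix(x)
  const <- which(apply(x, 2L, sd) == 0)
  if (length(const)) {
    nm <- colnames(x)[const]
    if (is.null(nm)) nm <- as.character(const)
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  if (nrow(x) <= ncol(x)) {
    warning(sprintf("n (%d) <= p (%d): correlation matrix may be singular",
                    nrow(x), ncol(x)))
  }
  s <- cor(x)
  off <- abs(s[upper.tri(s)])
  if (any(off >= 1 - 1e-12)) {
    warning("perfectly collinear columns detected (off-diagonal correlation of 1); downstream estimation may fail")
  }
  s
}

#' Graphical lasso fit at a single penalty
#'
#' Estimates the sparse precision matrix `K` maximizing the L1-penalized
#' Gaussian log-likelihood `log det K - tr(SK) - lambda * sum_{i != j} |K_ij|`
#' by block coordinate descent on the working covariance, to a mean
#' parameter-change tolerance of `tol` (relative to the mean absolute
#' off-diagonal of `S`). Off-diagonal zeros in the returned matrix are exact
#' (they come from the soft-thresholding step, not from rounding).
#'
#' @param s correlation (or covariance) matrix.
#' @param lambda nonnegative penalty; at `lambda = 0` the solution is
#'   `solve(s)`.
#' @param tol convergence tolerance (default 1e-6).
#' @param max_sweeps maximum full passes over the columns.
#' @param warm optional warm start: a previous `glasso_fit` result (used
#'   internally along the penalty path).
#' @return List of class `glasso_fit`: `K` (precision), `W` (estimated
#'   covariance), `lambda`, `sweeps`.
#' @export
glasso_fit <- function(s, lambda, tol = 1e-6, max_sweeps = 2000L, warm = NULL) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s), lambda >= 0)
  if (max(abs(s - t(s))) > 1e-8) stop("s must be symmetric")
  w0 <- b0 <- NULL
  if (!is.null(warm)) {
    w0 <- warm$W
    b0 <- warm$B
  }
  fit <- glasso_cd(s, lambda, tol, as.integer(max_sweeps), w0, b0)
  if (!fit$converged) {
    stop(sprintf(
      "graphical lasso did not converge (lambda = %.4g, %d sweeps, tol = %.1g)",
      lambda, fit$sweeps, tol
    ))
  }
  dimnames(fit$K) <- dimnames(s)
  structure(
    list(K = fit$K, W = fit$W, B = fit$B, lambda = lambda, sweeps = fit$sweeps),
    class = "glasso_fit"
  )
}

#' Extended Bayesian Information Criterion for a Gaussian graphical model
#'
#' `EBIC = -n (log det K - tr(SK)) + |E| log n + 4 |E| gamma log p`, where
#' `|E|` counts the nonzero upper-triangle entries of `K`. `gamma = 0`
#' recovers the ordinary BIC; larger values favour sparser graphs.
#'
#' @param k precision matrix (positive definite).
#' @param s sample correlation matrix.
#' @param n number of observations.
#' @param gamma extended-penalty weight (conventionally 0.5).
#' @return Scalar EBIC value (smaller is better).
#' @export
ebic <- function(k, s, n, gamma = 0.5) {
  p <- nrow(k)
  det_k <- determinant(k, logarithm = TRUE)
  if (det_k$sign <= 0) stop("precision matrix must be positive definite")
  n_edges <- sum(k[upper.tri(k)] != 0)
  loglik_term <- as.numeric(det_k$modulus) - sum(s * k)
  -n * loglik_term + n_edges * log(n) + 4 * n_edges * gamma * log(p)
}

#' Construct a symptom network
#'
#' @param weights symmetric partial-correlation matrix, zero diagonal.
#' @param lambda_selected,gamma,n_used selection metadata.
#' @return Object of class `symptom_network` with fields `nodes`, `weights`,
#'   `lambda_selected`, `gamma`, `n_used`.
#' @export
symptom_network <- function(weights, lambda_selected = NA_real_, gamma = NA_real_,
                            n_used = NA_integer_) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (max(abs(weights - t(weights))) > 1e-10) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  if (any(abs(weights[upper.tri(weights)]) >= 1)) {
    stop("partial correlations must have absolute value < 1")
  }
  nodes <- colnames(weights)
  if (is.null(nodes)) {
    nodes <- sprintf("V%02d", seq_len(ncol(weights)))
    dimnames(weights) <- list(nodes, nodes)
  }
  structure(
    list(nodes = nodes, weights = weights, lambda_selected = lambda_selected,
         gamma = gamma, n_used = as.integer(n_used)),
    class = "symptom_network"
  )
}

#' @export
print.symptom_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf(
    "<symptom_network> %d nodes, %d edges (lambda = %.4g, gamma = %.2g, n = %d)\n",
    length(x$nodes), ne, x$lambda_selected, x$gamma, x$n_used
  ))
  invisible(x)
}

#' Number of nonzero edges
#' @param network a `symptom_network`.
#' @return Integer count of nonzero upper-triangle weights.
#' @export
n_edges <- function(network) {
  sum(network$weights[upper.tri(network$weights)] != 0)
}

precision_to_partial <- function(k) {
  d <- sqrt(diag(k))
  p <- -k / outer(d, d)
  diag(p) <- 0
  p <- (p + t(p)) / 2
  dimnames(p) <- dimnames(k)
  p
}

#' EBIC-selected regularized partial-correlation network
#'
#' Fits the graphical lasso along a log-spaced penalty grid from
#' `lambda_max` (the largest off-diagonal absolute correlation — the
#' smallest penalty that empties the graph) down to
#' `lambda_min_ratio * lambda_max`, warm-starting each fit from the previous
#' one, scores every model by [ebic()], and converts the minimizing
#' precision matrix to partial correlations
#' `rho_ij = -K_ij / sqrt(K_ii K_jj)`.
#'
#' @param x transformed data matrix (patients x symptoms).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambdas grid size (default 100).
#' @param lambda_min_ratio ratio of smallest to largest penalty (default 0.01).
#' @param tol graphical-lasso convergence tolerance.
#' @return List with `network` (a [symptom_network()]) and `path` (a
#'   `glasso_path`: `lambdas`, `precisions`, `ebics`, `edge_counts`). When
#'   the selected model has no edges the network is returned empty with a
#'   warning, as can happen for cohorts with minimal symptom co-severity.
#' @export
select_network <- function(x, gamma = 0.5, n_lambdas = 100L,
                           lambda_min_ratio = 0.01, tol = 1e-6) {
  x <- as.matrix(x)
  s <- sample_correlation(x)
  n <- nrow(x)
  p <- ncol(x)
  lambda_max <- max(abs(s[upper.tri(s)]))
  if (lambda_max == 0) lambda_max <- 1e-4   # fully independent columns
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  precisions <- vector("list", n_lambdas)
  ebics <- numeric(n_lambdas)
  edge_counts <- integer(n_lambdas)
  fit <- NULL
  for (i in seq_along(lambdas)) {
    fit <- glasso_fit(s, lambdas[i], tol = tol, warm = fit)
    precisions[[i]] <- fit$K
    ebics[i] <- ebic(fit$K, s, n, gamma)
    edge_counts[i] <- sum(fit$K[upper.tri(fit$K)] != 0)
  }
  best <- which.min(ebics)
  k <- precisions[[best]]
  weights <- precision_to_partial(k)
  net <- symptom_network(weights, lambda_selected = lambdas[best],
                         gamma = gamma, n_used = n)
  if (n_edges(net) == 0L) {
    warning("selected network has no edges: the data are too sparse or weakly dependent for a stable network")
  }
  path <- structure(
    list(lambdas = lambdas, precisions = precisions, ebics = ebics,
         edge_counts = edge_counts),
    class = "glasso_path"
  )
  list(network = net, path = path)
}
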