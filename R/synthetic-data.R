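# Synthetic cohort generation: Gaussian copula with planted block correlation
# structure, planted patient subgroups (latent mean shifts), and covariates
# whose subgroup-conditional distributions imply known multinomial log-odds.

#' Precision matrix with planted block structure
#'
#' Builds the latent correlation matrix of a block-exchangeable model —
#' pairs inside the same symptom block correlate at `within_block_corr`,
#' pairs in different blocks at `between_block_corr`, symptoms outside any
#' block are independent — and returns its inverse (the precision matrix).
#' This is the ground truth against which graphical-model recovery is
#' tested: when `between_block_corr` is 0 the precision is exactly block
#' diagonal, so every between-block partial correlation is exactly zero.
#'
#' @param symptom_blocks list of disjoint integer index vectors (the planted
#'   clusters); indices in `1..p`.
#' @param within_block_corr latent correlation inside a block, in `[0, 1)`.
#' @param between_block_corr latent correlation between blocks, in `[0, 1)`.
#' @param p total number of symptoms; defaults to the largest block index.
#' @return A `p x p` symmetric positive-definite precision matrix.
#' @export
planted_precision <- function(symptom_blocks, within_block_corr,
                              between_block_corr, p = NULL) {
  idx <- unlist(symptom_blocks)
  if (length(symptom_blocks) == 0L || any(lengths(symptom_blocks) == 0L)) {
    stop("symptom_blocks must be non-empty index sets")
  }
  if (anyDuplicated(idx)) stop("symptom_blocks must be disjoint")
  if (is.null(p)) p <- max(idx)
  if (max(idx) > p || min(idx) < 1L) stop("block indices must lie in 1..p")
  if (within_block_corr < 0 || within_block_corr >= 1 ||
      between_block_corr < 0 || between_block_corr >= 1) {
    stop("correlations must lie in [0, 1)")
  }
  sigma <- matrix(between_block_corr, p, p)
  out_of_block <- setdiff(seq_len(p), idx)
  sigma[out_of_block, ] <- 0
  sigma[, out_of_block] <- 0
  for (blk in symptom_blocks) {
    sigma[blk, blk] <- within_block_corr
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "requested block correlations give a non-positive-definite matrix (smallest eigenvalue %.3g)",
      min(ev)
    ))
  }
  if (between_block_corr == 0) {
    # invert block-wise so off-block precision entries are exactly zero
    omega <- diag(p)
    for (blk in symptom_blocks) {
      omega[blk, blk] <- solve(sigma[blk, blk, drop = FALSE])
    }
  } else {
    omega <- solve(sigma)
    omega <- (omega + t(omega)) / 2
  }
  omega
}

#' Specify a synthetic cohort
#'
#' Collects all generation parameters: the planted symptom-block correlation
#' structure, patient subgroups as latent mean-shift profiles, covariate
#' effects expressed as the true multinomial log-odds of subgroup membership
#' (relative to subgroup 1), and the thresholds that cut the latent normal
#' scale into ordinal severities 0-4.
#'
#' @param n_patients number of patients to draw.
#' @param p number of symptoms.
#' @param symptom_blocks list of disjoint symptom-index sets (planted symptom
#'   clusters); symptoms outside every block are independent noise symptoms.
#' @param within_block_corr,between_block_corr latent correlations, in `[0,1)`.
#' @param subgroup_profiles list of length-`p` numeric vectors: per-subgroup
#'   mean shifts (in latent SD units) added to the latent scale.
#' @param subgroup_proportions mixing weights, summing to 1.
#' @param covariate_effects list with one element per subgroup, each a list
#'   with entries `age` (scalar log-odds per year), `treatment` (scalar
#'   log-odds for treated vs. untreated) and `diagnosis` (vector of log-odds
#'   for each non-reference diagnosis level). Subgroup 1 is the reference
#'   and must be all zeros.
#' @param thresholds 4 strictly increasing cutpoints mapping the latent scale
#'   to severities 0-4. The defaults give a zero-inflated profile with about
#'   half the cohort at severity 0 per symptom.
#' @param covariate_base reference-subgroup covariate distribution: `age_mean`,
#'   `age_sd`, `treatment_prob`, `diagnosis_probs` (named, sums to 1).
#' @param latent_corr optional `p x p` correlation matrix overriding the
#'   block-exchangeable latent structure (e.g. to plant a hub symptom); the
#'   block labels are still reported as the cluster ground truth.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return A `cohort_spec` object (validated list of the above).
#' @export
cohort_spec <- function(n_patients,
                        p,
                        symptom_blocks,
                        within_block_corr = 0.4,
                        between_block_corr = 0.05,
                        subgroup_profiles = list(rep(0, p)),
                        subgroup_proportions = rep(1 / length(subgroup_profiles), length(subgroup_profiles)),
                        covariate_effects = default_covariate_effects(length(subgroup_profiles)),
                        thresholds = c(0, 0.85, 1.5, 2.1),
                        covariate_base = list(
                          age_mean = 60, age_sd = 12, treatment_prob = 0.6,
                          diagnosis_probs = c(breast = 0.6, gi = 0.2, other = 0.2)
                        ),
                        latent_corr = NULL,
                        seed = 1L) {
  stopifnot(n_patients >= 1, p >= 2)
  idx <- unlist(symptom_blocks)
  if (any(lengths(symptom_blocks) == 0L)) stop("empty symptom block")
  if (anyDuplicated(idx) || max(idx) > p || min(idx) < 1L) {
    stop("symptom_blocks must be disjoint subsets of 1..p")
  }
  g <- length(subgroup_profiles)
  if (any(vapply(subgroup_profiles, length, 1L) != p)) {
    stop("each subgroup profile must have length p")
  }
  if (length(subgroup_proportions) != g) {
    stop("one proportion per subgroup required")
  }
  if (abs(sum(subgroup_proportions) - 1) > 1e-12) {
    stop("subgroup proportions must sum to 1")
  }
  if (any(subgroup_proportions <= 0)) stop("zero-probability subgroup")
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 4 strictly increasing reals")
  }
  if (length(covariate_effects) != g) {
    stop("one covariate_effects entry per subgroup required")
  }
  n_diag <- length(covariate_base$diagnosis_probs)
  for (ce in covariate_effects) {
    stopifnot(
      is.numeric(ce$age), is.numeric(ce$treatment),
      length(ce$diagnosis) == n_diag - 1L
    )
  }
  if (any(abs(unlist(covariate_effects[[1]])) > 0)) {
    stop("subgroup 1 is the reference: its covariate effects must be zero")
  }
  if (!is.null(latent_corr)) {
    stopifnot(is.matrix(latent_corr), nrow(latent_corr) == p,
              isSymmetric(latent_corr))
  }
  structure(
    list(
      n_patients = as.integer(n_patients), p = as.integer(p),
      symptom_blocks = symptom_blocks,
      within_block_corr = within_block_corr,
      between_block_corr = between_block_corr,
      subgroup_profiles = subgroup_profiles,
      subgroup_proportions = subgroup_proportions,
      covariate_effects = covariate_effects,
      thresholds = thresholds,
      covariate_base = covariate_base,
      latent_corr = latent_corr,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Null covariate effects
#'
#' @param n_subgroups number of subgroups.
#' @param n_diagnosis_levels number of diagnosis categories.
#' @return A list of per-subgroup all-zero effect sets (no covariate signal).
#' @export
default_covariate_effects <- function(n_subgroups, n_diagnosis_levels = 3L) {
  lapply(seq_len(n_subgroups), function(i) {
    list(age = 0, treatment = 0, diagnosis = rep(0, n_diagnosis_levels - 1L))
  })
}

#' Default three-block, three-subgroup cohort specification
#'
#' The reference study conditions used throughout the test-suite and the
#' worked examples: 20 symptoms in three planted blocks of five (five noise
#' symptoms), latent within-block correlation 0.4, three patient subgroups
#' whose profiles elevate one disjoint block each by 1.5 latent SD, and a
#' treatment effect of log-odds 1.2 on membership in subgroup 2.
#'
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n_patients = 1000, seed = 1L) {
  p <- 20L
  blocks <- list(1:5, 6:10, 11:15)
  profiles <- lapply(1:3, function(g) {
    pr <- rep(0, p)
    pr[blocks[[g]]] <- 1.5
    pr
  })
  eff <- default_covariate_effects(3L)
  eff[[2]]$treatment <- 1.2
  eff[[2]]$age <- 0.02
  eff[[3]]$age <- -0.02
  cohort_spec(
    n_patients = n_patients, p = p, symptom_blocks = blocks,
    within_block_corr = 0.4, between_block_corr = 0.05,
    subgroup_profiles = profiles,
    subgroup_proportions = c(0.4, 0.3, 0.3),
    covariate_effects = eff,
    seed = seed
  )
}

#' Three-subgroup cohort with disjoint dominant symptom constellations
#'
#' Study conditions for patient-subgroup recovery: three equally sized
#' subgroups, each elevating its own 5-symptom block by 3 latent SD over a
#' low-burden background (thresholds raised so background symptoms are
#' absent for roughly 84% of patients). Patients of different subgroups then
#' share few active co-severity cells — the disjoint-active-symptom regime
#' the second-order clustering is designed for.
#'
#' @param n_patients cohort size (default 300).
#' @param seed integer seed.
#' @return A `cohort_spec`.
#' @export
subgroup_cohort_spec <- function(n_patients = 300, seed = 1L) {
  p <- 20L
  blocks <- list(1:5, 6:10, 11:15)
  profiles <- lapply(1:3, function(g) {
    pr <- rep(0, p)
    pr[blocks[[g]]] <- 3
    pr
  })
  cohort_spec(
    n_patients = n_patients, p = p, symptom_blocks = blocks,
    within_block_corr = 0.4, between_block_corr = 0.05,
    subgroup_profiles = profiles,
    subgroup_proportions = rep(1 / 3, 3),
    thresholds = c(1.0, 1.6, 2.2, 2.8),
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Draws each patient's subgroup from the mixing proportions, then a latent
#' multivariate-normal severity vector (correlation from the planted block
#' structure, mean from the subgroup profile), cut at the thresholds into
#' ordinal severities 0-4 (a Gaussian copula with thresholding — the same
#' nonparanormal model the downstream network estimator assumes, so that
#' parameter-recovery tests are well-posed). Covariates are drawn with
#' subgroup-conditional distributions chosen so that the specified
#' `covariate_effects` are exactly the population multinomial log-odds of
#' subgroup membership given the covariates:
#' age is normal with a mean shifted by `beta_age * age_sd^2`, treatment is
#' Bernoulli with log-odds shifted by `beta_treatment`, and diagnosis is
#' categorical with exponentially tilted probabilities.
#'
#' @param spec a [cohort_spec()].
#' @return A `synthetic_cohort`: list with `severity` (integer matrix,
#'   patients x symptoms), `true_symptom_clusters` and `true_subgroups`
#'   ([cluster_assignment]s; noise symptoms are singleton clusters),
#'   `covariates` (data.frame with `patient_id`, `age`, `treatment`,
#'   `diagnosis`), and `latent_precision`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p <- spec$p
  n <- spec$n_patients
  omega <- planted_precision(
    spec$symptom_blocks, spec$within_block_corr, spec$between_block_corr, p
  )
  sigma <- if (is.null(spec$latent_corr)) {
    s <- solve(omega)
    (s + t(s)) / 2
  } else {
    spec$latent_corr
  }

  g <- length(spec$subgroup_profiles)
  subgroup <- sample.int(g, n, replace = TRUE, prob = spec$subgroup_proportions)
  z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  mu <- do.call(rbind, spec$subgroup_profiles)[subgroup, , drop = FALSE]
  z <- z + mu
  severity <- matrix(findInterval(z, spec$thresholds), n, p)
  storage.mode(severity) <- "integer"
  symptom_names <- sprintf("S%02d", seq_len(p))
  patient_ids <- sprintf("P%04d", seq_len(n))
  dimnames(severity) <- list(patient_ids, symptom_names)

  cb <- spec$covariate_base
  age <- rnorm(n,
    mean = cb$age_mean +
      vapply(subgroup, function(s) spec$covariate_effects[[s]]$age, 1) * cb$age_sd^2,
    sd = cb$age_sd
  )
  treat_logit <- log(cb$treatment_prob / (1 - cb$treatment_prob)) +
    vapply(subgroup, function(s) spec$covariate_effects[[s]]$treatment, 1)
  treatment <- as.integer(runif(n) < 1 / (1 + exp(-treat_logit)))
  diag_levels <- names(cb$diagnosis_probs)
  diagnosis <- character(n)
  for (s in seq_len(g)) {
    rows <- which(subgroup == s)
    if (!length(rows)) next
    tilt <- c(0, spec$covariate_effects[[s]]$diagnosis)
    pr <- cb$diagnosis_probs * exp(tilt)
    pr <- pr / sum(pr)
    diagnosis[rows] <- sample(diag_levels, length(rows), replace = TRUE, prob = pr)
  }
  covariates <- data.frame(
    patient_id = patient_ids,
    age = age,
    treatment = treatment,
    diagnosis = factor(diagnosis, levels = diag_levels),
    stringsAsFactors = FALSE
  )

  # symptom cluster truth: block id per member, singletons for noise symptoms
  sym_labels <- integer(p)
  for (b in seq_along(spec$symptom_blocks)) {
    sym_labels[spec$symptom_blocks[[b]]] <- b
  }
  nb <- length(spec$symptom_blocks)
  loose <- which(sym_labels == 0L)
  sym_labels[loose] <- nb + seq_along(loose)
  names(sym_labels) <- symptom_names
  subgroup_named <- setNames(subgroup, patient_ids)

  structure(
    list(
      severity = severity,
      true_symptom_clusters = cluster_assignment(sym_labels, "planted", sort_levels = TRUE),
      true_subgroups = cluster_assignment(subgroup_named, "planted", sort_levels = TRUE),
      covariates = covariates,
      latent_precision = omega,
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients x %d symptoms, %d planted subgroups, seed %d\n",
    nrow(x$severity), ncol(x$severity),
    x$true_subgroups$n_communities, x$spec$seed
  ))
  invisible(x)
}
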