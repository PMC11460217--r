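# End-to-end orchestration: preprocess -> network -> communities/centralities
# -> stability -> patient subgroups (with per-subgroup networks behind a
# sparsity gate) -> multinomial regression. All randomness flows from a
# single root seed, split per stage, so a fixed configuration reruns
# bit-identically.

#' Read a severity CSV
#'
#' Expects a header row, a `patient_id` first column and integer severities
#' 0-4 (empty cells allowed, read as NA).
#'
#' @param path file path.
#' @return Integer matrix with patient ids as rownames.
#' @export
read_severity_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("severity CSV must have a patient_id column")
  ids <- as.character(df$patient_id)
  m <- as.matrix(df[, setdiff(names(df), "patient_id"), drop = FALSE])
  storage.mode(m) <- "numeric"
  bad <- which(!is.na(m) & (m != round(m) | m < 0 | m > 4), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "severity out of range 0..4 at row %s, column '%s' (value %s)",
      ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], m[bad[1L, , drop = FALSE]]
    ))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Read a covariate CSV aligned to a severity matrix
#'
#' @param path file path.
#' @param severity optional severity matrix whose patient ids must all be
#'   present (an error lists any missing ids).
#' @return data.frame with `patient_id` first, character columns as factors.
#' @export
read_covariates_csv <- function(path, severity = NULL) {
  df <- read.csv(path, stringsAsFactors = TRUE)
  if (!"patient_id" %in% names(df)) stop("covariate CSV must have a patient_id column")
  df$patient_id <- as.character(df$patient_id)
  if (!is.null(severity)) {
    missing_ids <- setdiff(rownames(severity), df$patient_id)
    if (length(missing_ids)) {
      stop("covariate file missing patient id(s): ",
           paste(head(missing_ids, 10L), collapse = ", "))
    }
    df <- df[match(rownames(severity), df$patient_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a severity matrix as CSV
#' @param severity patients x symptoms matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_severity_csv <- function(severity, path) {
  df <- data.frame(patient_id = rownames(severity), severity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end analysis. Exactly
#' one input source is required: either `severity` (+ `covariates`) in
#' memory, paths to CSV files, or a [cohort_spec()] to simulate.
#'
#' @param severity matrix, CSV path, or NULL.
#' @param covariates data.frame, CSV path, or NULL.
#' @param cohort optional [cohort_spec()] used when `severity` is NULL.
#' @param uva_threshold wTO redundancy cutoff in (0,1).
#' @param gamma EBIC hyperparameter.
#' @param n_lambdas penalty-grid size.
#' @param walktrap_steps random-walk length.
#' @param B stability resamples.
#' @param conf edge-interval confidence level.
#' @param runs subgroup-consistency clustering runs.
#' @param reference_group optional override for the regression reference.
#' @param subgroup_min_edge_ratio a subgroup network is kept only if its
#'   edge count is at least this multiple of p (default 0.5, i.e. p/2
#'   edges); sparser models are reported as skipped.
#' @param seed root seed (mandatory); per-stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(severity = NULL, covariates = NULL, cohort = NULL,
                            uva_threshold = 0.25, gamma = 0.5,
                            n_lambdas = 100L, walktrap_steps = 4L,
                            B = 1000L, conf = 0.95, runs = 11L,
                            reference_group = NULL,
                            subgroup_min_edge_ratio = 0.5,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(severity) && is.null(cohort)) {
    stop("provide severity data or a cohort_spec to simulate")
  }
  stopifnot(
    uva_threshold > 0, uva_threshold < 1, gamma >= 0, n_lambdas >= 2,
    walktrap_steps >= 1, B >= 1, conf > 0, conf < 1, runs >= 1,
    subgroup_min_edge_ratio >= 0
  )
  structure(
    list(
      severity = severity, covariates = covariates, cohort = cohort,
      uva_threshold = uva_threshold, gamma = gamma,
      n_lambdas = as.integer(n_lambdas),
      walktrap_steps = as.integer(walktrap_steps),
      B = as.integer(B), conf = conf, runs = as.integer(runs),
      reference_group = reference_group,
      subgroup_min_edge_ratio = subgroup_min_edge_ratio,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage_seed <- function(config, offset) {
  (config$seed + offset) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading (or simulation), redundancy
#' detection/consolidation and nonparanormal transformation, EBIC-selected
#' network estimation, walktrap communities and (bridge) centralities,
#' resampling stability, second-order patient clustering with per-subgroup
#' severity profiles and gated per-subgroup networks, and multinomial
#' regression of subgroup membership on the covariates. Progress is logged
#' at stage granularity with the counts a report would quote (patients,
#' symptoms, edges, clusters, subgroups).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all artifacts (CSV/JSON)
#'   plus a machine-readable manifest are written there and reruns with the
#'   same config are byte-identical.
#' @return A report bundle (list) with elements `cohort` (when simulated),
#'   `shapiro`, `redundancy`, `consolidation_map`, `transformed`, `network`,
#'   `path_edge_counts`, `symptom_clusters`, `centralities`, `stability`,
#'   `similarity`, `subgroups`, `consistency`, `profiles`,
#'   `subgroup_networks`, `regression`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()

  # --- stage 1: inputs ------------------------------------------------------
  if (is.null(config$severity)) {
    spec <- config$cohort
    spec$seed <- stage_seed(config, 1L)
    cohort <- generate_cohort(spec)
    severity <- cohort$severity
    covariates <- cohort$covariates
    report$cohort <- cohort
  } else {
    severity <- config$severity
    if (is.character(severity)) severity <- read_severity_csv(severity)
    covariates <- config$covariates
    if (is.character(covariates)) covariates <- read_covariates_csv(covariates, severity)
  }
  complete_rows <- stats::complete.cases(severity)
  if (any(!complete_rows)) {
    message(sprintf("dropping %d patient(s) with missing severities", sum(!complete_rows)))
    severity <- severity[complete_rows, , drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[complete_rows, , drop = FALSE]
  }
  message(sprintf("inputs: %d patients x %d symptoms", nrow(severity), ncol(severity)))
  report$severity <- severity

  # --- stage 2: preprocess --------------------------------------------------
  report$shapiro <- shapiro_screen(severity)
  wto <- weighted_topological_overlap(severity)
  report$redundancy <- detect_redundant_pairs(wto, config$uva_threshold)
  cons <- consolidate_redundant(severity, report$redundancy)
  report$consolidation_map <- cons$map
  transformed <- nonparanormal_transform(cons$severity)
  report$transformed <- transformed
  message(sprintf("preprocess: %d redundant pair(s) merged, %d symptoms analyzed",
                  nrow(report$redundancy$flagged_pairs),
                  cons$map$resulting_symptom_count))

  # --- stage 3: network -----------------------------------------------------
  sel <- select_network(transformed, gamma = config$gamma,
                        n_lambdas = config$n_lambdas)
  network <- sel$network
  report$network <- network
  report$path_edge_counts <- sel$path$edge_counts
  message(sprintf("network: %d nodes, %d edges (lambda = %.4g)",
                  length(network$nodes), n_edges(network),
                  network$lambda_selected))

  # --- stage 4: communities and centralities --------------------------------
  clusters <- walktrap_communities(network, steps = config$walktrap_steps)
  report$symptom_clusters <- clusters
  report$centralities <- centrality_table(network, clusters)
  message(sprintf("communities: %d symptom cluster(s)", clusters$n_communities))

  # --- stage 5: stability ---------------------------------------------------
  report$stability <- assess_stability(
    transformed, network, clusters,
    B = config$B, seed = stage_seed(config, 2L), conf = config$conf,
    gamma = config$gamma, n_lambdas = config$n_lambdas,
    steps = config$walktrap_steps
  )
  message(sprintf("stability: %d resamples, %d significant edge(s)",
                  config$B, nrow(report$stability$significant_edges)))

  # --- stage 6: patient subgroups -------------------------------------------
  sim <- patient_similarity(severity)
  report$similarity <- sim
  det <- detect_patient_subgroups(sim, runs = config$runs,
                                  seed = stage_seed(config, 3L),
                                  steps = config$walktrap_steps)
  report$subgroups <- det$assignment
  report$consistency <- det$consistency
  report$profiles <- subgroup_profiles(severity, det$assignment)
  message(sprintf("subgroups: %d patient subgroup(s), sizes %s",
                  det$assignment$n_communities,
                  paste(table(det$assignment$labels), collapse = "/")))

  # --- stage 7: per-subgroup networks (with sparsity gate) ------------------
  report$subgroup_networks <- list()
  for (g in seq_len(det$assignment$n_communities)) {
    rows <- det$assignment$labels == g
    res <- tryCatch({
      tg <- nonparanormal_transform(
        consolidate_redundant(severity[rows, , drop = FALSE],
                              report$redundancy)$severity
      )
      net_g <- suppressWarnings(
        select_network(tg, gamma = config$gamma,
                       n_lambdas = config$n_lambdas)$network
      )
      min_edges <- config$subgroup_min_edge_ratio * length(net_g$nodes)
      if (n_edges(net_g) < min_edges) {
        list(skipped = TRUE,
             reason = sprintf("sparse network (%d edges < %.0f): unstable, not reported",
                              n_edges(net_g), ceiling(min_edges)))
      } else {
        cl_g <- walktrap_communities(net_g, steps = config$walktrap_steps)
        list(skipped = FALSE, network = net_g, clusters = cl_g,
             centralities = centrality_table(net_g, cl_g))
      }
    }, error = function(e) list(skipped = TRUE, reason = conditionMessage(e)))
    if (isTRUE(res$skipped)) {
      message(sprintf("subgroup %d: network skipped (%s)", g, res$reason))
    }
    report$subgroup_networks[[g]] <- res
  }

  # --- stage 8: regression --------------------------------------------------
  if (!is.null(covariates) && det$assignment$n_communities >= 2L) {
    report$regression <- fit_multinomial(
      covariates, det$assignment, reference = config$reference_group
    )
    message(sprintf("regression: reference subgroup %s, AIC %.1f (null %.1f)",
                    report$regression$reference_group,
                    report$regression$aic, report$regression$null_aic))
  }

  report$manifest <- list(
    package = "symptomnet",
    version = as.character(utils::packageVersion("symptomnet")),
    seed = config$seed,
    config = config[setdiff(names(config), c("severity", "covariates", "cohort"))],
    config_hash = rlang::hash(config),
    n_patients = nrow(severity),
    n_symptoms_input = ncol(severity),
    n_symptoms_analyzed = ncol(transformed)
  )

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  invisible(report)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  wc <- function(x, file) write.csv(x, file.path(out_dir, file), row.names = FALSE)

  write_severity_csv(report$severity, file.path(out_dir, "severity.csv"))
  if (!is.null(report$cohort)) {
    wc(report$cohort$covariates, "covariates.csv")
    wj(list(symptom_clusters = as.list(report$cohort$true_symptom_clusters$labels),
            subgroups = as.list(report$cohort$true_subgroups$labels)),
       "truth.json")
  }
  wc(report$shapiro, "shapiro.csv")
  wj(list(threshold = report$redundancy$threshold_used,
          flagged_pairs = report$redundancy$flagged_pairs),
     "redundancy.json")
  wj(list(merged = report$consolidation_map$merged,
          resulting_symptom_count = report$consolidation_map$resulting_symptom_count),
     "consolidation.json")
  net <- report$network
  ut <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  wc(data.frame(node_a = net$nodes[ut[, 1L]], node_b = net$nodes[ut[, 2L]],
                weight = net$weights[ut]), "edges.csv")
  wj(list(nodes = net$nodes, weights = net$weights,
          lambda = net$lambda_selected, gamma = net$gamma, n = net$n_used),
     "network.json")
  wj(as.list(report$symptom_clusters$labels), "symptom_clusters.json")
  wc(report$centralities, "centralities.csv")
  wc(report$stability$edge_ci, "edge_ci.csv")
  wj(list(
    n_resamples = report$stability$n_resamples,
    per_symptom_same_cluster_prop =
      as.list(report$stability$per_symptom_same_cluster_prop),
    cluster_count_distribution =
      as.list(report$stability$cluster_count_distribution),
    exact_cluster_replication_prop =
      as.list(report$stability$exact_cluster_replication_prop)
  ), "stability.json")
  wj(as.list(report$subgroups$labels), "patient_subgroups.json")
  wc(report$profiles, "subgroup_profiles.csv")
  if (!is.null(report$regression)) {
    wc(subgroup_model_table(report$regression), "regression_table.csv")
    reg <- report$regression
    wj(list(reference_group = reg$reference_group, aic = reg$aic,
            null_aic = reg$null_aic,
            pseudo_r2_cragg_uhler = reg$pseudo_r2_cragg_uhler,
            lr_chi2 = reg$lr_chi2, lr_df = reg$lr_df, lr_p = reg$lr_p,
            n = reg$n, m_bonferroni = reg$m),
       "regression.json")
  }
  wj(report$manifest, "manifest.json")
  invisible(out_dir)
}
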