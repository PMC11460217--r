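# Multinomial logistic regression of subgroup membership on demographic and
# clinical covariates, with Wald inference, Bonferroni correction, and the
# usual fit statistics (AIC, Cragg-Uhler pseudo R-squared, likelihood-ratio
# test against the intercept-only model). Model fitting is delegated to
# nnet::multinom.

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s).
#' @param m number of tests (at least 1).
#' @return `min(1, m * p_raw)`, elementwise.
#' @export
bonferroni <- function(p_raw, m) {
  if (m < 1) stop("m must be at least 1")
  pmin(1, m * p_raw)
}

#' Choose the reference subgroup
#'
#' Picks the subgroup most demographically similar to the whole cohort:
#' for each subgroup, continuous covariates contribute the absolute
#' subgroup-vs-cohort mean difference in cohort SD units and categorical
#' covariates the total variation distance between the subgroup and cohort
#' level frequencies; the subgroup with the smallest sum wins (smallest id
#' on ties).
#'
#' @param covariates data.frame of patient covariates (a `patient_id` column,
#'   if present, is ignored).
#' @param labels a [cluster_assignment()] over patients or a label vector.
#' @return The selected subgroup id (integer).
#' @export
select_reference_group <- function(covariates, labels) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  covariates <- covariates[, setdiff(names(covariates), "patient_id"),
                           drop = FALSE]
  if (length(labels) != nrow(covariates)) stop("one label per patient required")
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 subgroups")
  score <- setNames(numeric(length(groups)), groups)
  for (v in names(covariates)) {
    x <- covariates[[v]]
    keep <- !is.na(x)
    if (is.numeric(x)) {
      s_all <- sd(x[keep])
      m_all <- mean(x[keep])
      if (is.na(s_all) || s_all == 0) next
      for (g in groups) {
        xg <- x[keep & labels == g]
        score[as.character(g)] <- score[as.character(g)] +
          abs(mean(xg) - m_all) / s_all
      }
    } else {
      x <- as.factor(x)
      p_all <- prop.table(table(x[keep]))
      for (g in groups) {
        p_g <- prop.table(table(factor(x[keep & labels == g],
                                       levels = levels(x))))
        score[as.character(g)] <- score[as.character(g)] +
          0.5 * sum(abs(p_g - p_all))
      }
    }
  }
  groups[which.min(score)]
}

#' Multinomial logistic regression of subgroup membership
#'
#' Fits a softmax regression of subgroup labels on the covariates by maximum
#' likelihood (via `nnet::multinom`), with categorical covariates expanded
#' to indicator levels against their stated reference levels and
#' complete-case rows only. Reports per-coefficient odds ratios, Wald
#' p-values from the observed information, Bonferroni-corrected p-values,
#' AIC, Cragg-Uhler pseudo R-squared
#' `(1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))`, and the likelihood-ratio
#' chi-square against the intercept-only model.
#'
#' @param covariates data.frame of covariates (a `patient_id` column is
#'   dropped).
#' @param labels a [cluster_assignment()] over patients or a label vector.
#' @param reference reference subgroup id; defaults to
#'   [select_reference_group()].
#' @param m Bonferroni multiplicity; defaults to the number of non-intercept
#'   coefficient tests across all non-reference equations.
#' @param reltol,maxit optimizer controls passed to `nnet::multinom`.
#' @return A `subgroup_model`: list with `reference_group`, `coefficients`,
#'   `std_errors`, `odds_ratios`, `p_raw`, `p_bonferroni` (matrices:
#'   non-reference subgroups x terms), `m`, `aic`, `loglik`, `null_loglik`,
#'   `null_aic`, `pseudo_r2_cragg_uhler`, `lr_chi2`, `lr_df`, `lr_p`, `n`,
#'   and the underlying `fit`.
#' @export
fit_multinomial <- function(covariates, labels, reference = NULL, m = NULL,
                            reltol = 1e-10, maxit = 500L) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  covariates <- covariates[, setdiff(names(covariates), "patient_id"),
                           drop = FALSE]
  if (length(labels) != nrow(covariates)) stop("one label per patient required")
  if (is.null(reference)) reference <- select_reference_group(covariates, labels)
  dat <- covariates
  dat$.group <- factor(labels)
  if (!as.character(reference) %in% levels(dat$.group)) {
    stop("reference group not found among the labels")
  }
  dat$.group <- stats::relevel(dat$.group, ref = as.character(reference))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)

  mm <- stats::model.matrix(.group ~ ., data = dat)
  if (qr(mm)$rank < ncol(mm)) stop("singular design matrix: drop collinear covariates")

  fit <- nnet::multinom(.group ~ ., data = dat, trace = FALSE,
                        maxit = maxit, reltol = reltol, Hess = TRUE)
  fit0 <- nnet::multinom(.group ~ 1, data = dat, trace = FALSE,
                         maxit = maxit, reltol = reltol)

  co <- coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1, dimnames = list(levels(dat$.group)[2L], names(co)))
  se <- summary(fit)$standard.errors
  if (is.null(dim(se))) se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  z <- co / se
  p_raw <- 2 * pnorm(-abs(z))
  nonint <- colnames(co) != "(Intercept)"
  if (is.null(m)) m <- max(1L, sum(nonint) * nrow(co))
  p_bonf <- p_raw
  if (any(nonint)) p_bonf[, nonint] <- bonferroni(p_raw[, nonint], m)

  big <- which(abs(co[, nonint, drop = FALSE]) > 15, arr.ind = TRUE)
  if (nrow(big)) {
    terms_bad <- unique(colnames(co[, nonint, drop = FALSE])[big[, 2L]])
    warning("possible quasi-separation (|coef| > 15) for: ",
            paste(terms_bad, collapse = ", "))
  }

  ll1 <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(fit0))
  k1 <- attr(logLik(fit), "df")
  k0 <- attr(logLik(fit0), "df")
  # Cragg-Uhler / Nagelkerke on the log scale for numerical safety
  r2 <- (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
  lr <- 2 * (ll1 - ll0)
  lr_df <- k1 - k0
  structure(
    list(
      reference_group = reference,
      coefficients = co, std_errors = se,
      odds_ratios = exp(co), p_raw = p_raw, p_bonferroni = p_bonf, m = m,
      aic = 2 * k1 - 2 * ll1, loglik = ll1,
      null_loglik = ll0, null_aic = 2 * k0 - 2 * ll0,
      pseudo_r2_cragg_uhler = r2,
      lr_chi2 = lr, lr_df = lr_df,
      lr_p = pchisq(lr, df = lr_df, lower.tail = FALSE),
      n = n, fit = fit
    ),
    class = "subgroup_model"
  )
}

#' @export
print.subgroup_model <- function(x, ...) {
  cat(sprintf(
    "<subgroup_model> %d patients, reference subgroup %s\n  AIC %.1f (null %.1f), Cragg-Uhler R2 %.3f, LR chi2 %.1f (df %d, p %.3g)\n",
    x$n, x$reference_group, x$aic, x$null_aic, x$pseudo_r2_cragg_uhler,
    x$lr_chi2, x$lr_df, x$lr_p
  ))
  invisible(x)
}

#' Long-format odds-ratio table
#'
#' One row per (non-reference subgroup, covariate term): odds ratio, raw and
#' Bonferroni-corrected p-value. Intercepts are excluded.
#'
#' @param model a `subgroup_model`.
#' @return data.frame `subgroup`, `term`, `odds_ratio`, `p_raw`,
#'   `p_bonferroni`.
#' @export
subgroup_model_table <- function(model) {
  stopifnot(inherits(model, "subgroup_model"))
  co <- model$coefficients
  terms <- colnames(co)[colnames(co) != "(Intercept)"]
  out <- expand.grid(subgroup = rownames(co), term = terms,
                     stringsAsFactors = FALSE)
  out$odds_ratio <- model$odds_ratios[cbind(out$subgroup, out$term)]
  out$p_raw <- model$p_raw[cbind(out$subgroup, out$term)]
  out$p_bonferroni <- model$p_bonferroni[cbind(out$subgroup, out$term)]
  out[order(out$subgroup, out$term), , drop = FALSE]
}
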