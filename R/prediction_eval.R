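#' Fit a binomial or Poisson GLM
#'
#' Thin wrapper around [stats::glm()] that standardises the two families used
#' in the framework, records the exact log-likelihood, flags (quasi-)complete
#' separation instead of diverging silently, and turns rank deficiency into
#' an error naming the collinear columns.
#'
#' @param formula Model formula.
#' @param data Data frame with no missing values among the model variables.
#' @param family `"binary"` (logistic) or `"count"` (Poisson, log link).
#' @return Object of class `behaviour_fit`: `model` (the glm), `loglik`,
#'   `n_params`, `n_obs`, `coefficients` (estimate + SE), `fitted`, logical
#'   flags `separation` and `degenerate`.
#' @export
fit_glm <- function(formula, data, family = c("binary", "count")) {
  family <- match.arg(family)
  fam <- if (family == "binary") stats::binomial() else stats::poisson()
  vars <- all.vars(formula)
  assert_that(all(vars %in% names(data)),
              sprintf("data lacks model variable(s): %s",
                      paste(setdiff(vars, names(data)), collapse = ", ")))
  mf <- data[, vars, drop = FALSE]
  assert_that(!anyNA(mf), "missing values among model variables")
  fit <- suppressWarnings(stats::glm(formula, data = data, family = fam))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  y <- fit$y
  degenerate <- family == "binary" && length(unique(y)) < 2L
  separation <- FALSE
  if (family == "binary" && !degenerate) {
    p <- stats::fitted(fit)
    separation <- !fit$converged || max(abs(cf)) > 15 ||
      (all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6))
    if (separation)
      warning("possible complete separation: coefficients unreliable",
              call. = FALSE)
  }
  if (degenerate)
    warning("degenerate fit: outcome is constant", call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(model = fit,
                 formula = formula,
                 family = family,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_params = length(cf),
                 n_obs = stats::nobs(fit),
                 coefficients = data.frame(term = names(cf), estimate = unname(cf),
                                           se = unname(se),
                                           stringsAsFactors = FALSE),
                 fitted = stats::fitted(fit),
                 separation = separation, degenerate = degenerate),
            class = "behaviour_fit")
}

#' @export
print.behaviour_fit <- function(x, ...) {
  cat(sprintf("%s GLM: %s | n = %d, params = %d, logLik = %.4f%s\n",
              ifelse(x$family == "binary", "Logistic", "Poisson"),
              deparse(x$formula), x$n_obs, x$n_params, x$loglik,
              if (x$separation) " [separation]" else if (x$degenerate) " [degenerate]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood ratio test between nested fits
#'
#' The statistic 2 (ll_full - ll_nested) is referred to a chi-square
#' distribution with degrees of freedom equal to the difference in parameter
#' counts; the upper-tail probability is returned. Zero extra parameters (or
#' identical fits) give p = 1.
#'
#' @param full,nested `behaviour_fit` objects on the same data and family;
#'   the nested model's terms must be a subset of the full model's.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, nested) {
  stopifnot(inherits(full, "behaviour_fit"), inherits(nested, "behaviour_fit"))
  assert_that(full$family == nested$family, "fits use different families")
  assert_that(full$n_obs == nested$n_obs, "fits use different data sizes")
  t_full <- attr(stats::terms(full$formula), "term.labels")
  t_nest <- attr(stats::terms(nested$formula), "term.labels")
  assert_that(all(t_nest %in% t_full), "models are not nested")
  assert_that(full$loglik >= nested$loglik - 1e-6,
              "full model has lower likelihood than nested model")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  df <- full$n_params - nested$n_params
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Information criteria
#'
#' AIC = -2 ll + 2 k and BIC = -2 ll + k log(n).
#'
#' @param fit A `behaviour_fit`.
#' @return Named numeric vector `c(AIC = ..., BIC = ...)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "behaviour_fit"))
  c(AIC = -2 * fit$loglik + 2 * fit$n_params,
    BIC = -2 * fit$loglik + fit$n_params * log(fit$n_obs))
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Computed from midranks: the probability that a random positive outscores a
#' random negative, ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1) with both classes present.
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  assert_that(length(scores) == length(labels) && !anyNA(scores) && !anyNA(labels),
              "scores and labels must be complete and of equal length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  assert_that(n1 > 0L && n0 > 0L, "both outcome classes must be present")
  r <- rank(scores)                                # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation of two model arms
#'
#' Folds are drawn by a seeded permutation stratified by the outcome (fold
#' sizes differ by at most one overall and within each class). Cluster labels,
#' like every other covariate, are fixed pre-computed inputs: the clustering
#' is inferred once from observation-period data and the cross-validation
#' assesses the regression step. For each fold both arms are fitted on the
#' remaining folds and scored on the held-out fold.
#'
#' @param formula_with,formula_without Formulas for the augmented and the
#'   nested model arm.
#' @param data Analysis data frame.
#' @param outcome Name of the outcome column.
#' @param family `"binary"` or `"count"`.
#' @param k Number of folds (>= 2, <= n).
#' @param seed Integer seed for the fold permutation.
#' @param threshold Classification threshold on fitted probabilities
#'   (binary family; default 0.5).
#' @return List of two `cv_report`s (`with`, `without`), each holding
#'   `k_folds`, `seed`, per-fold `accuracy` and `auroc` (NA for a fold whose
#'   held-out outcomes are single-class), pooled `accuracy` and `auroc`, and
#'   `fold` membership.
#' @export
kfold_cv <- function(formula_with, formula_without, data, outcome,
                     family = c("binary", "count"), k = 5L, seed,
                     threshold = 0.5) {
  family <- match.arg(family)
  n <- nrow(data)
  assert_that(k >= 2L && k <= n, "k must be in [2, n]")
  y <- data[[outcome]]
  fold <- integer(n)
  with_seed(seed, {
    ord <- unlist(lapply(split(seq_len(n), y), sample), use.names = FALSE)
    fold[ord] <- rep_len(seq_len(k), n)
  })
  score_arm <- function(formula) {
    acc <- auc <- rep(NA_real_, k)
    pooled_pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- fit_glm(formula, data[!test, , drop = FALSE], family)
      pred <- stats::predict(fit$model, newdata = data[test, , drop = FALSE],
                             type = "response")
      pooled_pred[test] <- pred
      if (family == "binary") {
        acc[f] <- mean((pred >= threshold) == (y[test] == 1))
        if (length(unique(y[test])) == 2L) auc[f] <- auroc(pred, y[test])
      } else {
        acc[f] <- mean(round(pred) == y[test])
        if (length(unique(y[test] > 0)) == 2L)
          auc[f] <- auroc(pred, as.integer(y[test] > 0))
      }
    }
    pooled_auc <- if (family == "binary" && length(unique(y)) == 2L)
      auroc(pooled_pred, y)
    else if (family == "count" && length(unique(y > 0)) == 2L)
      auroc(pooled_pred, as.integer(y > 0))
    else NA_real_
    pooled_acc <- if (family == "binary")
      mean((pooled_pred >= threshold) == (y == 1))
    else mean(round(pooled_pred) == y)
    structure(list(k_folds = k, seed = as.integer(seed), fold = fold,
                   fold_accuracy = acc, fold_auroc = auc,
                   pooled_accuracy = pooled_acc, pooled_auroc = pooled_auc),
              class = "cv_report")
  }
  list(with = score_arm(formula_with), without = score_arm(formula_without))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d): pooled accuracy %.3f, pooled auROC %s\n",
              x$k_folds, x$seed, x$pooled_accuracy,
              ifelse(is.na(x$pooled_auroc), "NA", sprintf("%.3f", x$pooled_auroc))))
  invisible(x)
}

# Covariates of the conventional (nested) model arm.
nested_covariates <- function(family) {
  c("age", "last_flag",
    if (family == "binary") "prior_syphilis" else "prior_syph_count")
}

comparator_covariates <- function(comparator) {
  switch(comparator,
         cluster = "cluster",
         last = "last_flag",
         last_two = c("last2_older", "last2_newer"),
         ever = "ever",
         mean = "mean",
         none = character(0),
         stop(sprintf("unknown comparator '%s'", comparator), call. = FALSE))
}

#' Assemble the per-participant analysis frame
#'
#' Joins the outcome table, the cluster assignment and the simple trajectory
#' summaries into one modelling data frame. The cluster covariate is a factor
#' with the baseline cluster 0 as reference level.
#'
#' @param outcome_table [derive_outcome_table()] result.
#' @param assignment [assign_baseline_cluster()] result.
#' @param summaries [summarize_trajectories()] result.
#' @return Data frame keyed by `participant_id` with outcomes, covariates,
#'   `cluster` factor and summary covariates `last2_older`, `last2_newer`,
#'   `ever`, `mean`.
#' @export
build_model_frame <- function(outcome_table, assignment, summaries) {
  ids <- outcome_table$participant_id
  assert_that(all(ids %in% names(assignment)),
              "assignment does not cover all outcome-table participants")
  assert_that(all(ids %in% summaries$participant_id),
              "summaries do not cover all outcome-table participants")
  k <- attr(assignment, "k")
  df <- outcome_table
  # empty levels (e.g. an unpopulated baseline) are dropped for modelling
  df$cluster <- droplevels(factor(unclass(assignment)[ids], levels = 0:k))
  s <- summaries[match(ids, summaries$participant_id), ]
  df$last2_older <- ifelse(is.na(s$last2_older), 0, s$last2_older)
  df$last2_newer <- s$last2_newer
  df$ever <- s$ever
  df$mean <- s$mean
  df
}

arm_formula <- function(outcome, covs) {
  stats::as.formula(paste(outcome, "~",
                          if (length(covs)) paste(covs, collapse = " + ") else "1"))
}

#' Compare a nested model with a comparator-augmented model
#'
#' The nested arm contains the conventional covariates (age, last pre-cut-off
#' behaviour flag, and prior syphilis — the indicator for binary outcomes,
#' the episode count for count outcomes). The augmented arm adds the
#' comparator: `"cluster"` (factor with baseline 0 reference), or one of the
#' simple trajectory summaries `"last"`, `"last_two"`, `"ever"`, `"mean"`, or
#' `"none"`. Comparator columns that duplicate a nested covariate (e.g.
#' `"last"`, or the newer half of `"last_two"`) are dropped from the augmented
#' design rather than fitted as collinear copies, so `"last"` reduces to the
#' nested model with p_LRT = 1.
#'
#' @param data Analysis frame from [build_model_frame()].
#' @param outcome Outcome column name (e.g. `"out_nsCAI"`, `"sti_count"`).
#' @param family `"binary"` or `"count"`.
#' @param comparator One of `"cluster"`, `"last"`, `"last_two"`, `"ever"`,
#'   `"mean"`, `"none"`.
#' @return One-row data frame (`comparison_row`): `outcome`, `comparator`,
#'   `p_lrt`, `aic_without`, `aic_with`, `bic_without`, `bic_with`,
#'   `auroc_without`, `auroc_with` (auROCs are NA for count outcomes), plus
#'   the two fits as attributes `fit_with`, `fit_without`.
#' @export
compare_models <- function(data, outcome, family = c("binary", "count"),
                           comparator = c("cluster", "last", "last_two",
                                          "ever", "mean", "none")) {
  family <- match.arg(family)
  comparator <- match.arg(comparator)
  base_covs <- nested_covariates(family)
  add <- setdiff(comparator_covariates(comparator), base_covs)
  # last2_newer is the same quantity as the nested last_flag covariate
  if ("last_flag" %in% base_covs) add <- setdiff(add, "last2_newer")
  fit0 <- fit_glm(arm_formula(outcome, base_covs), data, family)
  fit1 <- if (length(add))
    fit_glm(arm_formula(outcome, c(base_covs, add)), data, family)
  else fit0
  lrt <- likelihood_ratio_test(fit1, fit0)
  ic0 <- information_criteria(fit0)
  ic1 <- information_criteria(fit1)
  roc0 <- roc1 <- NA_real_
  if (family == "binary" && length(unique(data[[outcome]])) == 2L) {
    roc0 <- auroc(fit0$fitted, data[[outcome]])
    roc1 <- auroc(fit1$fitted, data[[outcome]])
  }
  row <- data.frame(outcome = outcome, comparator = comparator,
                    p_lrt = lrt$p_value,
                    aic_without = unname(ic0["AIC"]), aic_with = unname(ic1["AIC"]),
                    bic_without = unname(ic0["BIC"]), bic_with = unname(ic1["BIC"]),
                    auroc_without = roc0, auroc_with = roc1,
                    stringsAsFactors = FALSE)
  attr(row, "fit_with") <- fit1
  attr(row, "fit_without") <- fit0
  class(row) <- c("comparison_row", class(row))
  row
}

#' Sweep the number of clusters
#'
#' Recuts the dendrogram at each k in `k_range`, rebuilds the cluster
#' covariate (always including the baseline cluster 0), refits the nested and
#' cluster-augmented models and records LRT p, AIC and BIC. The BIC-optimal k
#' is the k with the smallest `bic_with`, or `NA` when no k improves on the
#' cluster-free model.
#'
#' @param tree [ward_agglomerate()] tree over the clustered participants.
#' @param m `trajectory_matrix` over all included participants.
#' @param data Analysis frame **without** its cluster column being relied on
#'   (it is rebuilt per k); must contain the outcome and nested covariates.
#' @param outcome Outcome column name.
#' @param family `"binary"` or `"count"`.
#' @param k_range Integer vector of candidate k (within \[1, n\]).
#' @return List: `table` (data frame k, p_lrt, aic_with, bic_with, plus the
#'   constant aic_without/bic_without) and `bic_optimal_k` (integer or NA).
#' @export
sweep_cluster_number <- function(tree, m, data, outcome,
                                 family = c("binary", "count"), k_range) {
  family <- match.arg(family)
  assert_that(length(k_range) > 0L, "k_range must be non-empty")
  n <- length(tree$labels)
  assert_that(all(k_range >= 1 & k_range <= n),
              sprintf("k_range must lie within [1, %d]", n))
  base_covs <- nested_covariates(family)
  fit0 <- fit_glm(arm_formula(outcome, base_covs), data, family)
  ic0 <- information_criteria(fit0)
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    labels <- cut_to_k(tree, k, m)
    assignment <- assign_baseline_cluster(m, labels)
    d <- data
    d$cluster <- droplevels(factor(unclass(assignment)[d$participant_id],
                                   levels = 0:k))
    fit1 <- fit_glm(arm_formula(outcome, c(base_covs, "cluster")), d, family)
    lrt <- likelihood_ratio_test(fit1, fit0)
    ic1 <- information_criteria(fit1)
    data.frame(k = k, p_lrt = lrt$p_value, loglik_with = fit1$loglik,
               aic_with = unname(ic1["AIC"]), bic_with = unname(ic1["BIC"]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$aic_without <- unname(ic0["AIC"])
  tab$bic_without <- unname(ic0["BIC"])
  best <- tab$k[which.min(tab$bic_with)]
  if (min(tab$bic_with) >= unname(ic0["BIC"])) best <- NA_integer_
  list(table = tab, bic_optimal_k = best)
}
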