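test_that("intercept-only fits reproduce closed-form MLEs", {
  d <- data.frame(y = c(rep(1, 7), rep(0, 3)))
  fit <- fit_glm(y ~ 1, d, "binary")
  expect_equal(unname(fit$fitted[1]), 0.7, tolerance = 1e-8)
  expect_equal(fit$loglik, 7 * log(0.7) + 3 * log(0.3), tolerance = 1e-8)

  dp <- data.frame(y = c(0, 1, 2, 3))
  fitp <- fit_glm(y ~ 1, dp, "count")
  expect_equal(unname(fitp$fitted[1]), 1.5, tolerance = 1e-8)
  lam <- 1.5
  expect_equal(fitp$loglik, sum(stats::dpois(dp$y, lam, log = TRUE)),
               tolerance = 1e-8)
})

test_that("fit_glm flags degenerate and separated fits, errors on collinearity", {
  expect_warning(fit_glm(y ~ 1, data.frame(y = rep(0, 10)), "binary"),
                 "degenerate")
  d <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  expect_warning(fit <- fit_glm(y ~ x, d, "binary"), "separation")
  expect_true(fit$separation)
  d2 <- data.frame(y = rbinom(30, 1, 0.5), x = rnorm(30))
  d2$x2 <- d2$x
  expect_error(fit_glm(y ~ x + x2, d2, "binary"), "collinear.*x2")
  expect_error(fit_glm(y ~ x, data.frame(y = c(1, 0, NA), x = 1:3), "binary"),
               "missing values")
})

test_that("fit_glm matches stats::glm exactly and is deterministic", {
  set.seed(83)
  d <- data.frame(y = rbinom(200, 1, 0.4), a = rnorm(200), b = rbinom(200, 1, 0.5))
  fit <- fit_glm(y ~ a + b, d, "binary")
  ref <- stats::glm(y ~ a + b, data = d, family = stats::binomial())
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ref)))
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)))
  expect_identical(fit$coefficients, fit_glm(y ~ a + b, d, "binary")$coefficients)
})

test_that("likelihood ratio test matches the chi-square tail", {
  set.seed(89)
  d <- data.frame(y = rbinom(300, 1, 0.5), x = rnorm(300),
                  g = factor(sample(1:5, 300, TRUE)))
  full <- fit_glm(y ~ x + g, d, "binary")
  nested <- fit_glm(y ~ x, d, "binary")
  lrt <- likelihood_ratio_test(full, nested)
  expect_identical(lrt$df, 4L)
  expect_equal(lrt$statistic, 2 * (full$loglik - nested$loglik))
  expect_equal(lrt$p_value,
               stats::pchisq(lrt$statistic, 4, lower.tail = FALSE))
  # identical fits -> p = 1
  self <- likelihood_ratio_test(full, full)
  expect_identical(self$p_value, 1)
  # non-nested models error
  other <- fit_glm(y ~ g, d, "binary")
  expect_error(likelihood_ratio_test(nested, other), "not nested")
})

test_that("chi-square tail probabilities reproduce the printed examples", {
  expect_equal(round(stats::pchisq(3.841, 1, lower.tail = FALSE), 4), 0.05)
  expect_equal(round(stats::pchisq(13.28, 4, lower.tail = FALSE), 4), 0.01)
})

test_that("information criteria satisfy their identities", {
  fake <- structure(list(loglik = -100, n_params = 3L, n_obs = 100L),
                    class = "behaviour_fit")
  ic <- information_criteria(fake)
  expect_equal(unname(ic["AIC"]), 206)
  expect_equal(unname(ic["BIC"]), 206 - 6 + 3 * log(100), tolerance = 1e-9)
  # against stats::AIC/BIC on a real fit
  set.seed(97)
  d <- data.frame(y = rpois(150, 2), x = rnorm(150))
  fit <- fit_glm(y ~ x, d, "count")
  ic2 <- information_criteria(fit)
  expect_equal(unname(ic2["AIC"]), stats::AIC(fit$model), tolerance = 1e-9)
  expect_equal(unname(ic2["BIC"]), stats::BIC(fit$model), tolerance = 1e-9)
  # adding one parameter changes BIC by exactly log(n) - 2 * delta-loglik
  d$junk <- rnorm(150)
  fit2 <- fit_glm(y ~ x + junk, d, "count")
  expect_equal(unname(information_criteria(fit2)["BIC"] - ic2["BIC"]),
               log(150) - 2 * (fit2$loglik - fit$loglik), tolerance = 1e-9)
})

test_that("auroc equals the pairwise Mann-Whitney oracle including ties", {
  expect_identical(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both outcome classes")
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_identical(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("auroc agrees with pROC as an independent package cross-check", {
  skip_if_not_installed("pROC")
  set.seed(103)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

sim_frame <- function(n, K, eff, seed, null_cluster = FALSE) {
  pr <- make_default_profiles(K, 16)
  sim <- simulate_cohort(pr, n, 0.3, 0.1, seed = seed,
                         grid = time_grid(2009, 1, 16))
  cov <- simulate_covariates(sim$truth, seed = seed + 1)
  cov$last_flag <- vapply(seq_len(n), function(i) {
    o <- which(sim$truth$observed[i, ])
    if (!length(o)) 0 else as.numeric(sim$truth$events[i, max(o)])
  }, numeric(1))
  if (null_cluster) eff$beta_cluster <- rep(0, K)
  out <- simulate_outcomes(cov, eff, eff$family, seed = seed + 2)
  d <- cbind(cov, y = out$outcome)
  d$cluster <- factor(d$cluster, levels = 0:K)
  d
}

test_that("5-fold CV is seeded, stratified and partitions the cohort", {
  eff <- default_outcome_effects(2, "binary")
  d <- sim_frame(400, 2, eff, seed = 107)
  cv <- kfold_cv(y ~ age + last_flag + prior_syphilis + cluster,
                 y ~ age + last_flag + prior_syphilis,
                 d, "y", "binary", k = 5, seed = 11)
  fold <- cv$with$fold
  expect_identical(sort(unique(fold)), 1:5)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # stratification: per-class fold sizes also balanced
  for (cls in 0:1) {
    s <- table(fold[d$y == cls])
    expect_lte(max(s) - min(s), 1)
  }
  cv2 <- kfold_cv(y ~ age + last_flag + prior_syphilis + cluster,
                  y ~ age + last_flag + prior_syphilis,
                  d, "y", "binary", k = 5, seed = 11)
  expect_identical(cv$with$fold, cv2$with$fold)
  expect_identical(cv$with$pooled_accuracy, cv2$with$pooled_accuracy)
  expect_error(kfold_cv(y ~ age, y ~ 1, d, "y", "binary", k = 1, seed = 1),
               "k must be")
})

test_that("CV accuracy approaches the majority-class rate under the null", {
  eff <- default_outcome_effects(2, "binary")
  eff$beta_cluster <- rep(0, 2)
  eff$beta_last <- 0; eff$beta_syphilis <- 0; eff$beta_age <- 0
  eff$intercept <- stats::qlogis(0.3)
  d <- sim_frame(2000, 2, eff, seed = 109)
  cv <- kfold_cv(y ~ age + last_flag + prior_syphilis + cluster,
                 y ~ age + last_flag + prior_syphilis,
                 d, "y", "binary", k = 5, seed = 13)
  prev <- mean(d$y)
  base <- max(prev, 1 - prev)
  se <- sqrt(base * (1 - base) / nrow(d))
  expect_lt(abs(cv$without$pooled_accuracy - base), 3 * se + 0.01)
})

test_that("compare_models builds the comparison ledger correctly", {
  eff <- default_outcome_effects(3, "binary")
  d <- sim_frame(800, 3, eff, seed = 113)
  names(d)[names(d) == "y"] <- "out"
  d$last2_older <- d$last_flag  # stand-ins for the summary covariates
  d$last2_newer <- d$last_flag
  d$ever <- as.numeric(d$cluster != 0)
  d$mean <- d$ever * 0.5
  row <- compare_models(d, "out", "binary", "cluster")
  expect_lt(row$p_lrt, 0.05)
  expect_true(is.finite(row$bic_with) && is.finite(row$bic_without))
  expect_gte(row$auroc_with, row$auroc_without - 0.02)
  # comparator none: augmented equals nested
  none <- compare_models(d, "out", "binary", "none")
  expect_identical(none$p_lrt, 1)
  expect_identical(none$aic_with, none$aic_without)
  # comparator last duplicates the nested covariate -> reduces to nested
  last <- compare_models(d, "out", "binary", "last")
  expect_identical(last$p_lrt, 1)
  # count outcomes carry no auROC
  d$cnt <- rpois(nrow(d), 1)
  cnt <- compare_models(d, "cnt", "count", "cluster")
  expect_true(is.na(cnt$auroc_with))
})

test_that("planted labels never decrease the log-likelihood", {
  eff <- default_outcome_effects(2, "binary")
  for (seed in c(1, 2, 3)) {
    d <- sim_frame(500, 2, eff, seed = 500 + seed)
    full <- fit_glm(y ~ age + last_flag + prior_syphilis + cluster, d, "binary")
    nested <- fit_glm(y ~ age + last_flag + prior_syphilis, d, "binary")
    expect_gte(full$loglik, nested$loglik - 1e-6)
  }
})

test_that("sweep recuts the tree, is monotone in loglik, and k=1 equals an ever-style fit", {
  eff <- default_outcome_effects(3, "binary")
  pr <- make_default_profiles(3, 16)
  sim <- simulate_cohort(pr, 400, 0.3, 0.1, seed = 127,
                         grid = time_grid(2009, 1, 16))
  flagged <- derive_behaviour_flags(sim$visits)
  m <- bin_to_semiannual(flagged, time_grid(2009, 1, 16))
  cov <- simulate_covariates(sim$truth, seed = 128)
  cov$last_flag <- vapply(seq_len(400), function(i) {
    o <- which(sim$truth$observed[i, ])
    if (!length(o)) 0 else as.numeric(sim$truth$events[i, max(o)])
  }, numeric(1))
  out <- simulate_outcomes(cov, eff, "binary", seed = 129)
  d <- cbind(cov, out_y = out$outcome)

  never <- rownames(m)[rowSums(unclass(m) == 1L, na.rm = TRUE) == 0L]
  clustered <- setdiff(rownames(m), never)
  tree <- ward_agglomerate(pairwise_distance_matrix(m[clustered, , drop = FALSE]))
  sw <- sweep_cluster_number(tree, m, d, "out_y", "binary", k_range = 1:6)
  expect_identical(sw$table$k, 1:6)
  expect_true(all(diff(sw$table$loglik_with) >= -1e-8))  # nested in k
  expect_true(all(sw$table$p_lrt >= 0 & sw$table$p_lrt <= 1))
  # k = 1: baseline vs single hierarchical cluster == 2-level ever covariate
  d2 <- d
  d2$everpos <- as.numeric(d$participant_id %in% clustered)
  ref <- fit_glm(out_y ~ age + last_flag + prior_syphilis + everpos, d2, "binary")
  expect_equal(sw$table$loglik_with[1], ref$loglik, tolerance = 1e-8)
  expect_error(sweep_cluster_number(tree, m, d, "out_y", "binary",
                                    k_range = integer(0)), "non-empty")
})
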