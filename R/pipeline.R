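#' Default analysis configuration
#'
#' @param feature `"nsCAI"` or `"nsP"`.
#' @param k Number of hierarchical clusters (the assignment additionally
#'   carries the baseline cluster 0, so k = 4 gives five cluster labels).
#' @param cutoff_date Cut-off date splitting observation and outcome periods.
#' @param grid Observation [time_grid()].
#' @param comparators Comparator arms for the model-comparison ledger.
#' @param sweep_k Candidate cluster numbers for the sensitivity sweep.
#' @param cv_folds,cv_seed Cross-validation settings.
#' @param ward_method `"ward.D2"` (default) or `"ward.D"`.
#' @return Named list of settings.
#' @export
default_config <- function(feature = "nsCAI", k = 4L,
                           cutoff_date = as.Date("2017-05-01"),
                           grid = default_grid(),
                           comparators = c("cluster", "last", "last_two",
                                           "ever", "mean"),
                           sweep_k = 1:8, cv_folds = 5L, cv_seed = 1L,
                           ward_method = "ward.D2") {
  list(feature = feature, k = as.integer(k),
       cutoff_date = as.Date(cutoff_date), grid = grid,
       comparators = comparators, sweep_k = as.integer(sweep_k),
       cv_folds = as.integer(cv_folds), cv_seed = as.integer(cv_seed),
       ward_method = ward_method)
}

#' Run the full clustering-and-prediction analysis
#'
#' Executes every stage on the four input tables: derive behaviour flags,
#' classify incident syphilis, apply the inclusion criteria, split records at
#' the cut-off, build the semiannual trajectory matrix from observation-period
#' visits, compute Jaccard distances and the Ward dendrogram over participants
#' with at least one positive bin, cut to k clusters and append the baseline
#' cluster 0, then fit and compare the outcome models (behaviour at first
#' post-cut-off follow-up, any STI report, any laboratory-confirmed syphilis,
#' and the two count outcomes), run the comparator benchmark, the
#' cross-validation and the cluster-number sweep.
#'
#' @param visits,labs,sti,participants Input tables (see [read_tables]).
#' @param config A [default_config()] list.
#' @param verbose Log participant counts at each filter step.
#' @return List with elements `config`, `included` (ids), `trajectories`
#'   (`trajectory_matrix`), `tree`, `assignment`, `trends`, `outcome_table`,
#'   `model_frame`, `comparison` (one row per outcome x comparator),
#'   `cv` (per binary outcome), `sweep` (per outcome).
#' @export
run_behaviour_analysis <- function(visits, labs, sti, participants,
                                   config = default_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  feature <- config$feature
  visits <- derive_behaviour_flags(visits)
  say("read %d visit rows from %d participants",
      nrow(visits), length(unique(visits$participant_id)))

  episodes <- classify_incident_syphilis_all(labs)
  included <- apply_inclusion_criteria(visits, config$cutoff_date,
                                       feature = feature)
  say("included %d participants (>=2 %s records spanning >=2 years pre-cut-off, >=1 valid post-cut-off record)",
      length(included), feature)
  visits <- visits[visits$participant_id %in% included, , drop = FALSE]
  episodes <- episodes[episodes$participant_id %in% included, , drop = FALSE]
  sti <- sti[sti$participant_id %in% included, , drop = FALSE]

  split <- split_periods(visits, config$cutoff_date)
  m <- bin_to_semiannual(split$observation, grid = config$grid,
                         feature = feature)
  summaries <- summarize_trajectories(m)

  never <- rownames(m)[rowSums(unclass(m) == 1L, na.rm = TRUE) == 0L]
  clustered_ids <- setdiff(rownames(m), never)
  say("clustering %d participants; %d never reported %s (baseline cluster 0)",
      length(clustered_ids), length(never), feature)
  assert_that(length(clustered_ids) >= 2L,
              "need at least two participants with a positive trajectory")
  d <- pairwise_distance_matrix(m[clustered_ids, , drop = FALSE])
  tree <- ward_agglomerate(d, method = config$ward_method)
  labels <- cut_to_k(tree, config$k, m[clustered_ids, , drop = FALSE])
  assignment <- assign_baseline_cluster(m, labels)
  trends <- cluster_trend_curves(m, assignment)

  outcome_table <- derive_outcome_table(visits, episodes, sti, participants,
                                        config$cutoff_date, feature = feature)
  frame <- build_model_frame(outcome_table, assignment, summaries)

  outcomes <- list(
    list(name = if (feature == "nsCAI") "out_nsCAI" else "out_nsP",
         family = "binary"),
    list(name = "sti_any", family = "binary"),
    list(name = "syph_any", family = "binary"),
    list(name = "sti_count", family = "count"),
    list(name = "syph_count", family = "count"))

  comparison <- do.call(rbind, lapply(outcomes, function(o) {
    do.call(rbind, lapply(config$comparators, function(cmp) {
      row <- compare_models(frame, o$name, o$family, cmp)
      attr(row, "fit_with") <- attr(row, "fit_without") <- NULL
      class(row) <- "data.frame"
      row
    }))
  }))
  rownames(comparison) <- NULL

  cv <- lapply(outcomes[vapply(outcomes, function(o) o$family == "binary",
                               logical(1))], function(o) {
    base_covs <- nested_covariates("binary")
    kfold_cv(arm_formula(o$name, c(base_covs, "cluster")),
             arm_formula(o$name, base_covs),
             frame, o$name, "binary", k = config$cv_folds,
             seed = config$cv_seed)
  })
  names(cv) <- vapply(outcomes[vapply(outcomes, function(o) o$family == "binary",
                                      logical(1))], `[[`, character(1), "name")

  sweep <- lapply(outcomes, function(o) {
    sweep_cluster_number(tree, m, frame, o$name, o$family,
                         k_range = config$sweep_k[config$sweep_k <=
                                                    length(tree$labels)])
  })
  names(sweep) <- vapply(outcomes, `[[`, character(1), "name")

  list(config = config, included = included, trajectories = m,
       summaries = summaries, tree = tree, assignment = assignment,
       trends = trends, outcome_table = outcome_table, model_frame = frame,
       comparison = comparison, cv = cv, sweep = sweep)
}

#' Write analysis outputs to a directory
#'
#' Emits `comparison_table.csv` (model-comparison ledger), `sweep.csv`,
#' `trends.csv`, `assignment.csv`, `dendrogram.csv`, `dendrogram.nwk`,
#' `trajectories.csv`, `run_metadata.json`, and simple trend / BIC bar plots
#' as PDFs.
#'
#' @param res A [run_behaviour_analysis()] result.
#' @param dir Output directory.
#' @param plots Also render PDF figures (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(res, dir, plots = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$comparison, file.path(dir, "comparison_table.csv"),
                   row.names = FALSE)
  sweep_tab <- do.call(rbind, lapply(names(res$sweep), function(o) {
    t <- res$sweep[[o]]$table
    t$outcome <- o
    t$bic_optimal_k <- res$sweep[[o]]$bic_optimal_k
    t
  }))
  utils::write.csv(sweep_tab, file.path(dir, "sweep.csv"), row.names = FALSE)
  utils::write.csv(res$trends, file.path(dir, "trends.csv"), row.names = FALSE)
  utils::write.csv(data.frame(participant_id = names(res$assignment),
                              cluster = unclass(res$assignment)),
                   file.path(dir, "assignment.csv"), row.names = FALSE)
  write_dendrogram_csv(res$tree, file.path(dir, "dendrogram.csv"))
  write_dendrogram_newick(res$tree, file.path(dir, "dendrogram.nwk"))
  write_trajectory_csv(res$trajectories, file.path(dir, "trajectories.csv"))
  meta <- list(feature = res$config$feature, k = res$config$k,
               cutoff_date = as.character(res$config$cutoff_date),
               ward_method = res$config$ward_method,
               cv_folds = res$config$cv_folds, cv_seed = res$config$cv_seed,
               n_included = length(res$included),
               n_clustered = length(res$tree$labels),
               n_baseline = sum(unclass(res$assignment) == 0L),
               package_version = as.character(utils::packageVersion("trajclust")))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots) {
    grDevices::pdf(file.path(dir, "trends.pdf"), width = 8, height = 5)
    plot_trend_curves(res$trends)
    grDevices::dev.off()
    grDevices::pdf(file.path(dir, "bic_bars.pdf"), width = 8, height = 5)
    plot_bic_bars(res$comparison)
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Plot per-cluster behaviour trend curves
#'
#' @param trends A [cluster_trend_curves()] data frame.
#' @param main Plot title.
#' @export
plot_trend_curves <- function(trends, main = "Behaviour proportion by cluster") {
  clusters <- sort(unique(trends$cluster))
  cols <- grDevices::hcl.colors(max(length(clusters), 2L), "Dark 3")
  graphics::plot(NULL, xlim = range(trends$bin), ylim = c(0, 1),
                 xlab = "semiannual bin", ylab = "proportion reporting",
                 main = main)
  for (i in seq_along(clusters)) {
    t <- trends[trends$cluster == clusters[i], ]
    graphics::lines(t$bin, t$prop, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = paste("cluster", clusters),
                   col = cols[seq_along(clusters)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Bar plot of BIC with vs without clusters per outcome
#'
#' @param comparison Comparison table restricted to (or filtered for) the
#'   `"cluster"` comparator rows.
#' @export
plot_bic_bars <- function(comparison) {
  cc <- comparison[comparison$comparator == "cluster", ]
  h <- rbind(without = cc$bic_without, with = cc$bic_with)
  graphics::barplot(h, beside = TRUE, names.arg = cc$outcome,
                    legend.text = c("without clusters", "with clusters"),
                    ylab = "BIC", main = "Model comparison (smaller is better)",
                    args.legend = list(bty = "n"))
  invisible(NULL)
}
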