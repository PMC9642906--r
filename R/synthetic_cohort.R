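#' Default cluster probability profiles
#'
#' Well-separated per-bin event-probability curves emulating the qualitative
#' shapes seen in long-running behaviour cohorts: flat low-activity, flat
#' high-activity, a rising logistic ramp (behaviour adopted over calendar
#' time), a falling ramp, and two intermediate shapes. Profiles carry equal
#' mixture weights among the non-baseline strata; the never-event baseline
#' stratum is configured separately in [simulate_cohort()].
#'
#' @param K Number of profiles (1..6).
#' @param n_bins Number of semiannual bins (>= 2).
#' @return List of `cluster_profile` objects: `label` (1..K), `curve`
#'   (probabilities per bin), `weight` (summing to 1 across profiles).
#' @examples
#' pr <- make_default_profiles(3, 32)
#' sapply(pr, function(p) range(p$curve))
#' @export
make_default_profiles <- function(K, n_bins) {
  assert_that(K >= 1, "K must be >= 1")
  assert_that(n_bins >= 2, "n_bins must be >= 2")
  t <- seq(0, 1, length.out = n_bins)
  ramp_up <- stats::plogis(10 * (t - 0.55))
  templates <- list(
    flat_low = rep(0.10, n_bins),
    flat_high = rep(0.85, n_bins),
    rising = 0.03 + 0.87 * ramp_up,
    falling = 0.03 + 0.87 * (1 - ramp_up),
    mid = rep(0.45, n_bins),
    hump = 0.05 + 0.80 * exp(-((t - 0.5) / 0.18)^2)
  )
  assert_that(K <= length(templates),
              sprintf("K = %d exceeds the %d implemented profile templates", K,
                      length(templates)))
  lapply(seq_len(K), function(j) {
    structure(list(label = j, curve = templates[[j]], weight = 1 / K),
              class = "cluster_profile")
  })
}

#' Simulate a longitudinal visit cohort with planted cluster structure
#'
#' Participants are assigned to the baseline (never-event) stratum with
#' probability `baseline_fraction`, otherwise to a profile drawn by weight. At
#' each retained semiannual bin a participant's event flag is Bernoulli with
#' the profile's bin probability (always 0 in the baseline stratum); bins are
#' dropped independently with probability `visit_missingness`, and an optional
#' late-entry mechanism truncates a uniform number of leading bins to mimic
#' staggered enrolment. Visit dates fall uniformly inside their bin. Event
#' flags are dressed up as the three questionnaire answers: an event bin is
#' ("yes","yes","no"); a non-event bin of a non-baseline participant reports
#' non-steady partners with protected intercourse ("yes","yes","yes") with
#' probability `nsp_without_event_prob`, else ("no","",""); baseline bins are
#' always ("no","","").
#'
#' @param profiles List from [make_default_profiles()].
#' @param n_participants Cohort size (>= 1).
#' @param baseline_fraction Proportion in \[0, 1) assigned to the never-event
#'   stratum.
#' @param visit_missingness Per-(participant, bin) probability in \[0, 1) of a
#'   missed visit.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param grid A [time_grid()] for the observation period.
#' @param date_ceiling Optional `Date`; visit dates are drawn strictly before
#'   it (used to keep the final partial half-year inside the observation
#'   period).
#' @param late_entry_max_bins Maximum number of leading bins truncated per
#'   participant (uniform on 0..max; default 0 = everyone enrolled from bin 1).
#' @param nsp_without_event_prob Probability that a non-event bin of a
#'   non-baseline participant still reports (protected) non-steady-partner sex.
#' @return List: `visits` (data frame `participant_id`, `visit_date`,
#'   `ans_nsP`, `ans_intercourse`, `ans_condom_always`, ordered by participant
#'   and date) and `truth`, a `synthetic_truth` object with the planted labels
#'   (0 = baseline), profiles, the latent event/observation matrices, grid,
#'   seed and parameters.
#' @export
simulate_cohort <- function(profiles, n_participants, baseline_fraction = 0.3,
                            visit_missingness = 0.2, seed,
                            grid = default_grid(), date_ceiling = NULL,
                            late_entry_max_bins = 0L,
                            nsp_without_event_prob = 0.3) {
  assert_that(n_participants >= 1, "n_participants must be >= 1")
  assert_that(baseline_fraction >= 0 && baseline_fraction < 1,
              "baseline_fraction must be in [0, 1)")
  assert_that(visit_missingness >= 0 && visit_missingness < 1,
              "visit_missingness must be in [0, 1)")
  n_bins <- grid$n_bins
  for (p in profiles)
    assert_that(length(p$curve) == n_bins && all(p$curve >= 0 & p$curve <= 1),
                "profile curve must match the grid and lie in [0, 1]")
  w <- vapply(profiles, `[[`, numeric(1), "weight")
  assert_that(abs(sum(w) - 1) < 1e-9, "profile weights must sum to 1")
  K <- length(profiles)

  with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_participants))
    is_base <- stats::runif(n_participants) < baseline_fraction
    lab <- integer(n_participants)
    n_nb <- sum(!is_base)
    if (n_nb > 0L)
      lab[!is_base] <- sample.int(K, n_nb, replace = TRUE, prob = w)

    curves <- rbind(rep(0, n_bins),
                    do.call(rbind, lapply(profiles, `[[`, "curve")))
    pmat <- curves[lab + 1L, , drop = FALSE]
    events <- matrix(stats::rbinom(n_participants * n_bins, 1L, as.vector(pmat)),
                     n_participants, n_bins, dimnames = list(ids, grid$labels))
    observed <- matrix(stats::runif(n_participants * n_bins) >= visit_missingness,
                       n_participants, n_bins)
    if (late_entry_max_bins > 0L) {
      entry <- sample.int(late_entry_max_bins + 1L, n_participants,
                          replace = TRUE) - 1L
      observed <- observed & (col(observed) > entry[row(observed)])
    }
    nsp_extra <- matrix(stats::runif(n_participants * n_bins) < nsp_without_event_prob,
                        n_participants, n_bins)
    frac <- matrix(stats::runif(n_participants * n_bins), n_participants, n_bins)

    idx <- which(observed, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    span <- as.numeric(grid$bin_end - grid$bin_start)
    hi <- grid$bin_end
    if (!is.null(date_ceiling))
      hi <- pmin(hi, as.Date(date_ceiling))
    span_eff <- as.numeric(hi - grid$bin_start)
    keep <- span_eff[idx[, 2]] > 0
    idx <- idx[keep, , drop = FALSE]
    dates <- grid$bin_start[idx[, 2]] +
      floor(frac[idx] * span_eff[idx[, 2]])
    ev <- events[idx] == 1L
    nb <- lab[idx[, 1]] > 0L
    ans_a <- ifelse(ev | (nb & nsp_extra[idx]), "yes", "no")
    ans_b <- ifelse(ans_a == "yes", "yes", "")
    ans_c <- ifelse(ev, "no", ifelse(ans_a == "yes", "yes", ""))
    visits <- data.frame(participant_id = ids[idx[, 1]],
                         visit_date = dates,
                         ans_nsP = ans_a, ans_intercourse = ans_b,
                         ans_condom_always = ans_c,
                         stringsAsFactors = FALSE)
    visits <- visits[order(visits$participant_id, visits$visit_date), ]
    rownames(visits) <- NULL

    truth <- structure(list(labels = stats::setNames(lab, ids),
                            profiles = profiles,
                            events = events, observed = observed,
                            grid = grid, seed = as.integer(seed),
                            params = list(n_participants = n_participants,
                                          baseline_fraction = baseline_fraction,
                                          visit_missingness = visit_missingness,
                                          late_entry_max_bins = late_entry_max_bins,
                                          nsp_without_event_prob = nsp_without_event_prob)),
                       class = "synthetic_truth")
    list(visits = visits, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic cohort truth: %d participants, %d planted cluster(s) + baseline, seed %d\n",
              length(x$labels), length(x$profiles), x$seed))
  print(table(planted = x$labels))
  invisible(x)
}

#' Default planted outcome effects
#'
#' Reference-coded effect sets for the simulated post-cut-off outcomes, on the
#' log-odds (binary) or log-rate (count) scale. Cluster effects alternate in
#' sign with magnitude 1 (binary) or 0.5 (count) relative to the baseline
#' cluster 0; the intercept is chosen so that a baseline-cluster participant
#' of age 40 with no recent behaviour and no prior syphilis has outcome
#' probability ~0.15 (binary) or rate ~0.25 (count).
#'
#' @param K Number of non-baseline clusters.
#' @param family `"binary"` or `"count"`.
#' @return An `outcome_effects` list: `intercept`, `beta_cluster` (length K;
#'   baseline fixed at 0 by reference coding), `beta_last`, `beta_syphilis`,
#'   `beta_age`.
#' @export
default_outcome_effects <- function(K, family = c("binary", "count")) {
  family <- match.arg(family)
  alt <- (-1)^(seq_len(K) + 1)                 # +1, -1, +1, ...
  if (family == "binary") {
    eff <- list(intercept = stats::qlogis(0.15) + 0.03 * 40,
                beta_cluster = 1 * alt, beta_last = 0.7,
                beta_syphilis = 0.6, beta_age = -0.03)
  } else {
    eff <- list(intercept = log(0.25) + 0.02 * 40,
                beta_cluster = 0.5 * alt, beta_last = 0.5,
                beta_syphilis = 0.4, beta_age = -0.02)
  }
  structure(c(eff, list(family = family)), class = "outcome_effects")
}

#' Simulate participant covariates
#'
#' Age at cut-off is Normal(40, 10) truncated to \[18, 80\]; prior syphilis is
#' Bernoulli with a cluster-dependent probability (0.05 for the baseline
#' cluster, increasing by 0.05 per cluster label, capped at 0.4); prior
#' episode counts add a small Poisson excess on top of the indicator.
#'
#' @param truth A `synthetic_truth`.
#' @param seed Integer seed.
#' @return Data frame: `participant_id`, `cluster` (planted label), `age`,
#'   `prior_syphilis`, `prior_syph_count`.
#' @export
simulate_covariates <- function(truth, seed) {
  n <- length(truth$labels)
  with_seed(seed, {
    age <- stats::rnorm(n, 40, 10)
    while (any(bad <- age < 18 | age > 80))
      age[bad] <- stats::rnorm(sum(bad), 40, 10)
    p_syph <- pmin(0.05 + 0.05 * unname(truth$labels), 0.4)
    prior <- stats::rbinom(n, 1L, p_syph)
    count <- prior + prior * stats::rpois(n, 0.3)
    data.frame(participant_id = names(truth$labels),
               cluster = unname(truth$labels), age = age,
               prior_syphilis = prior, prior_syph_count = count,
               stringsAsFactors = FALSE)
  })
}

#' Simulate post-cut-off outcomes from planted effects
#'
#' Builds the linear predictor `intercept + beta_cluster[cluster] +
#' beta_last * last_flag + beta_syphilis * syph + beta_age * age` (cluster 0
#' contributes 0 by reference coding; `syph` is the binary indicator for
#' binary outcomes and the prior episode count for count outcomes) and draws
#' Bernoulli(inverse-logit(lp)) or Poisson(exp(lp)) outcomes.
#'
#' @param covariates Data frame with one row per participant: `participant_id`,
#'   `cluster`, `age`, `last_flag`, `prior_syphilis`, `prior_syph_count`.
#' @param effects An [default_outcome_effects()]-style `outcome_effects` list.
#' @param family `"binary"` or `"count"`.
#' @param seed Integer seed.
#' @return Data frame `participant_id`, `outcome`.
#' @export
simulate_outcomes <- function(covariates, effects, family = c("binary", "count"),
                              seed) {
  if (!family[1] %in% c("binary", "count"))
    stop(sprintf("unknown family '%s'", family[1]), call. = FALSE)
  family <- match.arg(family)
  need <- c("participant_id", "cluster", "age", "last_flag", "prior_syphilis",
            "prior_syph_count")
  assert_that(all(need %in% names(covariates)),
              sprintf("covariate table needs columns: %s", paste(need, collapse = ", ")))
  cl <- as.integer(covariates$cluster)
  K <- length(effects$beta_cluster)
  assert_that(all(cl >= 0 & cl <= K), "cluster labels outside 0..K")
  bc <- c(0, effects$beta_cluster)[cl + 1L]
  syph <- if (family == "binary") covariates$prior_syphilis else covariates$prior_syph_count
  lp <- effects$intercept + bc + effects$beta_last * covariates$last_flag +
    effects$beta_syphilis * syph + effects$beta_age * covariates$age
  with_seed(seed, {
    y <- if (family == "binary") stats::rbinom(length(lp), 1L, stats::plogis(lp))
         else stats::rpois(length(lp), exp(lp))
    data.frame(participant_id = covariates$participant_id, outcome = y,
               stringsAsFactors = FALSE)
  })
}

# Last observed pre-cut-off event flag per participant, straight from the
# latent matrices (0 when a participant has no observed bin).
last_observed_flag <- function(truth) {
  ev <- truth$events; obs <- truth$observed
  vapply(seq_len(nrow(ev)), function(i) {
    o <- which(obs[i, ])
    if (!length(o)) return(0)
    as.numeric(ev[i, max(o)])
  }, numeric(1))
}

#' Simulate a complete synthetic study
#'
#' End-to-end generator producing every table the ingest layer consumes:
#' pre-cut-off visits with planted cluster structure, post-cut-off visits
#' whose first follow-up encodes a behaviour outcome drawn from a logistic
#' model with planted effects, STI report rows drawn from a Poisson model,
#' a serology table encoding prior and incident syphilis episodes (via
#' treponemal seroconversion and VDRL titer rises that reproduce the planted
#' episode counts under the classification rule), and a participant table
#' with birth dates matching the simulated ages.
#'
#' @param n_participants Cohort size.
#' @param K Number of planted non-baseline clusters.
#' @param baseline_fraction,visit_missingness,late_entry_max_bins Passed to
#'   [simulate_cohort()].
#' @param seed Integer master seed (sub-streams are derived from it).
#' @param grid Observation-period [time_grid()].
#' @param cutoff_date Cut-off date (default 2017-05-01).
#' @param n_post_visits Post-cut-off semiannual visits per participant
#'   (default 2; the first encodes the behaviour outcome).
#' @param effects_binary,effects_sti,effects_syph Planted effect sets; default
#'   [default_outcome_effects()] (syphilis counts use a lower intercept,
#'   log(0.1) + 0.02 * 40).
#' @return List: `visits`, `labs`, `sti`, `participants` (CSV-ready data
#'   frames), and `truth` (a `synthetic_truth` augmented with covariates,
#'   outcomes and effect sets).
#' @export
simulate_study <- function(n_participants = 1000, K = 3,
                           baseline_fraction = 0.3, visit_missingness = 0.2,
                           late_entry_max_bins = 0L,
                           seed, grid = default_grid(),
                           cutoff_date = as.Date("2017-05-01"),
                           n_post_visits = 2L,
                           effects_binary = default_outcome_effects(K, "binary"),
                           effects_sti = default_outcome_effects(K, "count"),
                           effects_syph = NULL) {
  if (is.null(effects_syph)) {
    effects_syph <- default_outcome_effects(K, "count")
    effects_syph$intercept <- log(0.1) + 0.02 * 40
  }
  cutoff_date <- as.Date(cutoff_date)
  profiles <- make_default_profiles(K, grid$n_bins)
  sim <- simulate_cohort(profiles, n_participants, baseline_fraction,
                         visit_missingness, seed = seed, grid = grid,
                         date_ceiling = cutoff_date,
                         late_entry_max_bins = late_entry_max_bins)
  truth <- sim$truth
  ids <- names(truth$labels)
  n <- length(ids)

  cov <- simulate_covariates(truth, seed = seed + 1L)
  cov$last_flag <- last_observed_flag(truth)

  out_beh <- simulate_outcomes(cov, effects_binary, "binary", seed = seed + 2L)
  out_sti <- simulate_outcomes(cov, effects_sti, "count", seed = seed + 3L)
  out_syph <- simulate_outcomes(cov, effects_syph, "count", seed = seed + 4L)

  with_seed(seed + 5L, {
    # post-cut-off visits: first follow-up encodes the behaviour outcome
    post <- do.call(rbind, lapply(seq_len(n_post_visits), function(v) {
      dates <- cutoff_date + (v - 1L) * 183L + floor(stats::runif(n, 10, 170))
      ev <- if (v == 1L) out_beh$outcome == 1L
            else stats::rbinom(n, 1L, 0.2) == 1L & truth$labels > 0L
      data.frame(participant_id = ids, visit_date = dates,
                 ans_nsP = ifelse(ev, "yes", "no"),
                 ans_intercourse = ifelse(ev, "yes", ""),
                 ans_condom_always = ifelse(ev, "no", ""),
                 stringsAsFactors = FALSE)
    }))
    visits <- rbind(sim$visits, post)
    visits <- visits[order(visits$participant_id, visits$visit_date), ]
    rownames(visits) <- NULL

    # serology: everyone has a negative baseline; each planted episode is a
    # reset (low titer) lab followed by a spike that triggers the rule
    first_date <- grid$bin_start[1L]
    lab_rows <- list(data.frame(participant_id = ids,
                                date = first_date + seq_len(n) %% 30L,
                                treponemal_result = "negative",
                                vdrl_titer = 0, stringsAsFactors = FALSE))
    # Each planted episode is a titer reset (no treponemal result reported)
    # followed >= 3 weeks later by a spike that satisfies the incident rule;
    # anchors are >= 60 days apart so consecutive spikes classify separately.
    add_episodes <- function(id, n_ep, lo, hi) {
      if (n_ep == 0L) return(NULL)
      slots <- seq(30L, as.integer(hi - lo) - 40L, by = 60L)
      anchors <- sort(slots[sample.int(length(slots), n_ep)])
      do.call(rbind, lapply(seq_len(n_ep), function(e) {
        base <- lo + anchors[e]
        rbind(data.frame(participant_id = id, date = base,
                         treponemal_result = "", vdrl_titer = 2,
                         stringsAsFactors = FALSE),
              data.frame(participant_id = id, date = base + 21L,
                         treponemal_result = "positive", vdrl_titer = 32,
                         stringsAsFactors = FALSE))
      }))
    }
    # clamp at the number of materialisable episode slots (P(exceed) ~ 1e-6
    # at the default rates)
    pre_ep <- pmin(cov$prior_syph_count, 6L)
    post_ep <- pmin(out_syph$outcome, 6L)
    cov$prior_syph_count <- pre_ep
    cov$prior_syphilis <- as.numeric(pre_ep > 0L)
    out_syph$outcome <- post_ep
    for (i in seq_len(n)) {
      if (pre_ep[i] > 0L)
        lab_rows[[length(lab_rows) + 1L]] <-
          add_episodes(ids[i], pre_ep[i], first_date + 400L, cutoff_date - 60L)
      if (post_ep[i] > 0L)
        lab_rows[[length(lab_rows) + 1L]] <-
          add_episodes(ids[i], post_ep[i], cutoff_date + 10L,
                       cutoff_date + 1000L)
    }
    labs <- do.call(rbind, lab_rows)
    labs <- labs[order(labs$participant_id, labs$date), ]
    rownames(labs) <- NULL

    sti_rows <- rep(seq_len(n), out_sti$outcome)
    sti <- data.frame(participant_id = ids[sti_rows],
                      report_date = cutoff_date +
                        floor(stats::runif(length(sti_rows), 5, 1000)),
                      stringsAsFactors = FALSE)
    sti <- sti[order(sti$participant_id, sti$report_date), ]
    rownames(sti) <- NULL

    participants <- data.frame(participant_id = ids,
                               birth_date = cutoff_date - round(cov$age * 365.25),
                               stringsAsFactors = FALSE)

    truth$covariates <- cov
    truth$outcomes <- list(behaviour = out_beh, sti = out_sti, syphilis = out_syph)
    truth$effects <- list(behaviour = effects_binary, sti = effects_sti,
                          syphilis = effects_syph)
    truth$cutoff_date <- cutoff_date
    list(visits = visits, labs = labs, sti = sti, participants = participants,
         truth = truth)
  })
}

#' Write a simulated study to CSV + truth sidecar JSON
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(study$labs, file.path(dir, "labs.csv"), row.names = FALSE)
  utils::write.csv(study$sti, file.path(dir, "sti.csv"), row.names = FALSE)
  utils::write.csv(study$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  truth <- study$truth
  side <- list(seed = truth$seed,
               labels = as.list(stats::setNames(unname(truth$labels),
                                                names(truth$labels))),
               profiles = lapply(truth$profiles, function(p)
                 list(label = p$label, weight = p$weight, curve = p$curve)),
               effects = lapply(truth$effects, function(e)
                 e[c("intercept", "beta_cluster", "beta_last", "beta_syphilis",
                     "beta_age", "family")]),
               params = truth$params,
               cutoff_date = as.character(truth$cutoff_date))
  jsonlite::write_json(side, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
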