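#' Derive behaviour flags from the three questionnaire answers
#'
#' Follow-up questionnaires ask (a) whether the participant had sex with
#' non-steady partners in the last six months, (b) if yes, whether they had
#' anal or vaginal intercourse with these partners, and (c) if yes, whether
#' condoms were used all the time. `nsP` (non-steady partners) is 1 iff (a) is
#' "yes"; `nsCAI` (condomless anal intercourse with non-steady partners) is 1
#' iff (a) = "yes", (b) = "yes" and (c) = "no". Missingness propagates: a flag
#' is `NA` exactly when the gating answers needed to evaluate it are missing.
#'
#' @param visits Data frame with columns `ans_nsP`, `ans_intercourse`,
#'   `ans_condom_always`, each `"yes"`, `"no"` or missing (`NA`/empty string).
#' @return `visits` with columns `nsP` and `nsCAI` appended (0/1/NA). The
#'   implication `nsCAI == 1 => nsP == 1` holds on every row.
#' @examples
#' derive_behaviour_flags(data.frame(
#'   ans_nsP = c("yes", "no", "yes"),
#'   ans_intercourse = c("yes", NA, "yes"),
#'   ans_condom_always = c("no", NA, "yes")))[, c("nsP", "nsCAI")]
#' @export
derive_behaviour_flags <- function(visits) {
  norm <- function(x) {
    x <- tolower(trimws(as.character(x)))
    x[x == ""] <- NA_character_
    bad <- !is.na(x) & !x %in% c("yes", "no")
    if (any(bad))
      stop(sprintf("answers must be yes/no/missing; got: %s",
                   paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    x
  }
  a <- norm(visits$ans_nsP)
  b <- norm(visits$ans_intercourse)
  c_ <- norm(visits$ans_condom_always)

  nsP <- ifelse(is.na(a), NA_integer_, as.integer(a == "yes"))
  nsCAI <- rep(NA_integer_, length(a))
  nsCAI[!is.na(a) & a == "no"] <- 0L                       # gate (a) closed
  known_b <- !is.na(a) & a == "yes" & !is.na(b)
  nsCAI[known_b & b == "no"] <- 0L                          # no intercourse
  known_c <- known_b & b == "yes" & !is.na(c_)
  nsCAI[known_c] <- as.integer(c_[known_c] == "no")         # condoms not always
  visits$nsP <- nsP
  visits$nsCAI <- nsCAI
  visits
}

#' Classify incident syphilis episodes from serology
#'
#' Serological follow-up combines a treponemal antibody test and a
#' non-treponemal VDRL titer. An incident episode is flagged at a lab record
#' when either (i) the treponemal result flips from the most recent non-missing
#' prior result "negative" to "positive" (seroconversion), or (ii) the VDRL
#' titer exceeds 1:8 **and** exceeds `fold` times the most recent non-missing
#' prior titer (default four-fold, strict inequalities). A record with no prior
#' non-missing titer cannot trigger rule (ii); a prior titer of 0
#' (non-reactive) means any subsequent titer above 1:8 triggers it.
#'
#' @param labs Data frame for **one** participant with columns
#'   `participant_id`, `date`, `treponemal_result`
#'   (`"positive"`/`"negative"`/NA) and `vdrl_titer` (reciprocal titer, 0 =
#'   non-reactive, NA = not done), sorted by `date`, at most one row per date.
#' @param titer_threshold Reciprocal titer that must be exceeded (default 8,
#'   i.e. "> 1:8").
#' @param fold Required fold-rise over the prior titer (default 4); the
#'   comparison is strict (`>`).
#' @return Data frame of episodes: `participant_id`, `episode_date`, `trigger`
#'   (`"treponemal_seroconversion"` or `"vdrl_rise"`); zero rows if none.
#' @export
classify_incident_syphilis <- function(labs, titer_threshold = 8, fold = 4) {
  empty <- data.frame(participant_id = character(0),
                      episode_date = as.Date(character(0)),
                      trigger = character(0), stringsAsFactors = FALSE)
  if (nrow(labs) == 0L) return(empty)
  stopifnot(length(unique(labs$participant_id)) == 1L)
  d <- as.Date(labs$date)
  assert_that(!is.unsorted(d, strictly = FALSE), "lab records must be sorted by date")
  assert_that(!anyDuplicated(d), "at most one lab record per date per participant")

  trep <- tolower(as.character(labs$treponemal_result))
  trep[trep == "" | is.na(trep)] <- NA_character_
  titer <- suppressWarnings(as.numeric(labs$vdrl_titer))

  out <- empty
  prior_trep <- NA_character_
  prior_titer <- NA_real_
  for (i in seq_len(nrow(labs))) {
    trigger <- NA_character_
    if (!is.na(trep[i]) && trep[i] == "positive" &&
        !is.na(prior_trep) && prior_trep == "negative") {
      trigger <- "treponemal_seroconversion"
    } else if (!is.na(titer[i]) && titer[i] > titer_threshold &&
               !is.na(prior_titer) && titer[i] > fold * prior_titer) {
      trigger <- "vdrl_rise"
    }
    if (!is.na(trigger))
      out <- rbind(out, data.frame(participant_id = labs$participant_id[i],
                                   episode_date = d[i], trigger = trigger,
                                   stringsAsFactors = FALSE))
    if (!is.na(trep[i])) prior_trep <- trep[i]
    if (!is.na(titer[i])) prior_titer <- titer[i]
  }
  out
}

#' Classify episodes for a whole laboratory table
#'
#' @param labs Lab table for any number of participants (columns as in
#'   [classify_incident_syphilis()]); rows need not be sorted.
#' @inheritParams classify_incident_syphilis
#' @return Episode table over all participants.
#' @export
classify_incident_syphilis_all <- function(labs, titer_threshold = 8, fold = 4) {
  labs <- labs[order(labs$participant_id, as.Date(labs$date)), , drop = FALSE]
  parts <- split(labs, labs$participant_id)
  out <- do.call(rbind, lapply(parts, classify_incident_syphilis,
                               titer_threshold = titer_threshold, fold = fold))
  if (is.null(out)) out <- classify_incident_syphilis(labs[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Split dated records at the cut-off
#'
#' The cut-off is half-open: records strictly before `cutoff_date` form the
#' observation period (used to infer clusters), records on or after it form
#' the outcome period.
#'
#' @param records Data frame with a date column.
#' @param cutoff_date A `Date`.
#' @param date_col Name of the date column (default `"visit_date"`).
#' @return List with elements `observation` and `outcome`, a disjoint,
#'   exhaustive partition of `records`, plus `cutoff_date`.
#' @export
split_periods <- function(records, cutoff_date, date_col = "visit_date") {
  d <- as.Date(records[[date_col]])
  cutoff_date <- as.Date(cutoff_date)
  pre <- d < cutoff_date
  list(observation = records[pre, , drop = FALSE],
       outcome = records[!pre, , drop = FALSE],
       cutoff_date = cutoff_date)
}

#' Apply the cohort inclusion criteria
#'
#' A participant is included when, before the cut-off, they have at least
#' `min_records` non-missing records of the behaviour feature spanning at
#' least `min_span_years` years (first to last such record), and they have at
#' least one post-cut-off visit with a non-missing value of the feature (so
#' every configured outcome can be evaluated).
#'
#' @param visits Flagged visit table (see [derive_behaviour_flags()]).
#' @param cutoff_date The cut-off `Date`.
#' @param feature `"nsCAI"` or `"nsP"`.
#' @param min_span_years Minimum follow-up span in years (default 2).
#' @param min_records Minimum number of non-missing pre-cut-off records
#'   (default 2).
#' @param require_post Require a valid post-cut-off record (default `TRUE`).
#' @return Character vector of included participant ids.
#' @export
apply_inclusion_criteria <- function(visits, cutoff_date,
                                     feature = c("nsCAI", "nsP"),
                                     min_span_years = 2, min_records = 2L,
                                     require_post = TRUE) {
  feature <- match.arg(feature)
  assert_that(feature %in% names(visits),
              sprintf("visits lack derived '%s' flags", feature))
  d <- as.Date(visits$visit_date)
  cutoff_date <- as.Date(cutoff_date)
  flag <- visits[[feature]]
  pre <- !is.na(flag) & d < cutoff_date
  post <- !is.na(flag) & d >= cutoff_date

  pre_tab <- visits[pre, , drop = FALSE]
  pre_d <- d[pre]
  n_pre <- tapply(pre_d, pre_tab$participant_id, length)
  span_y <- tapply(as.numeric(pre_d), pre_tab$participant_id,
                   function(x) (max(x) - min(x)) / 365.25)
  ok <- names(n_pre)[n_pre >= min_records & span_y >= min_span_years]
  if (require_post) {
    post_ids <- unique(visits$participant_id[post])
    ok <- intersect(ok, post_ids)
  }
  assert_that(length(ok) > 0L, "no participants satisfy the inclusion criteria")
  sort(ok)
}

#' Build the per-participant outcome table
#'
#' For each included participant this collects the prospective outcomes and
#' the conventional covariates: the first non-missing post-cut-off `nsCAI` and
#' `nsP` flag, any/count of nurse- or physician-reported STIs in the outcome
#' window, any/count of laboratory-confirmed syphilis episodes after cut-off,
#' age at cut-off (years), the last non-missing pre-cut-off flag of the
#' configured feature, and prior-syphilis status (indicator and episode
#' count before cut-off).
#'
#' @param visits Flagged visit table restricted to included participants.
#' @param episodes Syphilis episode table ([classify_incident_syphilis_all()]).
#' @param sti_reports Data frame `participant_id`, `report_date` (may be empty).
#' @param participants Data frame `participant_id`, `birth_date`.
#' @param cutoff_date Cut-off `Date`.
#' @param feature Feature whose last pre-cut-off value becomes the `last_flag`
#'   covariate.
#' @return Data frame with one row per participant: `participant_id`,
#'   `out_nsCAI`, `out_nsP`, `sti_any`, `sti_count`, `syph_any`, `syph_count`,
#'   `age`, `last_flag`, `prior_syphilis`, `prior_syph_count`.
#' @export
derive_outcome_table <- function(visits, episodes, sti_reports, participants,
                                 cutoff_date, feature = c("nsCAI", "nsP")) {
  feature <- match.arg(feature)
  cutoff_date <- as.Date(cutoff_date)
  ids <- sort(unique(visits$participant_id))
  d <- as.Date(visits$visit_date)
  ord <- order(visits$participant_id, d)
  visits <- visits[ord, , drop = FALSE]
  d <- d[ord]

  first_post <- function(col) {
    vapply(ids, function(id) {
      sel <- visits$participant_id == id & d >= cutoff_date & !is.na(visits[[col]])
      if (!any(sel)) return(NA_real_)
      as.numeric(visits[[col]][which(sel)[1L]])
    }, numeric(1))
  }
  last_pre <- vapply(ids, function(id) {
    sel <- visits$participant_id == id & d < cutoff_date & !is.na(visits[[feature]])
    assert_that(any(sel), sprintf("participant %s has no pre-cut-off %s record", id, feature))
    as.numeric(visits[[feature]][utils::tail(which(sel), 1L)])
  }, numeric(1))

  out_nsCAI <- first_post("nsCAI")
  out_nsP <- first_post("nsP")
  feat_out <- if (feature == "nsCAI") out_nsCAI else out_nsP
  if (anyNA(feat_out))
    stop(sprintf("participant(s) with no valid post-cut-off %s record (should have been excluded): %s",
                 feature, paste(utils::head(ids[is.na(feat_out)], 3L), collapse = ", ")),
         call. = FALSE)

  ep_d <- as.Date(episodes$episode_date)
  count_ep <- function(pre) vapply(ids, function(id) {
    sum(episodes$participant_id == id & (if (pre) ep_d < cutoff_date else ep_d >= cutoff_date))
  }, numeric(1))
  syph_count <- count_ep(pre = FALSE)
  prior_syph_count <- count_ep(pre = TRUE)

  sti_d <- as.Date(sti_reports$report_date %||% as.Date(character(0)))
  sti_count <- vapply(ids, function(id) {
    sum(sti_reports$participant_id == id & sti_d >= cutoff_date)
  }, numeric(1))

  birth <- as.Date(participants$birth_date)[match(ids, participants$participant_id)]
  assert_that(!anyNA(birth), "missing birth_date for some included participants")
  age <- as.numeric(cutoff_date - birth) / 365.25

  data.frame(participant_id = ids,
             out_nsCAI = out_nsCAI, out_nsP = out_nsP,
             sti_any = as.numeric(sti_count > 0), sti_count = sti_count,
             syph_any = as.numeric(syph_count > 0), syph_count = syph_count,
             age = age, last_flag = last_pre,
             prior_syphilis = as.numeric(prior_syph_count > 0),
             prior_syph_count = prior_syph_count,
             stringsAsFactors = FALSE)
}

required_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  assert_that(length(missing) == 0L,
              sprintf("%s table lacks column(s): %s", what,
                      paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), cols)
  if (length(extra))
    warning(sprintf("%s table: ignoring unknown column(s) %s", what,
                    paste(extra, collapse = ", ")), call. = FALSE)
  df[, cols, drop = FALSE]
}

#' Read the input CSV tables
#'
#' All tables are UTF-8 CSV with a header row and ISO-8601 dates. Unknown
#' columns are dropped with a warning.
#' @param path File path.
#' @return Data frame with parsed date columns.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_visit_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- required_cols(df, c("participant_id", "visit_date", "ans_nsP",
                            "ans_intercourse", "ans_condom_always"), "visit")
  df$visit_date <- as_date_strict(df$visit_date, "visit_date")
  df
}

#' @rdname read_tables
#' @export
read_lab_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- required_cols(df, c("participant_id", "date", "treponemal_result",
                            "vdrl_titer"), "lab")
  df$date <- as_date_strict(df$date, "date")
  df$vdrl_titer <- suppressWarnings(as.numeric(df$vdrl_titer))
  df
}

#' @rdname read_tables
#' @export
read_sti_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- required_cols(df, c("participant_id", "report_date"), "STI report")
  df$report_date <- as_date_strict(df$report_date, "report_date")
  df
}

#' @rdname read_tables
#' @export
read_participant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- required_cols(df, c("participant_id", "birth_date"), "participant")
  df$birth_date <- as_date_strict(df$birth_date, "birth_date")
  df
}
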