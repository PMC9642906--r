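# Exhaustive rule table for the three-state questionnaire logic, written out
# independently of the implementation.
rule_oracle <- function(a, b, c_) {
  nsP <- if (is.na(a)) NA_integer_ else as.integer(a == "yes")
  nsCAI <- if (is.na(a)) NA_integer_
  else if (a == "no") 0L
  else if (is.na(b)) NA_integer_
  else if (b == "no") 0L
  else if (is.na(c_)) NA_integer_
  else as.integer(c_ == "no")
  c(nsP = nsP, nsCAI = nsCAI)
}

test_that("behaviour flags match the questionnaire rules on all 27 combinations", {
  states <- c("yes", "no", NA)
  grid <- expand.grid(a = states, b = states, c_ = states,
                      stringsAsFactors = FALSE)
  df <- data.frame(ans_nsP = grid$a, ans_intercourse = grid$b,
                   ans_condom_always = grid$c_, stringsAsFactors = FALSE)
  res <- derive_behaviour_flags(df)
  for (i in seq_len(nrow(grid))) {
    exp <- rule_oracle(grid$a[i], grid$b[i], grid$c_[i])
    expect_identical(res$nsP[i], unname(exp["nsP"]),
                     info = paste(grid[i, ], collapse = "/"))
    expect_identical(res$nsCAI[i], unname(exp["nsCAI"]),
                     info = paste(grid[i, ], collapse = "/"))
  }
  # implication nsCAI = 1 => nsP = 1 over the whole domain
  expect_true(all(res$nsP[which(res$nsCAI == 1L)] == 1L))
  # the four worked examples
  ex <- derive_behaviour_flags(data.frame(
    ans_nsP = c("yes", "no", "yes", "yes"),
    ans_intercourse = c("yes", NA, "yes", NA),
    ans_condom_always = c("no", NA, "yes", NA)))
  expect_identical(ex$nsP, c(1L, 0L, 1L, 1L))
  expect_identical(ex$nsCAI, c(1L, 0L, 0L, NA))
})

test_that("empty strings count as missing and bad answers error", {
  res <- derive_behaviour_flags(data.frame(ans_nsP = "", ans_intercourse = "",
                                           ans_condom_always = ""))
  expect_identical(res$nsP, NA_integer_)
  expect_error(derive_behaviour_flags(data.frame(
    ans_nsP = "maybe", ans_intercourse = "yes", ans_condom_always = "no")),
    "yes/no/missing")
})

lab_tab <- function(dates, trep = NA, titer = NA, id = "X") {
  data.frame(participant_id = id, date = as.Date(dates),
             treponemal_result = trep, vdrl_titer = titer,
             stringsAsFactors = FALSE)
}

test_that("incident syphilis classification follows the serological rule", {
  # seroconversion
  ep <- classify_incident_syphilis(lab_tab(c("2010-01-01", "2011-01-01"),
                                           trep = c("negative", "positive")))
  expect_identical(nrow(ep), 1L)
  expect_identical(ep$episode_date, as.Date("2011-01-01"))
  expect_identical(ep$trigger, "treponemal_seroconversion")

  # titer 2 -> 16: > 1:8 and > 4-fold
  ep <- classify_incident_syphilis(lab_tab(c("2010-01-01", "2011-01-01"),
                                           titer = c(2, 16)))
  expect_identical(ep$trigger, "vdrl_rise")

  # 4 -> 8: 8 is not > 8
  ep <- classify_incident_syphilis(lab_tab(c("2010-01-01", "2011-01-01"),
                                           titer = c(4, 8)))
  expect_identical(nrow(ep), 0L)

  # 16 -> 32: only two-fold
  ep <- classify_incident_syphilis(lab_tab(c("2010-01-01", "2011-01-01"),
                                           titer = c(16, 32)))
  expect_identical(nrow(ep), 0L)

  # a first titer cannot trigger the fold rule
  ep <- classify_incident_syphilis(lab_tab("2010-01-01", titer = 64))
  expect_identical(nrow(ep), 0L)

  # rise from non-reactive 0 to > 1:8 triggers
  ep <- classify_incident_syphilis(lab_tab(c("2010-01-01", "2011-01-01"),
                                           titer = c(0, 16)))
  expect_identical(ep$trigger, "vdrl_rise")

  # configurable fold threshold
  ep <- classify_incident_syphilis(lab_tab(c("2010-01-01", "2011-01-01"),
                                           titer = c(16, 32)), fold = 1.5)
  expect_identical(nrow(ep), 1L)

  expect_error(classify_incident_syphilis(
    lab_tab(c("2011-01-01", "2010-01-01"), titer = c(2, 16))), "sorted")
})

test_that("syphilis classification is order-stable after re-sorting", {
  set.seed(4)
  labs <- lab_tab(as.Date("2005-01-01") + sort(sample(0:4000, 12)),
                  trep = sample(c("negative", "positive", NA), 12, TRUE),
                  titer = sample(c(0, 2, 4, 8, 16, 32, 64, NA), 12, TRUE))
  ref <- classify_incident_syphilis(labs)
  perm <- labs[sample(nrow(labs)), ]
  again <- classify_incident_syphilis_all(perm)
  expect_equal(ref$episode_date, again$episode_date)
  expect_equal(ref$trigger, again$trigger)
  expect_equal(classify_incident_syphilis(labs), ref)  # idempotent
})

visits_of <- function(id, dates, flags) {
  data.frame(participant_id = id, visit_date = as.Date(dates),
             nsCAI = flags, nsP = flags, stringsAsFactors = FALSE)
}

test_that("inclusion criteria enforce span, record count and post-cut-off follow-up", {
  cutoff <- as.Date("2017-05-01")
  v <- rbind(
    visits_of("in_ok", c("2010-01-15", "2013-01-15", "2018-01-01"), c(0, 1, 0)),
    visits_of("one_rec", c("2010-01-15", "2018-01-01"), c(1, 0)),
    visits_of("short_span", c("2010-01-15", "2011-06-15", "2018-01-01"), c(0, 1, 0)),
    visits_of("no_post", c("2010-01-15", "2013-01-15"), c(0, 1)))
  inc <- apply_inclusion_criteria(v, cutoff)
  expect_identical(inc, "in_ok")
  # a missing-flag record does not count towards min_records
  v2 <- rbind(v, visits_of("one_rec2", c("2012-06-01"), NA))
  expect_identical(apply_inclusion_criteria(v2, cutoff), "in_ok")
  expect_error(apply_inclusion_criteria(v[v$participant_id == "one_rec", ],
                                        cutoff), "no participants")
})

test_that("inclusion is monotone in min_records and min_span_years", {
  set.seed(9)
  ids <- sprintf("p%02d", 1:40)
  v <- do.call(rbind, lapply(ids, function(id) {
    nr <- sample(1:6, 1)
    visits_of(id, as.Date("2009-01-01") + sort(sample(0:3650, nr + 1)),
              c(rbinom(nr, 1, 0.5), rep(1, 1)))
  }))
  # last visit pushed after cut-off so everyone has a post record
  v$visit_date[cumsum(tapply(seq_len(nrow(v)), v$participant_id, length))] <-
    as.Date("2018-06-01")
  cutoff <- as.Date("2017-05-01")
  strict <- apply_inclusion_criteria(v, cutoff, min_span_years = 3, min_records = 3)
  relaxed1 <- apply_inclusion_criteria(v, cutoff, min_span_years = 2, min_records = 3)
  relaxed2 <- apply_inclusion_criteria(v, cutoff, min_span_years = 3, min_records = 2)
  expect_true(all(strict %in% relaxed1))
  expect_true(all(strict %in% relaxed2))
})

test_that("split_periods partitions records half-open at the cut-off", {
  cutoff <- as.Date("2017-05-01")
  v <- visits_of("a", c("2017-04-30", "2017-05-01", "2017-05-02"), c(0, 1, 0))
  sp <- split_periods(v, cutoff)
  expect_identical(nrow(sp$observation), 1L)
  expect_identical(nrow(sp$outcome), 2L)
  expect_true(as.Date("2017-05-01") %in% sp$outcome$visit_date)  # boundary -> outcome
  expect_identical(nrow(sp$observation) + nrow(sp$outcome), nrow(v))
  all_pre <- split_periods(visits_of("a", "2010-01-01", 1), cutoff)
  expect_identical(nrow(all_pre$outcome), 0L)
})

test_that("derive_outcome_table collects outcomes and covariates", {
  cutoff <- as.Date("2017-05-01")
  v <- visits_of("a", c("2010-01-15", "2013-01-15",
                        "2017-06-01", "2017-12-01", "2018-06-01"),
                 c(0, 1, NA, 1, 0))
  eps <- data.frame(participant_id = "a",
                    episode_date = as.Date(c("2015-01-01", "2018-01-01",
                                             "2019-01-01")),
                    trigger = "vdrl_rise", stringsAsFactors = FALSE)
  sti <- data.frame(participant_id = "a",
                    report_date = as.Date("2018-03-01"),
                    stringsAsFactors = FALSE)
  parts <- data.frame(participant_id = "a", birth_date = as.Date("1977-05-01"),
                      stringsAsFactors = FALSE)
  out <- derive_outcome_table(v, eps, sti, parts, cutoff)
  expect_identical(out$out_nsCAI, 1)          # first non-missing post flag
  expect_identical(out$syph_any, 1)
  expect_identical(out$syph_count, 2)         # two post-cut-off episodes
  expect_identical(out$prior_syphilis, 1)
  expect_identical(out$prior_syph_count, 1)
  expect_identical(out$sti_count, 1)
  expect_identical(out$last_flag, 1)          # last pre-cut-off non-missing
  expect_equal(out$age, 40, tolerance = 0.01)

  # participants without a valid post record must have been excluded upstream
  v_bad <- visits_of("b", c("2010-01-15", "2013-01-15", "2018-01-01"),
                     c(0, 1, NA))
  expect_error(derive_outcome_table(v_bad, eps[0, ], sti[0, ],
                                    data.frame(participant_id = "b",
                                               birth_date = as.Date("1980-01-01")),
                                    cutoff),
               "no valid post-cut-off")
  # no prior episode -> zero prior covariates
  out2 <- derive_outcome_table(v, eps[eps$episode_date >= cutoff, ], sti,
                               parts, cutoff)
  expect_identical(out2$prior_syphilis, 0)
  expect_identical(out2$prior_syph_count, 0)
})

test_that("CSV readers validate columns, parse ISO dates and warn on extras", {
  tmp <- withr::local_tempdir()
  vp <- file.path(tmp, "v.csv")
  utils::write.csv(data.frame(participant_id = "a", visit_date = "2010-01-15",
                              ans_nsP = "yes", ans_intercourse = "yes",
                              ans_condom_always = "no", junk = 1),
                   vp, row.names = FALSE)
  expect_warning(v <- read_visit_table(vp), "unknown column")
  expect_s3_class(v$visit_date, "Date")
  expect_false("junk" %in% names(v))
  utils::write.csv(data.frame(participant_id = "a"), vp, row.names = FALSE)
  expect_error(read_visit_table(vp), "lacks column")
})
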