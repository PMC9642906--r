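#' Semiannual calendar grid
#'
#' Cohort follow-up happens at enrolment and every six months thereafter, so
#' trajectories are indexed by calendar half-years rather than by patient time.
#' A `time_grid` holds contiguous half-year bins, each a half-open date
#' interval: H1 is Jan 1 (inclusive) to Jul 1 (exclusive), H2 is Jul 1 to
#' Jan 1 of the following year.
#'
#' @param start_year Calendar year of the first bin.
#' @param start_half 1 or 2: whether the first bin is the first (Jan-Jun) or
#'   second (Jul-Dec) half of `start_year`.
#' @param n_bins Number of consecutive half-year bins (>= 1).
#' @return An object of class `time_grid` with bin labels (e.g. `"2005H1"`),
#'   start dates and exclusive end dates.
#' @examples
#' g <- time_grid(2001, 2, 32)  # 2001H2 .. 2017H1
#' g$labels[c(1, 32)]
#' @export
time_grid <- function(start_year, start_half = 1L, n_bins) {
  assert_that(start_half %in% c(1L, 2L), "start_half must be 1 or 2")
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  start_year <- as.integer(start_year)
  start_half <- as.integer(start_half)
  idx <- seq_len(n_bins) - 1L
  half0 <- (start_half - 1L) + idx            # 0-based half-year counter
  years <- start_year + half0 %/% 2L
  halves <- half0 %% 2L + 1L
  starts <- as.Date(sprintf("%d-%02d-01", years, ifelse(halves == 1L, 1L, 7L)))
  ends <- as.Date(sprintf("%d-%02d-01",
                          ifelse(halves == 1L, years, years + 1L),
                          ifelse(halves == 1L, 7L, 1L)))
  structure(list(start_year = start_year, start_half = start_half,
                 n_bins = as.integer(n_bins),
                 labels = sprintf("%dH%d", years, halves),
                 bin_start = starts, bin_end = ends),
            class = "time_grid")
}

#' Default observation grid: 2001H2 through 2017H1
#'
#' Covers mid-2001 up to the default cut-off (2017-05-01); the partial
#' half-year Jan-Apr 2017 folds into the 2017H1 bin.
#' @return A [time_grid()] with 32 bins.
#' @export
default_grid <- function() time_grid(2001L, 2L, 32L)

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("Semiannual time grid: %s .. %s (%d bins)\n",
              x$labels[1L], x$labels[x$n_bins], x$n_bins))
  invisible(x)
}

#' Map calendar dates to grid bins
#'
#' @param dates Date vector.
#' @param grid A [time_grid()].
#' @return Integer bin indices; `NA` for dates outside the grid span.
#' @export
date_to_bin <- function(dates, grid) {
  stopifnot(inherits(grid, "time_grid"))
  d <- as.Date(dates)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  half0 <- (y - grid$start_year) * 2L + ifelse(m <= 6L, 0L, 1L) -
    (grid$start_half - 1L)
  bin <- half0 + 1L
  bin[bin < 1L | bin > grid$n_bins] <- NA_integer_
  bin
}

#' Build a trajectory matrix from flagged visits
#'
#' Each participant's dated behaviour flags are placed on the semiannual grid
#' (one column per half-year). When several visits fall in the same bin the
#' default aggregation is logical OR: any report of the behaviour marks the
#' half-year. Bins with no non-missing flag are `NA`. Visits dated outside the
#' grid span are dropped with a message stating the count.
#'
#' @param visits Data frame with columns `participant_id`, `visit_date` and the
#'   flag column named by `feature` (values 0/1/NA), e.g. the output of
#'   [derive_behaviour_flags()] bound to a visit table.
#' @param grid A [time_grid()].
#' @param feature Which behaviour flag to use: `"nsCAI"` (condomless anal
#'   intercourse with non-steady partners) or `"nsP"` (any sex with non-steady
#'   partners).
#' @param aggregate `"or"` (default) or `"latest"` (last visit in the bin wins).
#' @return A `trajectory_matrix`: integer matrix in \{0, 1, NA\}, one row per
#'   participant (rownames = ids), one column per bin, with the grid and
#'   feature attached as attributes.
#' @export
bin_to_semiannual <- function(visits, grid = default_grid(),
                              feature = c("nsCAI", "nsP"),
                              aggregate = c("or", "latest")) {
  feature <- match.arg(feature)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(grid, "time_grid"))
  assert_that(grid$n_bins >= 1, "empty grid")
  assert_that(feature %in% names(visits),
              sprintf("visits lack a '%s' flag column", feature))
  ids <- unique(visits$participant_id)
  dates <- as.Date(visits$visit_date)
  bin <- date_to_bin(dates, grid)
  out_of_span <- sum(is.na(bin))
  if (out_of_span > 0L)
    message(sprintf("bin_to_semiannual: dropped %d visit(s) outside the grid span",
                    out_of_span))
  keep <- !is.na(bin)
  m <- matrix(NA_integer_, nrow = length(ids), ncol = grid$n_bins,
              dimnames = list(ids, grid$labels))
  if (any(keep)) {
    v <- visits[keep, , drop = FALSE]
    vbin <- bin[keep]
    vdate <- dates[keep]
    flag <- as.integer(v[[feature]])
    ok <- !is.na(flag)
    v <- v[ok, , drop = FALSE]; vbin <- vbin[ok]; vdate <- vdate[ok]; flag <- flag[ok]
    row <- match(v$participant_id, ids)
    if (aggregate == "or") {
      # max over non-missing flags per (participant, bin)
      key <- (row - 1L) * grid$n_bins + vbin
      agg <- tapply(flag, key, max)
      cell <- as.integer(names(agg))
      m[cbind((cell - 1L) %/% grid$n_bins + 1L,
              (cell - 1L) %% grid$n_bins + 1L)] <- as.integer(agg)
    } else {
      ord <- order(row, vbin, vdate)   # last write wins = latest visit
      m[cbind(row[ord], vbin[ord])] <- flag[ord]
    }
  }
  structure(m, grid = grid, feature = feature,
            class = c("trajectory_matrix", class(m)))
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("Trajectory matrix: %d participants x %d semiannual bins (%s..%s), feature %s\n",
              nrow(x), ncol(x), g$labels[1L], g$labels[g$n_bins],
              attr(x, "feature")))
  cat(sprintf("  non-missing cells: %d (%.1f%%); positive cells: %d\n",
              sum(!is.na(x)), 100 * mean(!is.na(x)), sum(x == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Simple trajectory summaries used as comparator predictors
#'
#' For one trajectory row, computes the conventional behaviour summaries that
#' cluster membership is benchmarked against: the last available value, the
#' last two available values, whether the behaviour was ever reported, and the
#' mean over non-missing bins.
#'
#' @param row Integer/numeric vector in \{0, 1, NA\} (one row of a
#'   [bin_to_semiannual()] matrix).
#' @return List with elements `last` (0/1), `last_two` (length-2 vector,
#'   older then newer; older is `NA` if only one value exists), `ever` (0/1)
#'   and `mean` (proportion in \[0, 1\]).
#' @export
summarize_trajectory <- function(row) {
  obs <- which(!is.na(row))
  assert_that(length(obs) >= 1L, "trajectory row has no non-missing value")
  vals <- as.numeric(row[obs])
  nlast <- length(vals)
  last_two <- if (nlast >= 2L) vals[c(nlast - 1L, nlast)] else c(NA_real_, vals[nlast])
  list(last = vals[nlast],
       last_two = last_two,
       ever = as.numeric(any(vals == 1)),
       mean = mean(vals))
}

#' Summaries for every row of a trajectory matrix
#'
#' @param m A `trajectory_matrix`.
#' @return Data frame with one row per participant: `participant_id`, `last`,
#'   `last2_older`, `last2_newer`, `ever`, `mean`.
#' @export
summarize_trajectories <- function(m) {
  rows <- lapply(seq_len(nrow(m)), function(i) summarize_trajectory(m[i, ]))
  data.frame(participant_id = rownames(m),
             last = vapply(rows, `[[`, numeric(1), "last"),
             last2_older = vapply(rows, function(r) r$last_two[1L], numeric(1)),
             last2_newer = vapply(rows, function(r) r$last_two[2L], numeric(1)),
             ever = vapply(rows, `[[`, numeric(1), "ever"),
             mean = vapply(rows, `[[`, numeric(1), "mean"),
             stringsAsFactors = FALSE)
}

#' Write a trajectory matrix to CSV
#'
#' One row per participant, columns = bin labels, missing bins as empty cells.
#' @param m A `trajectory_matrix`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(m, path) {
  df <- data.frame(participant_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
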