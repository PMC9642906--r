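#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a private, explicitly seeded RNG stream, restoring the
# caller's .Random.seed afterwards so simulation calls never leak global state.
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

as_date_strict <- function(x, what = "date") {
  d <- as.Date(x)
  if (anyNA(d) && !all(is.na(x) | x == "")) {
    bad <- x[is.na(d) & !(is.na(x) | x == "")]
    stop(sprintf("unparseable %s value(s): %s", what,
                 paste(utils::head(bad, 3L), collapse = ", ")), call. = FALSE)
  }
  d
}
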