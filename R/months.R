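#' Calendar-month utilities
#'
#' Months are represented throughout the package as `"YYYY-MM"` character
#' keys. `as_month()` normalises dates and date-like strings to that form;
#' `month_seq()` enumerates an inclusive range; `month_add()` shifts a month
#' by a number of calendar months (negative allowed).
#'
#' @param x a character vector of `"YYYY-MM"` or ISO-8601 `"YYYY-MM-DD"`
#'   strings, or a `Date` vector.
#' @return `as_month()`: a character vector of `"YYYY-MM"` keys, with `NA`
#'   for unparseable input.
#' @examples
#' as_month(c("2020-04", "2020-04-23"))
#' month_seq("2019-01", "2019-03")
#' month_add("2020-04", -12)
#' @export
as_month <- function(x) {
  if (inherits(x, "Date")) {
    return(format(x, "%Y-%m"))
  }
  x <- as.character(x)
  nc <- nchar(x)
  out <- rep(NA_character_, length(x))
  cand <- !is.na(x) & (nc == 7L | nc == 10L) & substr(x, 5L, 5L) == "-"
  out[cand] <- substr(x[cand], 1L, 7L)
  ok <- !is.na(out) & grepl("^\\d{4}-(0[1-9]|1[0-2])$", out)
  out[!ok] <- NA_character_
  out
}

# integer month index (0 = Jan of year 0); internal
month_index <- function(m) {
  as.integer(substr(m, 1L, 4L)) * 12L + as.integer(substr(m, 6L, 7L)) - 1L
}

index_month <- function(i) {
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' @rdname as_month
#' @param from,to single months (anything `as_month()` accepts), inclusive.
#' @export
month_seq <- function(from, to) {
  from <- as_month(from)
  to <- as_month(to)
  stopifnot(!is.na(from), !is.na(to))
  i <- month_index(from)
  j <- month_index(to)
  if (j < i) stop("month range is reversed: ", from, " .. ", to)
  index_month(seq.int(i, j))
}

#' @rdname as_month
#' @param m a vector of months.
#' @param k integer number of calendar months to add (may be negative).
#' @export
month_add <- function(m, k) {
  m <- as_month(m)
  index_month(month_index(m) + as.integer(k))
}

#' @rdname as_month
#' @export
month_year <- function(m) {
  as.integer(substr(as_month(m), 1L, 4L))
}

# Evaluate an expression under a temporary RNG state, restoring the caller's
# stream afterwards. All generator randomness goes through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Half-up decimal rounding used only at reporting time (internal computation
# stays at full precision).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
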