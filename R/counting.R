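#' Aggregate raw coded events into monthly counts
#'
#' Sums events per (practice, code, month) inside a study window. Input
#' may be event-level (one row per recorded event, with a `date` or
#' `month` column) or pre-aggregated (an additional `count` column).
#' Occurrences are counted as-is -- repeated codes for the same patient are
#' separate occurrences, not deduplicated. Rows outside the window are
#' dropped and the exclusion is logged (one `message()` with the tally,
#' also available as attribute `"n_excluded"`).
#'
#' @param raw a data frame with columns `practice`, `code`, and `month`
#'   (or `date`), plus optionally `count`.
#' @param window length-2 vector of first and last study months
#'   (inclusive); events outside are excluded.
#' @return an event-count table: data frame `practice`, `code`, `month`,
#'   `count` with one row per nonzero cell, window attached as attribute
#'   `"window"`. Absent combinations mean zero.
#' @export
count_events <- function(raw, window) {
  stopifnot(is.data.frame(raw))
  need <- c("practice", "code")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  mcol <- if ("month" %in% names(raw)) raw$month
    else if ("date" %in% names(raw)) raw$date
    else stop("need a 'month' or 'date' column")
  month <- as_month(mcol)
  if (anyNA(month)) stop("malformed month/date in row(s): ",
    paste(utils::head(which(is.na(month)), 5L), collapse = ", "))
  count <- if ("count" %in% names(raw)) raw$count else rep(1L, nrow(raw))
  if (any(count < 0)) stop("negative count in row(s): ",
    paste(utils::head(which(count < 0), 5L), collapse = ", "))

  window <- as_month(window)
  stopifnot(length(window) == 2L, !anyNA(window))
  mi <- month_index(month)
  inside <- mi >= month_index(window[1L]) & mi <= month_index(window[2L])
  n_excluded <- sum(!inside)
  if (n_excluded > 0L) {
    message("count_events: excluded ", n_excluded,
      " row(s) outside window ", window[1L], "..", window[2L])
  }

  if (!any(inside)) {
    out <- data.frame(practice = character(), code = character(),
      month = character(), count = integer(), stringsAsFactors = FALSE)
  } else {
    # integer-keyed group sum (factor levels sort lexicographically, so
    # the output comes out ordered by practice, code, month)
    fp <- factor(raw$practice[inside])
    fc <- factor(raw$code[inside])
    fm <- factor(month[inside])
    key <- (as.numeric(fp) - 1) * (nlevels(fc) * as.numeric(nlevels(fm))) +
      (as.numeric(fc) - 1) * nlevels(fm) + as.numeric(fm)
    o <- order(key)
    k <- key[o]
    v <- as.numeric(count[inside])[o]
    b <- which(c(TRUE, k[-1L] != k[-length(k)]))     # group start positions
    ends <- c(b[-1L] - 1L, length(v))
    cs <- cumsum(v)
    tot <- cs[ends] - cs[b] + v[b]
    rep_row <- o[b]
    out <- data.frame(practice = as.character(fp)[rep_row],
      code = as.character(fc)[rep_row],
      month = as.character(fm)[rep_row],
      count = as.integer(tot), stringsAsFactors = FALSE)
    out <- out[out$count > 0L, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "window") <- window
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Roll member-code counts up to a group-level series
#'
#' The group count for a practice-month is the sum of its member codes'
#' counts; membership is treated as a set, so a code listed twice is
#' counted once.
#'
#' @param counts an event-count table (see [count_events()]).
#' @param groups a single [build_group()] result or a list of them.
#' @return an event-count table whose `code` column holds group names.
#' @export
aggregate_group_counts <- function(counts, groups) {
  if (inherits(groups, "code_group")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, logical(1L), "code_group")))
  pieces <- lapply(groups, function(g) {
    members <- unique(g$members)
    sub <- counts[counts$code %in% members, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(practice = character(), code = character(),
        month = character(), count = integer(), stringsAsFactors = FALSE))
    }
    key <- paste(sub$practice, sub$month, sep = "\r")
    tot <- rowsum(as.numeric(sub$count), group = key)
    parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
    data.frame(practice = parts[, 1L], code = g$name, month = parts[, 2L],
      count = as.integer(tot[, 1L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$practice, out$code, out$month), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- attr(counts, "window")
  out
}

#' Convert counts to rates per 1000 registered patients
#'
#' `rate = 1000 * count / list_size`, with the denominator fixed at the
#' index-date list size for every month (the study cohort is everyone
#' registered at the study end date; see [apply_index_date_attrition()]
#' for the undercount this induces). Every registry practice receives an
#' explicit 0 rate for every measured subject and month in which it has no
#' events -- published medians of 0.0 are only obtainable when
#' zero-activity practices are included. A monthly-denominator mode is
#' available but off by default.
#'
#' @param counts an event-count table (codes or group names in `code`).
#' @param practices registry data frame `practice`, `list_size` (index-date
#'   sizes), or for `denominator = "monthly"` a data frame `practice`,
#'   `month`, `list_size`.
#' @param subjects codes/groups to measure; defaults to all present in
#'   `counts`.
#' @param months months to measure; defaults to the counts' window, or the
#'   observed months when no window is attached.
#' @param denominator `"index"` (default) or `"monthly"`.
#' @return a rate table: data frame `practice`, `subject`, `month`, `rate`
#'   covering the full practice x subject x month grid.
#' @export
compute_rates <- function(counts, practices, subjects = NULL, months = NULL,
                          denominator = c("index", "monthly")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(counts), is.data.frame(practices))
  if (denominator == "index") {
    stopifnot(all(c("practice", "list_size") %in% names(practices)))
    if (anyDuplicated(practices$practice))
      stop("duplicate practice in registry")
  } else {
    stopifnot(all(c("practice", "month", "list_size") %in% names(practices)))
  }
  if (any(practices$list_size <= 0)) stop("non-positive list_size for: ",
    paste(unique(practices$practice[practices$list_size <= 0]),
      collapse = ", "))
  missing <- setdiff(unique(counts$practice), unique(practices$practice))
  if (length(missing)) stop("practice(s) in counts not in registry: ",
    paste(sort(missing), collapse = ", "))

  if (is.null(subjects)) subjects <- sort(unique(counts$code))
  if (is.null(months)) {
    w <- attr(counts, "window")
    months <- if (!is.null(w)) month_seq(w[1L], w[2L])
      else sort(unique(counts$month))
  } else months <- as_month(months)

  ids <- sort(unique(practices$practice))
  P <- length(ids); S <- length(subjects); T <- length(months)
  grid <- data.frame(
    practice = rep(ids, times = S * T),
    subject = rep(rep(subjects, each = P), times = T),
    month = rep(months, each = P * S),
    stringsAsFactors = FALSE)
  cnt <- numeric(nrow(grid))
  keep <- counts$code %in% subjects & counts$month %in% months
  if (any(keep)) {
    sub <- counts[keep, , drop = FALSE]
    pos <- match(sub$practice, ids) +
      P * (match(sub$code, subjects) - 1L) +
      P * S * (match(sub$month, months) - 1L)
    cnt[pos] <- sub$count
  }
  denom <- if (denominator == "index") {
    practices$list_size[match(grid$practice, practices$practice)]
  } else {
    m <- match(paste(grid$practice, grid$month),
      paste(practices$practice, practices$month))
    if (anyNA(m)) stop("monthly denominator missing for some practice-months")
    practices$list_size[m]
  }
  grid$rate <- 1000 * cnt / denom
  attr(grid, "denominator") <- denominator
  grid
}
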