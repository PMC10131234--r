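#' Deciles of practice-level rates
#'
#' The central descriptive display of practice variation: for one subject
#' (code or group) and month, the 10th..90th percentiles of the rate
#' across practices, the 50th being the median. The quantile rule is
#' linear interpolation between order statistics (R type 7) by default,
#' configurable and recorded on the result so published numbers can be
#' reproduced bit-for-bit. Values are never rounded here; rounding happens
#' only at reporting time.
#'
#' @param rates a rate table from [compute_rates()] (zero-filled: every
#'   registry practice present).
#' @param subject a single code or group name.
#' @param month a single month.
#' @param probs quantile probabilities (default deciles 0.1..0.9).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return a one-row data frame `subject`, `month`, `d10`..`d90`,
#'   `n_practices`.
#' @export
practice_deciles <- function(rates, subject, month,
                             probs = seq(0.1, 0.9, by = 0.1), type = 7L) {
  month <- as_month(month)
  x <- rates$rate[rates$subject == subject & rates$month == month]
  if (!length(x)) stop("no practice rates for subject '", subject,
    "' in month ", month)
  q <- stats::quantile(x, probs = probs, type = type, names = FALSE)
  out <- data.frame(subject = subject, month = month,
    as.list(stats::setNames(q, sprintf("d%d", round(100 * probs)))),
    n_practices = length(x), stringsAsFactors = FALSE)
  attr(out, "quantile_type") <- type
  out
}

#' @rdname practice_deciles
#' @param subjects,months subsets to summarise (default: all present).
#' @return `decile_series()`: a data frame with one row per subject-month,
#'   class `decile_series`.
#' @export
decile_series <- function(rates, subjects = NULL, months = NULL,
                          probs = seq(0.1, 0.9, by = 0.1), type = 7L) {
  if (is.null(subjects)) subjects <- sort(unique(rates$subject))
  if (is.null(months)) months <- sort(unique(rates$month))
  keep <- rates$subject %in% subjects & rates$month %in% months
  sub <- rates[keep, , drop = FALSE]
  f <- interaction(factor(sub$subject, levels = subjects),
    factor(sub$month, levels = months), sep = "\r", drop = FALSE)
  groups <- split(sub$rate, f)
  qn <- t(vapply(groups, function(x) {
    if (!length(x)) rep(NA_real_, length(probs) + 1L)
    else c(stats::quantile(x, probs = probs, type = type, names = FALSE),
      length(x))
  }, numeric(length(probs) + 1L)))
  parts <- do.call(rbind, strsplit(rownames(qn), "\r", fixed = TRUE))
  out <- data.frame(subject = parts[, 1L], month = parts[, 2L],
    qn[, seq_along(probs), drop = FALSE],
    n_practices = as.integer(qn[, length(probs) + 1L]),
    stringsAsFactors = FALSE)
  names(out)[2L + seq_along(probs)] <- sprintf("d%d", round(100 * probs))
  out <- out[!is.na(out$n_practices), , drop = FALSE]
  out <- out[order(out$subject, out$month), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quantile_type") <- type
  class(out) <- c("decile_series", "data.frame")
  out
}

#' @export
print.decile_series <- function(x, ...) {
  cat("<decile_series> ", length(unique(x$subject)), " subject(s) x ",
    length(unique(x$month)), " month(s), quantile type ",
    attr(x, "quantile_type") %||% 7L, "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' @rdname practice_deciles
#' @param series a `decile_series`.
#' @return `median_series()`: data frame `subject`, `month`, `median`.
#' @export
median_series <- function(series) {
  stopifnot("d50" %in% names(series))
  data.frame(subject = series$subject, month = series$month,
    median = series$d50, stringsAsFactors = FALSE)
}

#' Year-on-year percentage change
#'
#' For each subject-month with a baseline 12 calendar months earlier,
#' `pct_change = 100 * (value_t - value_{t-12}) / value_{t-12}`. Computed
#' on the median-rate series by default (the published convention); a zero
#' baseline makes the change undefined and is flagged, never emitted as 0
#' or infinity. A positive baseline with a current value of 0 is a
#' well-defined -100%.
#'
#' @param series a data frame `subject`, `month`, `median` (see
#'   [median_series()]), spanning at least 13 months for any change to be
#'   defined.
#' @return data frame `subject`, `month`, `baseline_month`, `median`,
#'   `baseline_median`, `pct_change` (`NA` when undefined), `defined`.
#' @export
pct_change_yoy <- function(series) {
  stopifnot(all(c("subject", "month", "median") %in% names(series)))
  base_month <- month_add(series$month, -12L)
  m <- match(paste(series$subject, base_month),
    paste(series$subject, series$month))
  has_base <- !is.na(m)
  baseline <- ifelse(has_base, series$median[m], NA_real_)
  defined <- has_base & !is.na(baseline) & baseline > 0
  pct <- rep(NA_real_, nrow(series))
  pct[defined] <- 100 * (series$median[defined] - baseline[defined]) /
    baseline[defined]
  out <- data.frame(subject = series$subject, month = series$month,
    baseline_month = base_month, median = series$median,
    baseline_median = baseline, pct_change = pct, defined = defined,
    stringsAsFactors = FALSE)
  out[has_base, , drop = FALSE]
}

#' Key-month summary table
#'
#' One row per subject, one cell per requested month, rendered as
#' `"median (change%)"` with both numbers rounded half-up to 1 decimal
#' place and the change sign-prefixed (e.g. `"19.8 (-86.9%)"`,
#' `"6.5 (+12.0%)"`). The change is computed at full precision and rounded
#' afterwards. When the baseline is zero (change undefined) the cell shows
#' the median only and the companion `*_flag` column is set.
#'
#' @param series data frame `subject`, `month`, `median`.
#' @param change the output of [pct_change_yoy()] on that series.
#' @param months months to report (within the series).
#' @return data frame with `subject`, one formatted column per month, and
#'   one logical `*_flag` column per month marking undefined changes.
#' @export
key_month_summary <- function(series, change, months) {
  months <- as_month(months)
  miss <- setdiff(months, series$month)
  if (length(miss)) stop("requested month(s) outside series: ",
    paste(miss, collapse = ", "))
  subjects <- sort(unique(series$subject))
  out <- data.frame(subject = subjects, stringsAsFactors = FALSE)
  for (mo in months) {
    med <- series$median[match(paste(subjects, mo),
      paste(series$subject, series$month))]
    i <- match(paste(subjects, mo), paste(change$subject, change$month))
    pc <- ifelse(is.na(i), NA_real_, change$pct_change[i])
    def <- !is.na(i) & change$defined[i]
    def[is.na(def)] <- FALSE
    cell <- ifelse(def, paste0(format_rate(med), " (",
      format_pct(pc), "%)"), format_rate(med))
    out[[mo]] <- cell
    out[[paste0(mo, "_flag")]] <- !def
  }
  out
}

format_rate <- function(x) sprintf("%.1f", round_half_up(x, 1L))

format_pct <- function(x) {
  r <- round_half_up(x, 1L)
  ifelse(is.na(r), NA_character_,
    ifelse(r >= 0, sprintf("+%.1f", r), sprintf("%.1f", r)))
}

#' Default thresholds for disruption/recovery classification
#'
#' @param maintained_drop if the nadir change is above this (percent), the
#'   activity was maintained throughout.
#' @param increase_terminal terminal change above this is an increase over
#'   baseline.
#' @param recovered_terminal terminal change in
#'   `(recovered_terminal, increase_terminal]` is recovery to near-normal.
#' @param partial_terminal terminal change in
#'   `(partial_terminal, recovered_terminal]` is partial recovery; at or
#'   below it, a sustained drop.
#' @return a named list of thresholds (percent).
#' @export
recovery_thresholds <- function(maintained_drop = -20,
                                increase_terminal = 10,
                                recovered_terminal = -10,
                                partial_terminal = -30) {
  stopifnot(partial_terminal <= recovered_terminal,
    recovered_terminal <= increase_terminal)
  list(maintained_drop = maintained_drop,
    increase_terminal = increase_terminal,
    recovered_terminal = recovered_terminal,
    partial_terminal = partial_terminal)
}

#' Classify disruption and recovery from year-on-year changes
#'
#' Operationalises the qualitative vocabulary of service-restoration
#' reports ("substantial decline with good recovery", "sustained drop")
#' as a deterministic function of two numbers per subject: the nadir
#' change (most negative year-on-year change within the disruption
#' window) and the terminal change (at the final study month). With the
#' default thresholds: a nadir above -20% is `maintained`; otherwise the
#' terminal change decides between `increase` (> +10%), `recovered`
#' ((-10, +10]), `partial_recovery` ((-30, -10]) and `sustained_drop`
#' (<= -30%).
#'
#' @param change output of [pct_change_yoy()].
#' @param disruption_month first month of the disruption window.
#' @param final_month the terminal month of the study.
#' @param thresholds a [recovery_thresholds()] list.
#' @param window_months length of the disruption window in months
#'   (nadir is sought in `disruption_month .. disruption_month +
#'   window_months - 1`).
#' @return an object of class `recovery_classification`: data frame
#'   `subject`, `drop_pct`, `terminal_pct`, `category`.
#' @export
classify_recovery <- function(change, disruption_month, final_month,
                              thresholds = recovery_thresholds(),
                              window_months = 3L) {
  disruption_month <- as_month(disruption_month)
  final_month <- as_month(final_month)
  win <- month_seq(disruption_month,
    month_add(disruption_month, window_months - 1L))
  subjects <- sort(unique(change$subject))
  rows <- lapply(subjects, function(s) {
    ch <- change[change$subject == s & change$defined, , drop = FALSE]
    if (!nrow(ch)) stop("subject '", s,
      "' has no defined year-on-year changes")
    in_win <- ch[ch$month %in% win, , drop = FALSE]
    drop_pct <- if (nrow(in_win)) min(in_win$pct_change) else NA_real_
    terminal_pct <- ch$pct_change[ch$month == final_month]
    if (!length(terminal_pct)) terminal_pct <- NA_real_
    data.frame(subject = s, drop_pct = drop_pct,
      terminal_pct = terminal_pct,
      category = classify_one(drop_pct, terminal_pct, thresholds),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  attr(out, "disruption_window") <- win
  attr(out, "final_month") <- final_month
  class(out) <- c("recovery_classification", "data.frame")
  out
}

classify_one <- function(drop_pct, terminal_pct, th) {
  if (is.na(drop_pct) || is.na(terminal_pct)) return(NA_character_)
  if (drop_pct > th$maintained_drop) return("maintained")
  if (terminal_pct > th$increase_terminal) return("increase")
  if (terminal_pct > th$recovered_terminal) return("recovered")
  if (terminal_pct > th$partial_terminal) return("partial_recovery")
  "sustained_drop"
}

#' @export
print.recovery_classification <- function(x, ...) {
  cat("<recovery_classification> ", nrow(x), " subject(s); window ",
    attr(x, "disruption_window")[1L], "..",
    utils::tail(attr(x, "disruption_window"), 1L), ", terminal ",
    attr(x, "final_month"), "\n", sep = "")
  print(table(x$category))
  invisible(x)
}
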