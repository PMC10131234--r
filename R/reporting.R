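#' Summarise practice-level activity for a set of subjects
#'
#' The package's central analysis step: from a zero-filled rate table it
#' computes the decile series across practices, the year-on-year
#' percentage change of the median-rate series, and the
#' disruption/recovery classification, returning them together as one
#' classed object with `print`, `summary` and `plot` methods.
#'
#' @param rates a rate table from [compute_rates()].
#' @param disruption_month first month of the disruption window (used for
#'   the nadir search).
#' @param final_month terminal study month (used for the terminal change);
#'   defaults to the last month in `rates`.
#' @param key_months months for the key-month summary table.
#' @param thresholds a [recovery_thresholds()] list.
#' @param window_months disruption-window length for the nadir search.
#' @param quantile_type quantile rule for the deciles.
#' @return an object of class `activity_measures`: list with `deciles`
#'   (a [decile_series()]), `change` ([pct_change_yoy()]), `classification`
#'   ([classify_recovery()]) and `key_months` ([key_month_summary()]).
#' @examples
#' cfg <- synthetic_config(n_practices = 40, n_codes = 8, seed = 42)
#' pr <- generate_practices(cfg)
#' ev <- generate_events(cfg, pr,
#'   profiles = list(C001 = disruption_profile("2020-04", 0.8)))
#' rt <- compute_rates(ev, pr)
#' am <- activity_measures(rt, disruption_month = "2020-04")
#' am$classification
#' @export
activity_measures <- function(rates,
                              disruption_month = "2020-04",
                              final_month = NULL,
                              key_months = NULL,
                              thresholds = recovery_thresholds(),
                              window_months = 3L,
                              quantile_type = 7L) {
  series <- decile_series(rates, type = quantile_type)
  med <- median_series(series)
  change <- pct_change_yoy(med)
  if (is.null(final_month)) final_month <- max(med$month)
  classification <- classify_recovery(change, disruption_month,
    final_month, thresholds = thresholds, window_months = window_months)
  km <- if (is.null(key_months)) NULL
    else key_month_summary(med, change, key_months)
  structure(list(deciles = series, change = change,
    classification = classification, key_months = km,
    disruption_month = as_month(disruption_month),
    final_month = as_month(final_month)),
    class = "activity_measures")
}

#' @export
print.activity_measures <- function(x, ...) {
  cat("<activity_measures> ", length(unique(x$deciles$subject)),
    " subject(s), months ", min(x$deciles$month), "..",
    max(x$deciles$month), "\n", sep = "")
  print(table(x$classification$category))
  invisible(x)
}

#' @export
summary.activity_measures <- function(object, ...) {
  cls <- as.data.frame(object$classification)
  cat("Disruption month:", object$disruption_month,
    " terminal month:", object$final_month, "\n")
  cat("Median nadir change: ",
    sprintf("%.1f%%", stats::median(cls$drop_pct, na.rm = TRUE)),
    ";  median terminal change: ",
    sprintf("%.1f%%", stats::median(cls$terminal_pct, na.rm = TRUE)),
    "\n", sep = "")
  print(table(cls$category))
  invisible(cls)
}

#' @export
plot.activity_measures <- function(x, subjects = NULL, ...) {
  plot(x$deciles, subjects = subjects, ...)
}

#' Plot a decile series
#'
#' The standard decile chart: for each subject, one panel with months on
#' the x axis and the rate per 1000 registered patients on the y axis;
#' the median drawn as a solid line, the other deciles dashed.
#'
#' @param x a [decile_series()].
#' @param subjects subjects to draw (default: all, one panel each).
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.decile_series <- function(x, subjects = NULL, ...) {
  if (is.null(subjects)) subjects <- unique(x$subject)
  dcols <- grep("^d\\d+$", names(x), value = TRUE)
  nf <- grDevices::n2mfrow(length(subjects))
  old <- graphics::par(mfrow = nf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (s in subjects) {
    sub <- x[x$subject == s, , drop = FALSE]
    sub <- sub[order(sub$month), , drop = FALSE]
    mat <- as.matrix(sub[, dcols, drop = FALSE])
    lty <- ifelse(dcols == "d50", 1L, 2L)
    graphics::matplot(seq_len(nrow(sub)), mat, type = "l", lty = lty,
      col = "black", xaxt = "n", xlab = "Month",
      ylab = "Rate per 1000 patients", main = s, ...)
    ticks <- seq(1L, nrow(sub), by = max(1L, nrow(sub) %/% 8L))
    graphics::axis(1, at = ticks, labels = sub$month[ticks], las = 2,
      cex.axis = 0.7)
  }
  invisible(x)
}

#' Render a decile chart to an SVG file
#'
#' @param series a [decile_series()] with at least one month.
#' @param file output path (`.svg`).
#' @param subjects subjects to draw.
#' @param width,height device size in inches.
#' @return the file path, invisibly.
#' @export
render_decile_chart <- function(series, file, subjects = NULL,
                                width = 8, height = 6) {
  if (!nrow(series)) stop("empty decile series")
  grDevices::svg(file, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(series, subjects = subjects)
  invisible(file)
}

#' Monthly total counts for one subject
#'
#' Sums counts across all practices per month -- the display used for
#' newly introduced codes (e.g. Structured Medication Reviews under their
#' long SNOMED identifier) whose practice deciles are mostly zero. Months
#' of the window with no events are reported as 0.
#'
#' @param counts an event-count table.
#' @param subject a code or group name present in `counts` (or in the
#'   supplied `months` window).
#' @param months months to cover; defaults to the counts' window.
#' @return data frame `month`, `total`.
#' @export
total_counts <- function(counts, subject, months = NULL) {
  if (!subject %in% counts$code) stop("unknown subject: ", subject)
  if (is.null(months)) {
    w <- attr(counts, "window")
    months <- if (!is.null(w)) month_seq(w[1L], w[2L])
      else sort(unique(counts$month))
  } else months <- as_month(months)
  sub <- counts[counts$code == subject & counts$month %in% months, ,
    drop = FALSE]
  tot <- stats::setNames(rep(0, length(months)), months)
  if (nrow(sub)) {
    t <- rowsum(as.numeric(sub$count), group = sub$month)
    tot[rownames(t)] <- t[, 1L]
  }
  data.frame(month = months, total = as.numeric(tot),
    stringsAsFactors = FALSE)
}

#' @rdname total_counts
#' @param file_stem path stem; writes `<stem>.csv` and `<stem>.svg`.
#' @export
render_total_counts <- function(counts, subject, file_stem, months = NULL) {
  tot <- total_counts(counts, subject, months = months)
  utils::write.csv(tot, paste0(file_stem, ".csv"), row.names = FALSE)
  grDevices::svg(paste0(file_stem, ".svg"), width = 7, height = 4)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(seq_len(nrow(tot)), tot$total, type = "l", xaxt = "n",
    xlab = "Month", ylab = "Total events", main = subject)
  ticks <- seq(1L, nrow(tot), by = max(1L, nrow(tot) %/% 8L))
  graphics::axis(1, at = ticks, labels = tot$month[ticks], las = 2,
    cex.axis = 0.7)
  invisible(tot)
}

#' Run manifest
#'
#' Every pipeline output directory carries one manifest recording the
#' exact configuration (as a canonical-JSON MD5 hash and in full), the
#' seed, study window, quantile rule and frequency threshold, so a run
#' can be reproduced byte-for-byte.
#'
#' @param config the merged pipeline configuration (a list).
#' @param path output path for the JSON manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, path) {
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
    null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(canon, tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    config = config,
    package_version = as.character(utils::packageVersion("ehrmonitor")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(manifest)
}
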