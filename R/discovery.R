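#' Configuration for data-driven code discovery
#'
#' Controls how high-volume codes are selected and organised into clinical
#' topics. The default frequency threshold retains codes with at least
#' 1000 total occurrences across all practices in the threshold year --
#' the rule used to surface the most frequent clinical activities while
#' discarding rarely used codes (a total of exactly 1000 is retained; only
#' strictly fewer occurrences are excluded).
#'
#' @param threshold minimum total occurrences in `threshold_year` for a
#'   code to be retained (>= 1).
#' @param threshold_year calendar year whose totals are thresholded.
#' @param topic_rules ordered list of [topic_rule()] definitions. A code
#'   may match several topics; codes matching none are assigned the
#'   reserved topic `"unclassified"`.
#' @param exclusions character vector of code prefixes to drop from
#'   selection regardless of volume (e.g. medication/vaccination record
#'   codes); a full code string excludes itself and any longer code
#'   sharing it as a prefix.
#' @return an object of class `discovery_config`.
#' @export
discovery_config <- function(threshold = 1000L, threshold_year = 2020L,
                             topic_rules = list(),
                             exclusions = character()) {
  stopifnot(threshold >= 1L, length(threshold_year) == 1L)
  nm <- vapply(topic_rules, `[[`, character(1L), "topic")
  if (anyDuplicated(nm)) stop("duplicate topic name(s): ",
    paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(threshold = as.integer(threshold),
    threshold_year = as.integer(threshold_year),
    topic_rules = topic_rules,
    exclusions = as.character(exclusions)), class = "discovery_config")
}

#' @rdname discovery_config
#' @param topic topic name (e.g. `"cardiovascular"`).
#' @param prefixes code-string prefixes assigned to the topic.
#' @param keywords description keywords (matched case-insensitively as
#'   substrings).
#' @param codes explicit code list.
#' @export
topic_rule <- function(topic, prefixes = character(),
                       keywords = character(), codes = character()) {
  stopifnot(is.character(topic), length(topic) == 1L)
  list(topic = topic, prefixes = as.character(prefixes),
    keywords = as.character(keywords), codes = as.character(codes))
}

#' Select high-volume codes by annual total
#'
#' Sums each code's counts over all practices and all months of the
#' threshold year and retains codes whose total meets the threshold.
#' Exclusion prefixes from the config are applied afterwards.
#'
#' @param counts an event-count table (see [count_events()]).
#' @param cfg a [discovery_config()].
#' @return sorted character vector of retained codes, with the per-code
#'   annual totals (all codes, pre-exclusion) as attribute `"totals"`.
#' @export
frequency_filter <- function(counts, cfg) {
  stopifnot(inherits(cfg, "discovery_config"))
  w <- attr(counts, "window")
  if (!is.null(w)) {
    years <- month_year(w[1L]):month_year(w[2L])
    if (!cfg$threshold_year %in% years)
      stop("threshold_year ", cfg$threshold_year,
        " outside study window ", w[1L], "..", w[2L])
  }
  in_year <- month_year(counts$month) == cfg$threshold_year
  totals <- if (any(in_year)) {
    t <- rowsum(as.numeric(counts$count[in_year]),
      group = counts$code[in_year])
    stats::setNames(t[, 1L], rownames(t))
  } else stats::setNames(numeric(), character())
  selected <- sort(names(totals)[totals >= cfg$threshold])
  if (length(cfg$exclusions)) {
    drop <- Reduce(`|`, lapply(cfg$exclusions, startsWith, x = selected),
      accumulate = FALSE, init = rep(FALSE, length(selected)))
    selected <- selected[!drop]
  }
  attr(selected, "totals") <- totals
  selected
}

#' Assign clinical topics to selected codes
#'
#' A code matches a topic if it satisfies any of the topic's prefix,
#' keyword, or explicit-code rules; multi-topic membership is allowed
#' (e.g. diabetic retinopathy screening belongs with both screening and
#' diabetes). Codes matching no rule receive `"unclassified"`.
#'
#' @param selected character vector of code identifiers.
#' @param h a [code_hierarchy()] providing descriptions for keyword rules.
#' @param cfg a [discovery_config()] with `topic_rules`.
#' @return named list: for each code, the character vector of its topics.
#' @export
assign_topics <- function(selected, h, cfg) {
  stopifnot(inherits(h, "code_hierarchy"), inherits(cfg, "discovery_config"))
  desc <- tolower(h$codes$description[match(selected, h$codes$code)])
  desc[is.na(desc)] <- ""
  out <- stats::setNames(vector("list", length(selected)), selected)
  for (rule in cfg$topic_rules) {
    hit <- selected %in% rule$codes
    for (p in rule$prefixes) hit <- hit | startsWith(selected, p)
    for (k in tolower(rule$keywords)) hit <- hit | grepl(k, desc, fixed = TRUE)
    for (i in which(hit)) out[[i]] <- c(out[[i]], rule$topic)
  }
  lapply(out, function(x) if (is.null(x)) "unclassified" else unique(x))
}

#' Report overlaps between code groups
#'
#' Prefix groups and explicitly listed codes can overlap (a "24" prefix
#' group contains any individually analysed code beginning "24"). This
#' reports, without modifying the groups: every code that belongs to more
#' than one group, and every ordered group pair where one group's members
#' are a subset of the other's.
#'
#' @param groups list of [build_group()] results.
#' @return an object of class `overlap_report`: list with `shared_codes`
#'   (data frame `code`, `groups`) and `containment` (data frame `inner`,
#'   `outer`).
#' @export
resolve_overlaps <- function(groups) {
  stopifnot(all(vapply(groups, inherits, logical(1L), "code_group")))
  nm <- vapply(groups, `[[`, character(1L), "name")
  membership <- lapply(groups, `[[`, "members")
  names(membership) <- nm
  all_codes <- sort(unique(unlist(membership)))
  in_groups <- lapply(all_codes, function(cd)
    nm[vapply(membership, function(m) cd %in% m, logical(1L))])
  multi <- lengths(in_groups) > 1L
  shared <- data.frame(code = all_codes[multi],
    groups = vapply(in_groups[multi], paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)
  pairs <- list()
  if (length(groups) >= 2L) {
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i != j && all(membership[[i]] %in% membership[[j]]))
        pairs[[length(pairs) + 1L]] <- c(nm[i], nm[j])
    }
  }
  containment <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(inner = m[, 1L], outer = m[, 2L], stringsAsFactors = FALSE)
  } else data.frame(inner = character(), outer = character(),
    stringsAsFactors = FALSE)
  structure(list(shared_codes = shared, containment = containment),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> ", nrow(x$shared_codes), " shared code(s), ",
    nrow(x$containment), " containment pair(s)\n", sep = "")
  invisible(x)
}

#' Tabulate the discovery result
#'
#' One row per selected code with its description, annual total and
#' assigned topics -- the shape emitted to the selection CSV.
#'
#' @param counts an event-count table.
#' @param h a [code_hierarchy()].
#' @param cfg a [discovery_config()].
#' @return data frame `code`, `description`, `total`, `topics`, sorted by
#'   descending total.
#' @export
discovery_table <- function(counts, h, cfg) {
  selected <- frequency_filter(counts, cfg)
  totals <- attr(selected, "totals")
  topics <- assign_topics(selected, h, cfg)
  out <- data.frame(
    code = as.character(selected),
    description = h$codes$description[match(selected, h$codes$code)],
    total = as.numeric(totals[selected]),
    topics = vapply(topics, paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)
  out$description[is.na(out$description)] <- ""
  out <- out[order(-out$total, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}
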