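#' Synthetic-data generator configuration
#'
#' Bundles every parameter of the synthetic EHR generator. The defaults
#' describe a medium-sized study: 200 general practices with log-normal
#' list sizes (median about 8000 registered patients), 60 clinical codes
#' with heavy-tailed baseline usage rates, mild annual seasonality,
#' negative-binomial count noise, persistent multiplicative between-practice
#' heterogeneity, and a two-year monthly window with the denominator
#' population fixed at the study end date.
#'
#' @param n_practices number of general practices.
#' @param list_size list with `meanlog`, `sdlog`: log-normal parameters of
#'   the registered-patient list size (rounded, floored at 1). `sdlog = 0`
#'   gives every practice the same size.
#' @param n_codes number of clinical codes in the toy terminology.
#' @param baseline_rate list with `meanlog`, `sdlog`: log-normal parameters
#'   of the per-code mean monthly rate per 1000 registered patients. A
#'   large `sdlog` yields the heavy-tailed, power-law-like frequency
#'   profile seen in real coded activity.
#' @param practice_effect_sd log-scale SD of the multiplicative practice
#'   effect (constant over time); this is what spreads the practice
#'   deciles. 0 makes all practices identical.
#' @param seasonality_amplitude sinusoidal seasonal amplitude in `[0, 1)`;
#'   0 disables seasonality.
#' @param seasonality_phase month of the seasonal peak (1 = January).
#' @param dispersion negative-binomial size parameter of the count noise
#'   (variance `mu + mu^2/dispersion`); `Inf` gives Poisson counts.
#' @param study_window length-2 vector of first and last study months.
#' @param index_date ISO date at which the registered population is fixed
#'   (the denominator date; also the last month never subject to
#'   attrition).
#' @param attrition_fraction_start fraction (in `[0, 0.1]`) of events lost
#'   in the first study month due to fixing the population at the index
#'   date; the loss declines linearly to 0 at the index month.
#' @param seed integer master seed; identical config + seed reproduces
#'   every generated object exactly.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_practices = 200L,
                             list_size = list(meanlog = log(8000), sdlog = 0.45),
                             n_codes = 60L,
                             baseline_rate = list(meanlog = log(5), sdlog = 1),
                             practice_effect_sd = 0.35,
                             seasonality_amplitude = 0.1,
                             seasonality_phase = 1L,
                             dispersion = 15,
                             study_window = c("2019-01", "2020-12"),
                             index_date = "2020-12-31",
                             attrition_fraction_start = 0,
                             seed = 1L) {
  stopifnot(n_practices >= 1L, n_codes >= 1L,
    is.list(list_size), is.numeric(list_size$meanlog),
    is.numeric(list_size$sdlog), list_size$sdlog >= 0,
    is.list(baseline_rate), baseline_rate$sdlog >= 0,
    practice_effect_sd >= 0,
    seasonality_amplitude >= 0, seasonality_amplitude < 1,
    dispersion > 0,
    attrition_fraction_start >= 0, attrition_fraction_start <= 0.1,
    length(study_window) == 2L)
  window <- as_month(study_window)
  if (anyNA(window)) stop("invalid study_window")
  if (month_index(window[2L]) < month_index(window[1L]))
    stop("study_window is reversed")
  idx_month <- as_month(index_date)
  if (is.na(idx_month)) stop("invalid index_date")
  structure(list(
    n_practices = as.integer(n_practices),
    list_size = list_size,
    n_codes = as.integer(n_codes),
    baseline_rate = baseline_rate,
    practice_effect_sd = practice_effect_sd,
    seasonality_amplitude = seasonality_amplitude,
    seasonality_phase = as.integer(seasonality_phase),
    dispersion = dispersion,
    study_window = window,
    index_date = index_date,
    index_month = idx_month,
    attrition_fraction_start = attrition_fraction_start,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_practices, " practices, ", x$n_codes,
    " codes, ", x$study_window[1L], "..", x$study_window[2L],
    ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# distinct, fixed RNG stream offsets so each generator is reproducible both
# standalone and inside the pipeline
seed_for <- function(config, stream) {
  offsets <- c(practices = 11L, terminology = 23L, rates = 37L,
    effects = 53L, events = 71L, attrition = 89L)
  (config$seed + offsets[[stream]]) %% .Machine$integer.max
}

#' Generate a synthetic practice registry
#'
#' Draws practice list sizes from the configured log-normal distribution.
#'
#' @param config a [synthetic_config()].
#' @return a data frame with columns `practice` and `list_size`
#'   (integer, at least 1), one row per practice.
#' @export
generate_practices <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sizes <- with_seed(seed_for(config, "practices"), {
    stats::rlnorm(config$n_practices,
      meanlog = config$list_size$meanlog, sdlog = config$list_size$sdlog)
  })
  data.frame(
    practice = sprintf("P%04d", seq_len(config$n_practices)),
    list_size = pmax(1L, as.integer(round(sizes))),
    stringsAsFactors = FALSE)
}

#' Disruption profile: a multiplicative trajectory on expected rates
#'
#' Describes an abrupt service disruption and its recovery as a
#' multiplier `m(t)` on the baseline expected rate: `m = 1` before the
#' disruption month, `m = 1 - drop_fraction` at the disruption month, then
#' an approach to `terminal_level` over `recovery_months` following the
#' chosen shape. `terminal_level = 1` is full recovery, `0.6` a sustained
#' 40% drop, `1.2` a 20% increase over baseline.
#'
#' @param disruption_month the month of the abrupt drop.
#' @param drop_fraction proportional reduction at the disruption month, in
#'   `[0, 1]`.
#' @param recovery_shape one of `"none"` (stays at the dropped level),
#'   `"linear"`, `"exponential"` (fast-then-slow approach), `"overshoot"`
#'   (transiently exceeds the terminal level before settling).
#' @param recovery_months months over which the terminal level is reached.
#' @param terminal_level long-run multiplier of baseline (> 0).
#' @return an object of class `disruption_profile`.
#' @export
disruption_profile <- function(disruption_month,
                               drop_fraction,
                               recovery_shape = c("linear", "none",
                                 "exponential", "overshoot"),
                               recovery_months = 8L,
                               terminal_level = 1) {
  recovery_shape <- match.arg(recovery_shape)
  stopifnot(drop_fraction >= 0, drop_fraction <= 1,
    recovery_months >= 1L, terminal_level > 0)
  m <- as_month(disruption_month)
  if (is.na(m)) stop("invalid disruption_month")
  structure(list(disruption_month = m,
    drop_fraction = drop_fraction,
    recovery_shape = recovery_shape,
    recovery_months = as.integer(recovery_months),
    terminal_level = terminal_level), class = "disruption_profile")
}

#' @rdname disruption_profile
#' @param profile a `disruption_profile`, or `NULL` for no disruption.
#' @param months character vector of months at which to evaluate the
#'   multiplier.
#' @return `disruption_multiplier()`: a numeric vector, one multiplier per
#'   month.
#' @export
disruption_multiplier <- function(profile, months) {
  months <- as_month(months)
  if (is.null(profile)) return(rep(1, length(months)))
  stopifnot(inherits(profile, "disruption_profile"))
  t0 <- month_index(profile$disruption_month)
  s <- (month_index(months) - t0) / profile$recovery_months
  low <- 1 - profile$drop_fraction
  gap <- profile$terminal_level - low
  m <- rep(1, length(months))
  during <- s >= 0 & s < 1
  after <- s >= 1
  m[during] <- switch(profile$recovery_shape,
    none = low,
    linear = low + gap * s[during],
    # ~1% of the gap left at the end of the recovery period
    exponential = profile$terminal_level - gap * exp(-log(100) * s[during]),
    overshoot = low + gap * (s[during] + 0.3 * sin(pi * s[during]^2)))
  m[after] <- if (profile$recovery_shape == "none") low else
    profile$terminal_level
  m
}

#' Generate synthetic monthly coded-event counts
#'
#' Simulates one count per (practice, code, month): the expected count is
#' `list_size/1000 * base_rate * practice_effect * season(t) * m(t)` where
#' `m(t)` is the code's disruption multiplier, and the realised count is
#' negative-binomial around it (Poisson when `dispersion = Inf`). Zero
#' counts are omitted from the returned table (absence means zero).
#'
#' @param config a [synthetic_config()].
#' @param practices registry from [generate_practices()].
#' @param code_rates named numeric vector: per-code baseline mean monthly
#'   rate per 1000 registered patients. Defaults to rates drawn from
#'   `config$baseline_rate`, named `C001..`, or taken from a hierarchy via
#'   [generate_code_rates()].
#' @param profiles named list mapping a code to its [disruption_profile()];
#'   codes absent from the list are undisrupted. Every name must appear in
#'   `code_rates`.
#' @return an event-count table: data frame with columns `practice`,
#'   `code`, `month`, `count`, carrying the study window as attribute
#'   `"window"`.
#' @export
generate_events <- function(config, practices,
                            code_rates = NULL,
                            profiles = list()) {
  stopifnot(inherits(config, "synthetic_config"), is.data.frame(practices))
  if (is.null(code_rates)) code_rates <- generate_code_rates(config)
  if (length(profiles)) {
    bad <- setdiff(names(profiles), names(code_rates))
    if (length(bad)) stop("profiled code(s) not in code_rates: ",
      paste(bad, collapse = ", "))
  }
  months <- month_seq(config$study_window[1L], config$study_window[2L])
  P <- nrow(practices); C <- length(code_rates); T <- length(months)

  effects <- with_seed(seed_for(config, "effects"), {
    sd <- config$practice_effect_sd
    exp(stats::rnorm(P, mean = -sd^2 / 2, sd = sd))  # mean-1 multiplier
  })
  season <- 1 + config$seasonality_amplitude *
    cos(2 * pi * (month_index(months) %% 12L + 1L -
      config$seasonality_phase) / 12)
  mult <- vapply(names(code_rates), function(cd)
    disruption_multiplier(profiles[[cd]], months), numeric(T))

  # mu laid out practice-fastest, then code, then month
  base_p <- practices$list_size / 1000 * effects                   # length P
  pc <- as.vector(outer(base_p, as.numeric(code_rates)))           # P*C
  ct <- as.vector(t(mult) * matrix(season, C, T, byrow = TRUE))    # C*T
  mu <- rep(pc, times = T) * rep(ct, each = P)

  counts <- with_seed(seed_for(config, "events"), {
    if (is.infinite(config$dispersion)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = config$dispersion, mu = mu)
  })

  keep <- counts > 0L
  out <- data.frame(
    practice = rep(practices$practice, times = C * T)[keep],
    code = rep(rep(names(code_rates), each = P), times = T)[keep],
    month = rep(months, each = P * C)[keep],
    count = as.integer(counts[keep]),
    stringsAsFactors = FALSE)
  attr(out, "window") <- config$study_window
  out
}

#' @rdname generate_events
#' @param codes optional character vector of code identifiers to attach the
#'   rates to (defaults to `C001..C<n_codes>`).
#' @export
generate_code_rates <- function(config, codes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(codes)) codes <- sprintf("C%03d", seq_len(config$n_codes))
  rates <- with_seed(seed_for(config, "rates"), {
    stats::rlnorm(length(codes), meanlog = config$baseline_rate$meanlog,
      sdlog = config$baseline_rate$sdlog)
  })
  names(rates) <- codes
  rates
}

#' Emulate index-date attrition of early-period counts
#'
#' Fixing the denominator population at the study end date removes the
#' events of patients who died or deregistered before it, so recorded
#' activity in the earliest months undercounts the true totals. This is
#' emulated by binomial thinning: counts in month `t` are retained with
#' probability `1 - a(t)`, where `a(t)` declines linearly from
#' `attrition_fraction_start` at the first study month to 0 at the index
#' month (which is never thinned).
#'
#' @param counts an event-count table (columns `practice`, `code`, `month`,
#'   `count`).
#' @param config a [synthetic_config()].
#' @return the thinned event-count table (zero rows dropped).
#' @export
apply_index_date_attrition <- function(counts, config) {
  stopifnot(inherits(config, "synthetic_config"))
  a0 <- config$attrition_fraction_start
  if (a0 == 0 || nrow(counts) == 0L) return(counts)
  t0 <- month_index(config$study_window[1L])
  tI <- month_index(config$index_month)
  if (tI <= t0) return(counts)
  a <- a0 * pmax(0, tI - month_index(counts$month)) / (tI - t0)
  thinned <- with_seed(seed_for(config, "attrition"), {
    stats::rbinom(nrow(counts), size = counts$count, prob = 1 - a)
  })
  out <- counts
  out$count <- thinned
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- attr(counts, "window")
  out
}

#' Generate a toy clinical terminology
#'
#' Builds a small CTV3-like forest with 2-3 levels and prefix-consistent
#' 5-character code strings (roots `Aa...`, children `Aab..`, grandchildren
#' `Aabc.`), with synthetic descriptions assembled from clinical keyword
#' pools ("review", "monitoring", "screening", ...) so that keyword search
#' is exercisable against it.
#'
#' @param config a [synthetic_config()].
#' @return a [code_hierarchy()] with `config$n_codes` codes.
#' @export
generate_toy_terminology <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_codes
  areas <- c("cardiovascular", "diabetic", "mental health", "contraception",
    "screening", "medication")
  acts <- c("examination", "monitoring", "review", "screening", "test",
    "risk score", "smear", "assessment")
  with_seed(seed_for(config, "terminology"), {
    n_roots <- max(1L, min(length(areas), ceiling(n / 8)))
    stems <- paste0(LETTERS[seq_len(n_roots)],
      letters[seq_len(n_roots)])                         # "Aa", "Bb", ...
    code <- paste0(stems, "...")
    description <- paste0(toupper(substr(areas[seq_len(n_roots)], 1, 1)),
      substring(areas[seq_len(n_roots)], 2), " activity")
    parent <- rep(NA_character_, n_roots)
    while (length(code) < n) {
      # attach a child to a random existing code of depth < 3
      stem_len <- nchar(sub("\\.+$", "", code))
      eligible <- which(stem_len < 4L)
      p <- code[sample(eligible, 1L)]
      stem <- sub("\\.+$", "", p)
      used <- substr(sub("\\.+$", "", code[startsWith(code, stem)]),
        nchar(stem) + 1L, nchar(stem) + 1L)
      pool <- setdiff(c(letters, LETTERS, 0:9), used[used != ""])
      if (!length(pool)) next
      new_stem <- paste0(stem, sample(pool, 1L))
      new_code <- paste0(new_stem, strrep(".", 5L - nchar(new_stem)))
      area <- sub(" activity$", "",
        description[match(paste0(substr(new_code, 1, 2), "..."), code)])
      code <- c(code, new_code)
      parent <- c(parent, p)
      description <- c(description,
        paste(sample(c(area, paste(area, sample(acts, 1L))), 1L),
          sample(acts, 1L)))
    }
    # guarantee a searchable seeded keyword
    if (!any(grepl("review", description, fixed = TRUE))) {
      description[length(description)] <-
        paste(description[length(description)], "review")
    }
    code_hierarchy(data.frame(code = code, description = description,
      parent = parent, stringsAsFactors = FALSE))
  })
}
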