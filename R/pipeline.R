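#' Default pipeline configuration
#'
#' The full pipeline is driven by one nested configuration (read from
#' YAML by [run_pipeline()], or passed as a list). `pipeline_defaults()`
#' documents every key and its default; user values are merged over it
#' key-wise.
#'
#' @return nested list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    synthetic = list(
      n_practices = 50L,
      list_size = list(meanlog = log(8000), sdlog = 0.45),
      n_codes = 20L,
      baseline_rate = list(meanlog = log(5), sdlog = 1),
      practice_effect_sd = 0.35,
      seasonality_amplitude = 0.1,
      seasonality_phase = 1L,
      dispersion = 15,
      study_window = c("2019-01", "2020-12"),
      index_date = "2020-12-31",
      attrition_fraction_start = 0,
      profiles = list()),
    discovery = list(
      threshold = 1000L,
      threshold_year = 2020L,
      topics = list(),
      exclusions = character()),
    measures = list(
      disruption_month = "2020-04",
      final_month = "2020-12",
      key_months = c("2020-02", "2020-04", "2020-12"),
      window_months = 3L,
      quantile_type = 7L),
    report = list(
      charts = TRUE,
      chart_subjects = 4L))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(user[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full observatory pipeline
#'
#' Executes generate (synthetic data) -> count -> discover -> measure ->
#' report, writing a manifest, the practice registry and event table, the
#' code-selection table, the decile series, the key-month summary, the
#' recovery classification and (optionally) decile charts to `out_dir`.
#' All randomness derives from `config$seed`: identical configuration and
#' seed produce byte-identical CSV outputs. Each stage logs one line with
#' its row counts; any stage failure aborts the run with the stage named,
#' and partial outputs are left quarantined in a `.partial` staging
#' directory rather than mixed with complete ones.
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   nested list (see [pipeline_defaults()]).
#' @param out_dir output directory (created; must not already contain a
#'   manifest from another run unless `overwrite = TRUE`).
#' @param overwrite replace existing outputs.
#' @return the output directory path, invisibly; the merged configuration
#'   is attached as attribute `"config"`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_config(pipeline_defaults(), config)

  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json"))
      && !overwrite) {
    stop("output directory already contains a run; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- file.path(out_dir, ".partial")
  unlink(stage_dir, recursive = TRUE)
  dir.create(stage_dir, recursive = TRUE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })
  }
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(stage_dir, name), row.names = FALSE)
  }

  # -- generate ---------------------------------------------------------
  gen <- run_stage("generate", {
    scfg <- do.call(synthetic_config, c(
      cfg$synthetic[setdiff(names(cfg$synthetic), "profiles")],
      list(seed = cfg$seed)))
    practices <- generate_practices(scfg)
    terminology <- generate_toy_terminology(scfg)
    code_rates <- generate_code_rates(scfg, codes = terminology$codes$code)
    profiles <- list()
    for (p in cfg$synthetic$profiles) {
      prof <- disruption_profile(p$disruption_month, p$drop_fraction,
        p$recovery_shape %||% "linear", p$recovery_months %||% 8L,
        p$terminal_level %||% 1)
      target <- if (identical(p$codes, "all")) names(code_rates)
        else unique(c(intersect(p$codes %||% character(),
            names(code_rates)),
          unlist(lapply(p$prefixes %||% character(), function(px)
            names(code_rates)[startsWith(names(code_rates), px)]))))
      for (cd in target) profiles[[cd]] <- prof
    }
    events <- generate_events(scfg, practices, code_rates, profiles)
    events <- apply_index_date_attrition(events, scfg)
    list(scfg = scfg, practices = practices, terminology = terminology,
      events = events)
  })
  message("stage generate: ", nrow(gen$practices), " practices, ",
    nrow(gen$events), " event rows")
  wcsv(gen$practices, "practices.csv")
  wcsv(gen$events, "events.csv")
  write_terminology(gen$terminology, file.path(stage_dir, "terminology.csv"))

  # -- count ------------------------------------------------------------
  counts <- run_stage("count",
    count_events(gen$events, window = gen$scfg$study_window))
  message("stage count: ", nrow(gen$events), " rows in, ",
    nrow(counts), " cells out")

  # -- discover ---------------------------------------------------------
  disc <- run_stage("discover", {
    rules <- lapply(cfg$discovery$topics, function(t)
      topic_rule(t$topic, t$prefixes %||% character(),
        t$keywords %||% character(), t$codes %||% character()))
    dcfg <- discovery_config(cfg$discovery$threshold,
      cfg$discovery$threshold_year, rules,
      cfg$discovery$exclusions %||% character())
    list(dcfg = dcfg,
      table = discovery_table(counts, gen$terminology, dcfg))
  })
  message("stage discover: ", length(unique(counts$code)), " codes in, ",
    nrow(disc$table), " selected")
  if (!nrow(disc$table)) stop("pipeline stage 'discover' failed: ",
    "no code reached the frequency threshold", call. = FALSE)
  wcsv(disc$table, "selection.csv")

  # -- measure ----------------------------------------------------------
  meas <- run_stage("measure", {
    rates <- compute_rates(counts, gen$practices,
      subjects = disc$table$code)
    activity_measures(rates,
      disruption_month = cfg$measures$disruption_month,
      final_month = cfg$measures$final_month,
      key_months = cfg$measures$key_months,
      window_months = cfg$measures$window_months,
      quantile_type = cfg$measures$quantile_type)
  })
  message("stage measure: ", nrow(meas$deciles), " subject-months")
  wcsv(as.data.frame(meas$deciles), "deciles.csv")
  wcsv(meas$key_months, "key_months.csv")
  wcsv(as.data.frame(meas$classification), "recovery.csv")

  # -- report -----------------------------------------------------------
  run_stage("report", {
    if (isTRUE(cfg$report$charts)) {
      top <- utils::head(disc$table$code, cfg$report$chart_subjects)
      dir.create(file.path(stage_dir, "charts"), showWarnings = FALSE)
      render_decile_chart(meas$deciles,
        file.path(stage_dir, "charts", "deciles.svg"), subjects = top)
    }
    write_manifest(cfg, file.path(stage_dir, "manifest.json"))
  })
  message("stage report: outputs written")

  # promote staged outputs
  for (f in list.files(stage_dir, recursive = TRUE)) {
    dest <- file.path(out_dir, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(stage_dir, f), dest, overwrite = TRUE)
  }
  unlink(stage_dir, recursive = TRUE)
  out <- out_dir
  attr(out, "config") <- cfg
  invisible(out)
}

#' Parameter-recovery experiment for injected disruptions
#'
#' Generates one synthetic study in which each code carries a disruption
#' profile drawn from a grid of `(drop_fraction, terminal_level)`
#' combinations, runs the full measurement path (rates, deciles,
#' year-on-year change, classification), and returns the measured nadir
#' and terminal changes per code next to the injected truth. As in the
#' real pipeline, only codes clearing the frequency threshold are
#' measured, and codes whose baseline median is zero at a measurement
#' month (so no percentage change exists) are excluded from the result. Under the
#' injected parameters the expected nadir change is `-100 * drop_fraction`
#' and the expected terminal change `100 * (terminal_level - 1)`.
#'
#' @param combos data frame with columns `drop_fraction`,
#'   `terminal_level`; codes are assigned combinations cyclically.
#' @param config a [synthetic_config()]; its seed drives the replicate.
#' @param disruption_month month of the injected drop.
#' @param recovery_months recovery horizon; the default reaches the
#'   terminal level exactly at the final study month when disruption is
#'   in April of the final year.
#' @param window_months nadir search window for the classifier. The
#'   generator places the trough of `m(t)` at the disruption month by
#'   construction, so the default window is that single month; widen it
#'   only when the trough month is not known a priori (field data).
#' @return data frame: one row per code with injected and measured
#'   quantities (`drop_fraction`, `terminal_level`, `drop_pct`,
#'   `terminal_pct`, `category`, `expected_category`).
#' @export
recovery_experiment <- function(combos,
                                config = synthetic_config(),
                                disruption_month = "2020-04",
                                recovery_months = 8L,
                                window_months = 1L) {
  stopifnot(is.data.frame(combos),
    all(c("drop_fraction", "terminal_level") %in% names(combos)))
  practices <- generate_practices(config)
  code_rates <- generate_code_rates(config)
  codes <- names(code_rates)
  idx <- rep_len(seq_len(nrow(combos)), length(codes))
  profiles <- lapply(seq_along(codes), function(i)
    disruption_profile(disruption_month, combos$drop_fraction[idx[i]],
      "linear", recovery_months, combos$terminal_level[idx[i]]))
  names(profiles) <- codes

  events <- generate_events(config, practices, code_rates, profiles)
  counts <- count_events(events, config$study_window)
  # measure only codes that clear the frequency threshold, as the real
  # pipeline would; codes too rare for a defined baseline drop out here
  measured <- frequency_filter(counts, discovery_config(
    threshold_year = month_year(config$study_window[2L])))
  rates <- compute_rates(counts, practices, subjects = measured)
  med <- median_series(decile_series(rates))
  change <- pct_change_yoy(med)
  # a % change only exists for codes with a positive baseline median;
  # codes undefined throughout cannot be classified at all
  measurable <- unique(change$subject[change$defined])
  cls <- classify_recovery(change[change$subject %in% measurable, ,
    drop = FALSE], disruption_month, config$study_window[2L],
    window_months = window_months)

  keep <- codes %in% cls$subject
  m <- match(codes[keep], cls$subject)
  th <- recovery_thresholds()
  out <- data.frame(code = codes[keep],
    drop_fraction = combos$drop_fraction[idx][keep],
    terminal_level = combos$terminal_level[idx][keep],
    drop_pct = cls$drop_pct[m],
    terminal_pct = cls$terminal_pct[m],
    category = cls$category[m],
    stringsAsFactors = FALSE)
  out$expected_category <- mapply(classify_one,
    -100 * out$drop_fraction, 100 * (out$terminal_level - 1),
    MoreArgs = list(th = th))
  # drop codes whose nadir- or terminal-month change is undefined (zero
  # baseline median): no published-style measure exists for them
  out <- out[!is.na(out$drop_pct) & !is.na(out$terminal_pct), ,
    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname recovery_experiment
#' @param result a [recovery_experiment()] result.
#' @details `summarize_recovery_experiment()` reduces one replicate to a
#'   per-profile summary: several codes carry each injected profile, so
#'   the replicate's measured nadir and terminal changes for a profile
#'   are the medians across those codes and its category the modal
#'   code-level category.
#' @export
summarize_recovery_experiment <- function(result) {
  key <- interaction(result$drop_fraction, result$terminal_level,
    drop = TRUE)
  rows <- lapply(split(result, key), function(g) {
    data.frame(drop_fraction = g$drop_fraction[1L],
      terminal_level = g$terminal_level[1L],
      drop_pct = stats::median(g$drop_pct),
      terminal_pct = stats::median(g$terminal_pct),
      category = names(which.max(table(g$category))),
      expected_category = g$expected_category[1L],
      n_codes = nrow(g),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
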