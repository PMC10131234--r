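test_that("deciles follow the linear-interpolation quantile rule", {
  all7 <- practice_deciles(mk_rates(rep(7, 20)), "S", "2020-01")
  expect_equal(unlist(all7[sprintf("d%d", seq(10, 90, 10))]),
    rep(7, 9), ignore_attr = TRUE)

  d <- practice_deciles(mk_rates(1:10), "S", "2020-01")
  expect_equal(d$d50, 5.5)
  expect_equal(d$n_practices, 10)

  empty <- data.frame(practice = character(), subject = character(),
    month = character(), rate = numeric())
  expect_error(practice_deciles(empty, "S", "2020-01"),
    "no practice rates")
})

test_that("deciles match an independent sort-and-interpolate oracle", {
  set.seed(151)
  for (i in 1:50) {
    x <- stats::rgamma(sample(2:300, 1), shape = 1.2, rate = 0.3)
    d <- practice_deciles(mk_rates(x), "S", "2020-01")
    got <- unlist(d[sprintf("d%d", seq(10, 90, 10))], use.names = FALSE)
    oracle <- quantile7_oracle(x, seq(0.1, 0.9, 0.1))
    expect_equal(got, oracle, tolerance = 1e-13)
    expect_true(all(diff(got) >= -1e-12))    # non-decreasing in q
  }
})

test_that("decile_series agrees with per-cell practice_deciles", {
  set.seed(152)
  rates <- do.call(rbind, lapply(c("2020-01", "2020-02"), function(m)
    rbind(mk_rates(runif(30), "A", m), mk_rates(runif(30), "B", m))))
  ds <- decile_series(rates)
  expect_equal(nrow(ds), 4)
  for (i in seq_len(nrow(ds))) {
    cell <- practice_deciles(rates, ds$subject[i], ds$month[i])
    expect_equal(unlist(ds[i, sprintf("d%d", seq(10, 90, 10))]),
      unlist(cell[sprintf("d%d", seq(10, 90, 10))]), ignore_attr = TRUE)
  }
})

test_that("duplicating every practice leaves deciles nearly unchanged", {
  set.seed(153)
  x <- stats::rlnorm(200)
  d1 <- practice_deciles(mk_rates(x), "S", "2020-01")
  d2 <- practice_deciles(mk_rates(c(x, x)), "S", "2020-01")
  q1 <- unlist(d1[sprintf("d%d", seq(10, 90, 10))])
  q2 <- unlist(d2[sprintf("d%d", seq(10, 90, 10))])
  # interpolation offsets differ by O(1/n) between n and 2n
  expect_equal(q1, q2, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("year-on-year change handles equality, drops and zero baselines", {
  series <- data.frame(subject = "S",
    month = c("2019-01", "2019-02", "2019-03", "2020-01", "2020-02",
      "2020-03"),
    median = c(8, 10, 0, 8, 4, 5))
  ch <- pct_change_yoy(series)
  expect_equal(nrow(ch), 3)   # only months with a baseline
  expect_equal(ch$pct_change[ch$month == "2020-01"], 0)
  expect_equal(ch$pct_change[ch$month == "2020-02"], -60)
  expect_true(is.na(ch$pct_change[ch$month == "2020-03"]))
  expect_false(ch$defined[ch$month == "2020-03"])
})

test_that("year-on-year change is scale invariant", {
  set.seed(161)
  series <- data.frame(subject = "S",
    month = month_seq("2019-01", "2020-12"),
    median = stats::rlnorm(24, 2, 0.5))
  ch1 <- pct_change_yoy(series)
  series2 <- series; series2$median <- series2$median * 3.7
  ch2 <- pct_change_yoy(series2)
  expect_equal(ch1$pct_change, ch2$pct_change)
})

test_that("key-month cells render as 'median (signed change%)'", {
  series <- data.frame(subject = "S",
    month = c("2019-04", "2019-12", "2019-06", "2020-04", "2020-12",
      "2020-06"),
    median = c(164.2 / (1 - 0.869), 5.803571, 0, 19.8, 6.5, 3))
  # engineer exact medians/baselines
  series$median[1] <- 19.8 / (1 - 0.869)    # -86.9% at April
  series$median[2] <- 6.5 / 1.12            # +12.0% at December
  ch <- pct_change_yoy(series)
  km <- key_month_summary(series, ch, c("2020-04", "2020-12", "2020-06"))
  expect_equal(km[["2020-04"]], "19.8 (-86.9%)")
  expect_equal(km[["2020-12"]], "6.5 (+12.0%)")
  # zero baseline: median only, flagged
  expect_equal(km[["2020-06"]], "3.0")
  expect_true(km[["2020-06_flag"]])
  expect_false(km[["2020-04_flag"]])
})

test_that("reporting rounds half-up at one decimal place", {
  series <- data.frame(subject = "S",
    month = c("2019-02", "2020-02", "2019-03", "2020-03"),
    median = c(1, 0.04999, 2, 0.05))
  ch <- pct_change_yoy(series)
  km <- key_month_summary(series, ch, c("2020-02", "2020-03"))
  expect_match(km[["2020-02"]], "^0\\.0 ")
  expect_match(km[["2020-03"]], "^0\\.1 ")   # 0.05 rounds up, not to even
})

test_that("recovery classification reproduces the published patterns", {
  cases <- list(
    list(drop = -86.9, term = -0.6, want = "recovered"),    # HbA1c-style
    list(drop = -56.2, term = -41.6, want = "sustained_drop"),
    list(drop = 0, term = 0, want = "maintained"),
    list(drop = -60.6, term = 12.1, want = "increase"),     # contraception
    list(drop = -87.5, term = -16.6, want = "partial_recovery"))
  months <- month_seq("2019-01", "2020-12")
  for (cs in cases) {
    med <- rep(10, 24)
    med[months == "2020-04"] <- 10 * (1 + cs$drop / 100)
    med[months == "2020-12"] <- 10 * (1 + cs$term / 100)
    ch <- pct_change_yoy(data.frame(subject = "S", month = months,
      median = med))
    cls <- classify_recovery(ch, "2020-04", "2020-12", window_months = 1)
    expect_equal(cls$category, cs$want)
    expect_equal(cls$drop_pct, cs$drop)
    expect_equal(cls$terminal_pct, cs$term)
  }
})

test_that("classification is monotone in the terminal change", {
  months <- month_seq("2019-01", "2020-12")
  order_levels <- c("sustained_drop", "partial_recovery", "recovered",
    "increase")
  prev_rank <- 1
  for (term in seq(-60, 40, by = 5)) {
    med <- rep(10, 24)
    med[months == "2020-04"] <- 3
    med[months == "2020-12"] <- 10 * (1 + term / 100)
    ch <- pct_change_yoy(data.frame(subject = "S", month = months,
      median = med))
    cls <- classify_recovery(ch, "2020-04", "2020-12", window_months = 1)
    rank <- match(cls$category, order_levels)
    expect_gte(rank, prev_rank)
    prev_rank <- rank
  }
})

test_that("classification refuses a subject with no defined changes", {
  months <- month_seq("2019-01", "2020-12")
  ch <- pct_change_yoy(data.frame(subject = "S", month = months,
    median = rep(0, 24)))
  expect_error(classify_recovery(ch, "2020-04", "2020-12"),
    "no defined")
})

test_that("activity_measures bundles deciles, changes and classes", {
  cfg <- synthetic_config(n_practices = 40, n_codes = 6, seed = 171)
  pr <- generate_practices(cfg)
  ev <- generate_events(cfg, pr, profiles = list(
    C001 = disruption_profile("2020-04", 0.9, "linear", 8, 1)))
  rt <- compute_rates(ev, pr)
  am <- activity_measures(rt, disruption_month = "2020-04",
    key_months = c("2020-02", "2020-04", "2020-12"), window_months = 1)
  expect_s3_class(am, "activity_measures")
  expect_equal(sort(unique(am$deciles$subject)), sprintf("C%03d", 1:6))
  expect_lt(am$classification$drop_pct[am$classification$subject == "C001"],
    -60)
  expect_equal(nrow(am$key_months), 6)
  expect_output(print(am), "activity_measures")
})
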