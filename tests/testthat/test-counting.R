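window <- c("2019-01", "2020-12")

test_that("events are summed per practice-code-month", {
  raw <- data.frame(practice = "P1", code = "K1",
    month = rep("2020-03", 3))
  out <- count_events(raw, window)
  expect_equal(nrow(out), 1)
  expect_equal(out$count, 3)

  # pre-aggregated input with a count column
  raw2 <- data.frame(practice = c("P1", "P1"), code = "K1",
    month = "2020-03", count = c(2, 5))
  expect_equal(count_events(raw2, window)$count, 7)

  # date-level rows collapse to their calendar month
  raw3 <- data.frame(practice = "P1", code = "K1",
    date = c("2020-03-01", "2020-03-31"))
  expect_equal(count_events(raw3, window)$count, 2)
})

test_that("rows outside the study window are excluded and logged", {
  raw <- data.frame(practice = "P1", code = "K1",
    month = c("2020-12", "2021-01"))
  expect_message(out <- count_events(raw, window), "excluded 1")
  expect_equal(attr(out, "n_excluded"), 1)
  expect_equal(out$month, "2020-12")
})

test_that("malformed months and negative counts are rejected by row", {
  bad <- data.frame(practice = "P1", code = "K1",
    month = c("2020-01", "2020-13"))
  expect_error(count_events(bad, window), "malformed.*2")
  neg <- data.frame(practice = "P1", code = "K1", month = "2020-01",
    count = -1)
  expect_error(count_events(neg, window), "negative count")
})

test_that("counting matches a brute-force tally and ignores row order", {
  rows <- random_event_rows(1000, seed = 61,
    months = month_seq("2018-10", "2021-03"))
  got <- suppressMessages(count_events(rows, window))
  oracle <- tally_oracle(rows, window)
  expect_equal(got[c("practice", "code", "month", "count")], oracle,
    ignore_attr = TRUE)

  perm <- rows[sample(nrow(rows)), ]
  got2 <- suppressMessages(count_events(perm, window))
  expect_identical(got, got2)
})

test_that("group counts sum member codes as a set", {
  counts <- data.frame(
    practice = "P1", code = c("A", "B"), month = "2020-01",
    count = c(2L, 3L), stringsAsFactors = FALSE)
  h <- code_hierarchy(data.frame(code = c("A", "B"),
    description = c("a", "b"), parent = c(NA, NA)))
  g <- build_group(h, explicit_group("AB", c("A", "B", "B")))  # B repeated
  out <- aggregate_group_counts(counts, g)
  expect_equal(out$count, 5)
  expect_equal(out$code, "AB")

  g1 <- build_group(h, explicit_group("justA", "A"))
  one <- aggregate_group_counts(counts, g1)
  expect_equal(one$count, counts$count[counts$code == "A"])
})

test_that("group aggregation matches brute-force summation", {
  rows <- random_event_rows(800, seed = 71)
  counts <- count_events(rows, window)
  codes <- sort(unique(counts$code))
  h <- code_hierarchy(data.frame(code = codes, description = codes,
    parent = NA_character_))
  set.seed(72)
  members <- sample(codes, 4)
  g <- build_group(h, explicit_group("G", members))
  got <- aggregate_group_counts(counts, g)
  for (i in seq_len(nrow(got))) {
    expected <- 0
    for (j in seq_len(nrow(counts))) {
      if (counts$practice[j] == got$practice[i] &&
          counts$month[j] == got$month[i] &&
          counts$code[j] %in% members) {
        expected <- expected + counts$count[j]
      }
    }
    expect_equal(got$count[i], expected)
  }
})

test_that("a disjoint partition of codes conserves total counts", {
  rows <- random_event_rows(2000, seed = 81)
  counts <- count_events(rows, window)
  codes <- sort(unique(counts$code))
  h <- code_hierarchy(data.frame(code = codes, description = codes,
    parent = NA_character_))
  set.seed(82)
  split_at <- sample(seq_along(codes)[-1], 2)
  parts <- split(codes, cut(seq_along(codes),
    c(0, sort(split_at) - 0.5, length(codes) + 1), labels = FALSE))
  groups <- lapply(seq_along(parts), function(i)
    build_group(h, explicit_group(paste0("G", i), parts[[i]])))
  agg <- aggregate_group_counts(counts, groups)
  per_pm_groups <- tapply(agg$count, paste(agg$practice, agg$month), sum)
  per_pm_total <- tapply(counts$count, paste(counts$practice, counts$month),
    sum)
  expect_equal(per_pm_groups[order(names(per_pm_groups))],
    per_pm_total[order(names(per_pm_total))])
})

test_that("rates are 1000 * count / list_size with explicit zero-fill", {
  counts <- data.frame(practice = "P1", code = "K1", month = "2020-01",
    count = 5L, stringsAsFactors = FALSE)
  reg <- data.frame(practice = c("P1", "P2"), list_size = c(2000L, 1000L))
  rt <- compute_rates(counts, reg, subjects = "K1", months = "2020-01")
  expect_equal(rt$rate[rt$practice == "P1"], 2.5)
  expect_equal(rt$rate[rt$practice == "P2"], 0)   # zero-activity practice
  expect_equal(nrow(rt), 2)
})

test_that("rate computation matches the elementwise oracle", {
  rows <- random_event_rows(600, seed = 91)
  counts <- count_events(rows, window)
  set.seed(92)
  reg <- data.frame(practice = sort(unique(rows$practice)),
    list_size = sample(1000:20000, length(unique(rows$practice))))
  rt <- compute_rates(counts, reg)
  for (i in sample(nrow(rt), 50)) {
    n <- counts$count[counts$practice == rt$practice[i] &
      counts$code == rt$subject[i] & counts$month == rt$month[i]]
    n <- if (length(n)) n else 0
    L <- reg$list_size[reg$practice == rt$practice[i]]
    expect_equal(rt$rate[i], 1000 * n / L)
  }
})

test_that("rates are homogeneous in counts and inverse in list size", {
  rows <- random_event_rows(300, seed = 101)
  counts <- count_events(rows, window)
  reg <- data.frame(practice = sort(unique(rows$practice)),
    list_size = 5000L)
  rt <- compute_rates(counts, reg)

  doubled <- counts; doubled$count <- doubled$count * 2L
  attr(doubled, "window") <- attr(counts, "window")
  expect_equal(compute_rates(doubled, reg)$rate, rt$rate * 2)

  reg2 <- reg; reg2$list_size <- reg2$list_size * 2L
  expect_equal(compute_rates(counts, reg2)$rate, rt$rate / 2)
})

test_that("registry problems are reported by name", {
  counts <- data.frame(practice = "P9", code = "K1", month = "2020-01",
    count = 1L)
  reg <- data.frame(practice = "P1", list_size = 1000L)
  expect_error(compute_rates(counts, reg), "P9")
  reg0 <- data.frame(practice = "P9", list_size = 0L)
  expect_error(compute_rates(counts, reg0), "list_size")
})

test_that("monthly denominators are supported as an explicit mode", {
  counts <- data.frame(practice = "P1", code = "K1",
    month = c("2020-01", "2020-02"), count = c(4L, 4L))
  reg <- data.frame(practice = "P1", month = c("2020-01", "2020-02"),
    list_size = c(1000L, 2000L))
  rt <- compute_rates(counts, reg, subjects = "K1",
    months = c("2020-01", "2020-02"), denominator = "monthly")
  expect_equal(rt$rate[rt$month == "2020-01"], 4)
  expect_equal(rt$rate[rt$month == "2020-02"], 2)
})
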