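# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, brute-force scans) and share no code with the implementation.

tiny_hierarchy <- function() {
  code_hierarchy(data.frame(
    code = c("A....", "AB...", "ABC..", "61abc", "61xyz", "24abc"),
    description = c("Top concept", "Mid concept", "Leaf concept",
      "Oral contraception discussed", "Contraceptive implant fitted",
      "Cervical smear taken"),
    parent = c(NA, "A....", "AB...", NA, "61abc", NA),
    stringsAsFactors = FALSE))
}

# random forest: each node's parent is an earlier node or none
random_tree_df <- function(n, seed, p_root = 0.15) {
  set.seed(seed)
  pool <- c(letters, LETTERS, 0:9)
  repeat {
    code <- unique(replicate(n * 2, paste(sample(pool, 5, TRUE),
      collapse = "")))[seq_len(n)]
    if (length(code) == n && !anyNA(code)) break
  }
  parent <- rep(NA_character_, n)
  for (i in seq_len(n)[-1]) {
    if (stats::runif(1) > p_root) parent[i] <- code[sample.int(i - 1L, 1L)]
  }
  data.frame(code = code,
    description = paste("concept", seq_len(n)),
    parent = parent, stringsAsFactors = FALSE)
}

# breadth-first descendant oracle working directly on the parent table
bfs_descendants_oracle <- function(df, root) {
  out <- character()
  frontier <- root
  while (length(frontier)) {
    kids <- df$code[!is.na(df$parent) & df$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  sort(unique(out))
}

# type-7 quantile oracle: sort, then linearly interpolate order statistics
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_event_rows <- function(n, seed, n_practices = 12, n_codes = 8,
                              months = month_seq("2019-01", "2020-12"),
                              max_count = 5L) {
  set.seed(seed)
  data.frame(
    practice = sample(sprintf("P%02d", seq_len(n_practices)), n, TRUE),
    code = sample(sprintf("K%02d", seq_len(n_codes)), n, TRUE),
    month = sample(months, n, TRUE),
    count = sample.int(max_count, n, TRUE),
    stringsAsFactors = FALSE)
}

mk_rates <- function(x, subject = "S", month = "2020-01") {
  data.frame(practice = sprintf("P%03d", seq_along(x)), subject = subject,
    month = month, rate = x, stringsAsFactors = FALSE)
}

# brute-force tally oracle using an environment as a hash map
tally_oracle <- function(rows, window) {
  env <- new.env(parent = emptyenv())
  win <- month_seq(window[1], window[2])
  for (i in seq_len(nrow(rows))) {
    if (!rows$month[i] %in% win) next
    k <- paste(rows$practice[i], rows$code[i], rows$month[i])
    prev <- if (exists(k, envir = env)) get(k, envir = env) else 0
    assign(k, prev + rows$count[i], envir = env)
  }
  ks <- sort(ls(env))
  parts <- do.call(rbind, strsplit(ks, " ", fixed = TRUE))
  data.frame(practice = parts[, 1], code = parts[, 2], month = parts[, 3],
    count = as.integer(vapply(ks, get, numeric(1), envir = env)),
    stringsAsFactors = FALSE)
}
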