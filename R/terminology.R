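#' Construct a clinical code hierarchy
#'
#' A `code_hierarchy` holds a CTV3-like coding dictionary: a forest of
#' codes where broad "parent" concepts refine into more specific "child"
#' codes. CTV3-style codes are short case-sensitive strings (conventionally
#' 5 characters); long numeric SNOMED-CT-style identifiers are also
#' accepted and flagged as such.
#'
#' @param codes a data frame with columns `code`, `description` and
#'   `parent` (`NA` or `""` for a top-level concept), and optionally
#'   `terminology` (`"CTV3"` or `"SNOMED"`; inferred from the code string
#'   when absent: all-digit identifiers longer than 5 characters are
#'   SNOMED-style).
#' @return an object of class `code_hierarchy` with elements
#'   `codes` (validated data frame, one row per code) and
#'   `children` (named list mapping a parent code to its child codes).
#' @details Validation enforces: non-empty unique code strings, every
#'   `parent` present in `code`, and an acyclic parent relation. Row order
#'   of the input never affects the result: codes are stored sorted.
#' @seealso [load_terminology()], [descendants()], [build_group()]
#' @export
code_hierarchy <- function(codes) {
  stopifnot(is.data.frame(codes))
  need <- c("code", "description", "parent")
  miss <- setdiff(need, names(codes))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  code <- as.character(codes$code)
  description <- as.character(codes$description)
  parent <- as.character(codes$parent)
  parent[!is.na(parent) & parent == ""] <- NA_character_

  if (any(is.na(code) | code == "")) stop("empty code identifier in row(s) ",
    paste(which(is.na(code) | code == ""), collapse = ", "))
  dup <- unique(code[duplicated(code)])
  if (length(dup)) stop("duplicate code identifier(s): ",
    paste(dup, collapse = ", "))
  orphan <- setdiff(parent[!is.na(parent)], code)
  if (length(orphan)) stop("parent code(s) not found in hierarchy: ",
    paste(sort(orphan), collapse = ", "))

  # cycle check: peel codes whose parent is already resolved
  cyc <- detect_cycle(code, parent)
  if (length(cyc)) stop("cycle detected among codes: ",
    paste(cyc, collapse = " -> "))

  if ("terminology" %in% names(codes)) {
    terminology <- as.character(codes$terminology)
    bad <- setdiff(unique(terminology), c("CTV3", "SNOMED"))
    if (length(bad)) stop("unknown terminology value(s): ",
      paste(bad, collapse = ", "))
  } else {
    terminology <- ifelse(nchar(code) > 5L & grepl("^[0-9]+$", code),
      "SNOMED", "CTV3")
  }

  ord <- order(code, method = "radix")
  df <- data.frame(code = code, description = description, parent = parent,
    terminology = terminology, stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(df) <- NULL
  has_parent <- !is.na(df$parent)
  children <- split(df$code[has_parent], df$parent[has_parent])
  structure(list(codes = df, children = children), class = "code_hierarchy")
}

# Returns a character vector tracing one cycle (empty if acyclic).
detect_cycle <- function(code, parent) {
  resolved <- is.na(parent)
  names(resolved) <- code
  repeat {
    newly <- !resolved & resolved[match(parent, code)]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    resolved[newly] <- TRUE
  }
  if (all(resolved)) return(character())
  start <- code[!resolved][1L]
  path <- start
  cur <- parent[match(start, code)]
  while (!cur %in% path) {
    path <- c(path, cur)
    cur <- parent[match(cur, code)]
  }
  c(path[which(path == cur):length(path)], cur)
}

#' @export
print.code_hierarchy <- function(x, ...) {
  n_top <- sum(is.na(x$codes$parent))
  cat("<code_hierarchy> ", nrow(x$codes), " codes (",
    n_top, " top-level, ",
    sum(x$codes$terminology == "SNOMED"), " SNOMED-style)\n", sep = "")
  invisible(x)
}

#' Read and write a terminology file
#'
#' The on-disk form is delimited text, one row per code. Column names are
#' remappable through `dialect` so files from different sources can be read
#' without editing; defaults are `code,description,parent` with a comma
#' delimiter. An empty `parent` field marks a top-level concept.
#'
#' @param path file path.
#' @param dialect named list mapping the canonical names `code`,
#'   `description`, `parent` (and optionally `terminology`) to the column
#'   names used in the file.
#' @param sep field delimiter.
#' @return `load_terminology()`: a validated [code_hierarchy()].
#' @export
load_terminology <- function(path,
                             dialect = list(code = "code",
                                            description = "description",
                                            parent = "parent"),
                             sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
    colClasses = "character", stringsAsFactors = FALSE,
    quote = "\"", comment.char = "", na.strings = character())
  for (canon in c("code", "description", "parent")) {
    col <- dialect[[canon]] %||% canon
    if (!col %in% names(raw)) stop("terminology file lacks column '", col,
      "' (mapped to '", canon, "')")
    names(raw)[names(raw) == col] <- canon
  }
  if (!is.null(dialect$terminology) && dialect$terminology %in% names(raw)) {
    names(raw)[names(raw) == dialect$terminology] <- "terminology"
  }
  code_hierarchy(raw)
}

#' @rdname load_terminology
#' @param h a [code_hierarchy()].
#' @export
write_terminology <- function(h, path, sep = ",") {
  stopifnot(inherits(h, "code_hierarchy"))
  out <- h$codes
  out$parent[is.na(out$parent)] <- ""
  utils::write.table(out, path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Query a code hierarchy
#'
#' `descendants()` returns every code strictly below a given code in the
#' parent-child tree (the code itself is excluded). `codes_with_prefix()`
#' returns codes whose identifier starts with a literal, case-sensitive
#' prefix -- the convention used when published figures define a group as
#' "codes beginning with" certain characters. `keyword_search()` matches
#' search terms case-insensitively as substrings of code descriptions,
#' returning the union over terms.
#'
#' @param h a [code_hierarchy()].
#' @param code_id a single code identifier present in `h`.
#' @return a character vector of code identifiers (sorted; possibly empty).
#' @export
descendants <- function(h, code_id) {
  stopifnot(inherits(h, "code_hierarchy"), length(code_id) == 1L)
  if (!code_id %in% h$codes$code) stop("unknown code: ", code_id)
  out <- character()
  frontier <- h$children[[code_id]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(h$children[frontier], use.names = FALSE)
  }
  sort(out)
}

#' @rdname descendants
#' @param prefix non-empty literal prefix (matching is case-sensitive:
#'   CTV3 distinguishes e.g. `XaF8d` from `Xaf8d`).
#' @export
codes_with_prefix <- function(h, prefix) {
  stopifnot(inherits(h, "code_hierarchy"),
    length(prefix) == 1L, nchar(prefix) > 0L)
  sort(h$codes$code[startsWith(h$codes$code, prefix)])
}

#' @rdname descendants
#' @param terms character vector of search terms (at least one).
#' @export
keyword_search <- function(h, terms) {
  stopifnot(inherits(h, "code_hierarchy"), length(terms) >= 1L)
  desc <- tolower(h$codes$description)
  hit <- rep(FALSE, length(desc))
  for (term in tolower(as.character(terms))) {
    hit <- hit | grepl(term, desc, fixed = TRUE)
  }
  sort(h$codes$code[hit])
}

#' Define and resolve a code group
#'
#' A code group names a set of codes analysed together (e.g. all
#' contraception-related activity). Three definition styles are supported,
#' mirroring how groups are specified in practice: a literal code-string
#' `prefix` ("codes beginning 61"), an `explicit` list, or a `subtree`
#' rooted at one concept (the root plus all its descendants). Membership is
#' fully resolved against the hierarchy at construction.
#'
#' @param name group name.
#' @param prefix literal code-string prefix.
#' @param codes explicit character vector of member codes.
#' @param root code identifier of a subtree root.
#' @param topic optional clinical topic label carried on the group.
#' @return a `group_spec` (unresolved definition) or, from `build_group()`,
#'   a `code_group` with resolved, non-empty `members`.
#' @examples
#' h <- code_hierarchy(data.frame(
#'   code = c("61...", "611..", "24..."),
#'   description = c("Contraception", "Oral contraception", "CVS examination"),
#'   parent = c(NA, "61...", NA)))
#' build_group(h, prefix_group("Contraception", "61"))
#' @export
prefix_group <- function(name, prefix, topic = NULL) {
  structure(list(name = name, type = "prefix", value = prefix, topic = topic),
    class = "group_spec")
}

#' @rdname prefix_group
#' @export
explicit_group <- function(name, codes, topic = NULL) {
  structure(list(name = name, type = "explicit",
    value = as.character(codes), topic = topic), class = "group_spec")
}

#' @rdname prefix_group
#' @export
subtree_group <- function(name, root, topic = NULL) {
  structure(list(name = name, type = "subtree", value = root, topic = topic),
    class = "group_spec")
}

#' @rdname prefix_group
#' @param h a [code_hierarchy()].
#' @param spec a `group_spec` from [prefix_group()], [explicit_group()] or
#'   [subtree_group()].
#' @export
build_group <- function(h, spec) {
  stopifnot(inherits(h, "code_hierarchy"), inherits(spec, "group_spec"))
  members <- switch(spec$type,
    prefix = codes_with_prefix(h, spec$value),
    explicit = {
      missing <- setdiff(spec$value, h$codes$code)
      if (length(missing)) stop("group '", spec$name,
        "': code(s) not in hierarchy: ", paste(missing, collapse = ", "))
      sort(unique(spec$value))
    },
    subtree = {
      if (!spec$value %in% h$codes$code) stop("group '", spec$name,
        "': subtree root not in hierarchy: ", spec$value)
      sort(c(spec$value, descendants(h, spec$value)))
    },
    stop("unknown group definition type: ", spec$type))
  if (!length(members)) stop("group '", spec$name, "' resolved to no codes")
  structure(list(name = spec$name, members = members,
    definition = spec[c("type", "value")], topic = spec$topic),
    class = "code_group")
}

#' @export
print.code_group <- function(x, ...) {
  cat("<code_group> '", x$name, "' (", x$definition$type, "): ",
    length(x$members), " codes\n", sep = "")
  invisible(x)
}
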