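# Structured cohort-selection grammar.
#
# A statement has three elements: attribute, comparison operator, value.
# Operators: "is", "is not", "is greater than"/"greater than",
# "is less than"/"less than", "from X to Y", "is in {..}", "is not in {..}".
# Statements (optionally parenthesized) are joined with "and"/"or" and a
# chain is evaluated strictly by position, left to right — "A and B or C"
# means "(A and B) or C"; nested parentheses override that order.

.op_labels <- c(IS = "is", IS_NOT = "is not", GT = "is greater than",
                LT = "is less than", RANGE = "is from", IN = "is in",
                NOT_IN = "is not in")

new_comparison <- function(attribute, operator, value, text = NULL) {
  structure(list(attribute = attribute, operator = operator, value = value,
                 text = text),
            class = c("filter_comparison", "filter_expr"))
}

new_connective <- function(op, left, right, text = NULL) {
  structure(list(op = op, left = left, right = right, text = text),
            class = c("filter_connective", "filter_expr"))
}

#' Parse one comparison statement
#'
#' Parses a single statement such as `"Age is greater than 30"` or
#' `"Disease stage is in {Stage I, Stage II}"` into a comparison leaf.
#' Operator keywords match case-insensitively; values are trimmed of
#' surrounding whitespace but internal spaces are preserved. Set literals
#' are braces around comma-separated values and must be non-empty.
#'
#' @param text statement text with no logical connectives.
#' @return a `filter_comparison` with fields `attribute`, `operator` (one of
#'   `IS`, `IS_NOT`, `GT`, `LT`, `RANGE`, `IN`, `NOT_IN`) and `value`
#'   (scalar, length-2 range, or character set).
#' @export
parse_statement <- function(text) {
  raw <- text
  s <- trimws(text)
  if (!nzchar(s)) stop("empty statement")
  grab <- function(pattern) {
    m <- regexec(pattern, s, ignore.case = TRUE, perl = TRUE)
    r <- regmatches(s, m)[[1]]
    if (length(r) == 0) NULL else trimws(r[-1])
  }
  parse_set <- function(body, span) {
    items <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
    items <- items[nzchar(items)]
    if (length(items) == 0) {
      stop("empty set literal in statement: '", span, "'")
    }
    items
  }
  if (!is.null(p <- grab("^(.*?\\S)\\s+is\\s+not\\s+in\\s*\\{(.*)\\}$"))) {
    return(new_comparison(p[1], "NOT_IN", parse_set(p[2], raw), raw))
  }
  if (!is.null(p <- grab("^(.*?\\S)\\s+is\\s+in\\s*\\{(.*)\\}$"))) {
    return(new_comparison(p[1], "IN", parse_set(p[2], raw), raw))
  }
  if (!is.null(p <- grab("^(.*?\\S)\\s+(?:is\\s+)?greater\\s+than\\s+(\\S.*)$"))) {
    return(new_comparison(p[1], "GT", p[2], raw))
  }
  if (!is.null(p <- grab("^(.*?\\S)\\s+(?:is\\s+)?less\\s+than\\s+(\\S.*)$"))) {
    return(new_comparison(p[1], "LT", p[2], raw))
  }
  if (!is.null(p <- grab("^(.*?\\S)\\s+(?:is\\s+)?from\\s+(\\S.*?)\\s+to\\s+(\\S.*)$"))) {
    lo <- suppressWarnings(as.numeric(p[2]))
    hi <- suppressWarnings(as.numeric(p[3]))
    if (!is.na(lo) && !is.na(hi) && lo > hi) {
      stop("range start exceeds end in statement: '", raw, "'")
    }
    return(new_comparison(p[1], "RANGE", c(p[2], p[3]), raw))
  }
  if (!is.null(p <- grab("^(.*?\\S)\\s+is\\s+not\\s+(\\S.*)$"))) {
    return(new_comparison(p[1], "IS_NOT", p[2], raw))
  }
  if (!is.null(p <- grab("^(.*?\\S)\\s+is\\s+(\\S.*)$"))) {
    return(new_comparison(p[1], "IS", p[2], raw))
  }
  stop("no recognized comparison operator in statement: '", raw, "'")
}

# Split `s` at top-level "and"/"or" word tokens (outside parens and braces).
# Returns list(parts = character, ops = character).
.split_top_level <- function(s) {
  n <- nchar(s)
  depth_paren <- 0L
  depth_brace <- 0L
  parts <- character()
  ops <- character()
  start <- 1L
  i <- 1L
  is_boundary <- function(ch) is.na(ch) || grepl("[^A-Za-z0-9_]", ch)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth_paren <- depth_paren + 1L
    else if (ch == ")") {
      depth_paren <- depth_paren - 1L
      if (depth_paren < 0) stop("unbalanced parentheses at position ", i)
    } else if (ch == "{") depth_brace <- depth_brace + 1L
    else if (ch == "}") depth_brace <- depth_brace - 1L
    else if (depth_paren == 0L && depth_brace == 0L &&
             (ch == "a" || ch == "A" || ch == "o" || ch == "O")) {
      for (kw in c("and", "or")) {
        klen <- nchar(kw)
        if (i + klen - 1L <= n &&
            tolower(substr(s, i, i + klen - 1L)) == kw) {
          before <- if (i == 1L) NA_character_ else chars[i - 1L]
          after <- if (i + klen > n) NA_character_ else chars[i + klen]
          if (is_boundary(before) && is_boundary(after)) {
            parts <- c(parts, substr(s, start, i - 1L))
            ops <- c(ops, kw)
            i <- i + klen
            start <- i
            break
          }
        }
      }
    }
    i <- i + 1L
  }
  if (depth_paren != 0L) stop("unbalanced parentheses in expression")
  parts <- c(parts, substr(s, start, n))
  list(parts = trimws(parts), ops = ops)
}

# TRUE when s is entirely wrapped by one matching pair of parentheses.
.fully_wrapped <- function(s) {
  if (!startsWith(s, "(") || !endsWith(s, ")")) return(FALSE)
  depth <- 0L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth == 0L && i < length(chars)) return(FALSE)
    }
  }
  depth == 0L
}

#' Parse a cohort-selection expression
#'
#' Parses statements joined by `and`/`or` into a binary expression tree.
#' There is deliberately no operator precedence: an unparenthesized chain
#' associates strictly left-to-right, so `"A and B or C"` parses as
#' `"(A and B) or C"`. Parenthesized groups parse as subtrees and override
#' that order. A single statement, with or without enclosing parentheses,
#' is a valid expression.
#'
#' @param text expression text.
#' @return a `filter_expr`: either a `filter_comparison` leaf or a
#'   `filter_connective` node with fields `op` (`"and"`/`"or"`), `left`,
#'   `right`.
#' @export
parse_expression <- function(text) {
  s <- trimws(text)
  if (!nzchar(s)) stop("empty expression")
  pieces <- .split_top_level(s)
  if (any(!nzchar(pieces$parts))) {
    stop("dangling logical connective in expression: '", text, "'")
  }
  parse_unit <- function(u) {
    if (.fully_wrapped(u)) {
      inner <- trimws(substr(u, 2L, nchar(u) - 1L))
      if (!nzchar(inner)) stop("empty parenthesized group in: '", text, "'")
      parse_expression(inner)
    } else {
      parse_statement(u)
    }
  }
  acc <- parse_unit(pieces$parts[1])
  for (j in seq_along(pieces$ops)) {
    acc <- new_connective(pieces$ops[j], acc, parse_unit(pieces$parts[j + 1L]))
  }
  acc$text <- s
  acc
}

as_filter_expr <- function(x) {
  if (inherits(x, "filter_expr")) x else parse_expression(x)
}

#' Canonical text of an expression
#'
#' Renders a fully parenthesized form that re-parses to an identical tree
#' (`parse_expression(canonical_text(e))` equals `e` structurally). Used in
#' reports and run records so that the executed logic is unambiguous.
#'
#' @param expr a `filter_expr` (or text, parsed first).
#' @return character scalar.
#' @export
canonical_text <- function(expr) {
  expr <- as_filter_expr(expr)
  if (inherits(expr, "filter_comparison")) {
    val <- switch(expr$operator,
      RANGE = paste(expr$value[1], "to", expr$value[2]),
      IN = paste0("{", paste(expr$value, collapse = ", "), "}"),
      NOT_IN = paste0("{", paste(expr$value, collapse = ", "), "}"),
      expr$value
    )
    paste0("(", expr$attribute, " ", .op_labels[[expr$operator]], " ", val, ")")
  } else {
    paste0("(", canonical_text(expr$left), " ", expr$op, " ",
           canonical_text(expr$right), ")")
  }
}

#' @export
print.filter_expr <- function(x, ...) {
  cat(canonical_text(x), "\n")
  invisible(x)
}

# Structural equality ignoring source-text spans.
expr_equal <- function(a, b) {
  a <- as_filter_expr(a); b <- as_filter_expr(b)
  if (inherits(a, "filter_comparison") != inherits(b, "filter_comparison")) {
    return(FALSE)
  }
  if (inherits(a, "filter_comparison")) {
    identical(a$attribute, b$attribute) && identical(a$operator, b$operator) &&
      identical(a$value, b$value)
  } else {
    identical(a$op, b$op) && expr_equal(a$left, b$left) &&
      expr_equal(a$right, b$right)
  }
}

.eval_comparison <- function(cmp, bundle, case_fold, set_delimiter) {
  attr_names <- bundle$attributes$name
  if (!cmp$attribute %in% attr_names) {
    stop("unknown attribute in expression: '", cmp$attribute, "'")
  }
  kind <- attribute_kind(bundle, cmp$attribute)
  col <- bundle$table[[cmp$attribute]]
  numeric_kind <- kind %in% c("numeric", "event_time", "event_indicator")
  norm <- function(x) {
    x <- trimws(x)
    if (case_fold) tolower(x) else x
  }
  want_num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
      stop("non-numeric ", what, " '", paste(v, collapse = ", "),
           "' for numeric attribute '", cmp$attribute, "'")
    }
    out
  }
  res <- switch(cmp$operator,
    GT = , LT = {
      if (!numeric_kind) {
        stop("operator '", .op_labels[[cmp$operator]],
             "' requires a numeric attribute; '", cmp$attribute,
             "' is ", kind)
      }
      v <- want_num(cmp$value, "value")
      if (cmp$operator == "GT") col > v else col < v
    },
    RANGE = {
      if (!numeric_kind) {
        stop("range comparison requires a numeric attribute; '",
             cmp$attribute, "' is ", kind)
      }
      v <- want_num(cmp$value, "range endpoints")
      col >= v[1] & col <= v[2]
    },
    IS = , IS_NOT = {
      hit <- if (numeric_kind) {
        col == want_num(cmp$value, "value")
      } else {
        norm(col) == norm(cmp$value)
      }
      if (cmp$operator == "IS") hit else !hit
    },
    IN = , NOT_IN = {
      hit <- if (numeric_kind) {
        col %in% want_num(cmp$value, "set values")
        # %in% on numeric drops NA to FALSE; restore NA for missing cells
      } else {
        set <- norm(cmp$value)
        vapply(col, function(cell) {
          if (is.na(cell)) return(NA)
          any(norm(strsplit(cell, set_delimiter, fixed = TRUE)[[1]]) %in% set)
        }, logical(1), USE.NAMES = FALSE)
      }
      if (numeric_kind) hit[is.na(col)] <- NA
      if (cmp$operator == "IN") hit else !hit
    },
    stop("unknown operator: ", cmp$operator)
  )
  # missing cells fail every comparison, including negated ones
  res[is.na(res)] <- FALSE
  res
}

#' Evaluate an expression against a bundle
#'
#' Produces a per-sample logical mask. A comparison on a missing cell
#' excludes that sample (yields `FALSE`), including for the negated
#' operators `is not` and `is not in` — cohort definitions are conservative
#' with respect to missingness, which affects counts and is therefore
#' stated here prominently. `greater than` / `less than` / ranges require a
#' numeric attribute; `is` compares numerically on numeric attributes and
#' as trimmed case-sensitive strings on categorical ones.
#'
#' Multi-valued categorical cells (e.g. a treatment column listing several
#' agents separated by `set_delimiter`) match an `is in` set when any
#' listed component is in the set.
#'
#' @param expr a `filter_expr` or expression text.
#' @param bundle a `dataset_bundle`.
#' @param case_fold fold case before string comparison (default `FALSE`:
#'   clinical codes are compared exactly).
#' @param set_delimiter delimiter splitting multi-valued categorical cells
#'   for set-membership tests (default `"|"`).
#' @return logical vector of length `bundle$n_samples`.
#' @export
evaluate_filter <- function(expr, bundle, case_fold = FALSE, set_delimiter = "|") {
  expr <- as_filter_expr(expr)
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (inherits(expr, "filter_comparison")) {
    .eval_comparison(expr, bundle, case_fold, set_delimiter)
  } else {
    l <- evaluate_filter(expr$left, bundle, case_fold, set_delimiter)
    r <- evaluate_filter(expr$right, bundle, case_fold, set_delimiter)
    if (expr$op == "and") l & r else l | r
  }
}
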