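# In-code fixtures shared across the suite.

# Minimal well-formed bundle: stage, a binary mutation flag, age, and a
# survival endpoint.
toy_bundle <- function() {
  idx <- attribute_index(
    name = c("TUMOR_STAGE", "TP53_Mutation_status", "AGE",
             "OS_months", "OS_event"),
    kind = c("categorical", "categorical", "numeric",
             "event_time", "event_indicator"),
    endpoint_group = c(NA, NA, NA, "OS", "OS"))
  tab <- data.frame(
    SAMPLE_ID = paste0("S", 1:10),
    TUMOR_STAGE = c("T1", "T2", "T3", "T4", "T1", "T3", "T3", "T2", "T4", "T1"),
    TP53_Mutation_status = c("0", "1", "1", "1", "0", "1", "0", "0", "1", "0"),
    AGE = c(55, 61, NA, 70, 48, 66, 59, 72, 63, 50),
    OS_months = c(12, 30, 8, 5, 40, 22, 18, 33, 7, 25),
    OS_event = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0),
    check.names = FALSE)
  dataset_bundle("toy fixture", idx, tab)
}

# Random bundle for property tests: k_cat categorical + k_num numeric
# attributes with injected missingness, optional survival endpoint.
random_bundle <- function(n = 40, k_cat = 3, k_num = 2, seed = 1,
                          survival = FALSE, miss_rate = 0.1) {
  withr::local_seed(seed)
  cols <- list(ID = sprintf("R%03d", 1:n))
  kinds <- character(); eps <- character()
  for (i in seq_len(k_cat)) {
    nm <- paste0("CAT", i)
    v <- sample(LETTERS[1:sample(2:4, 1)], n, TRUE)
    v[runif(n) < miss_rate] <- NA
    cols[[nm]] <- v; kinds[nm] <- "categorical"; eps[nm] <- NA
  }
  for (i in seq_len(k_num)) {
    nm <- paste0("NUM", i)
    v <- round(rnorm(n, 50, 12), 3)
    v[runif(n) < miss_rate] <- NA
    cols[[nm]] <- v; kinds[nm] <- "numeric"; eps[nm] <- NA
  }
  if (survival) {
    cols$T_months <- round(rexp(n, 0.05), 3)
    cols$T_event <- rbinom(n, 1, 0.7)
    kinds["T_months"] <- "event_time"; eps["T_months"] <- "T"
    kinds["T_event"] <- "event_indicator"; eps["T_event"] <- "T"
  }
  idx <- attribute_index(names(kinds), unname(kinds),
                         endpoint_group = unname(eps))
  dataset_bundle("random fixture", idx,
                 as.data.frame(cols, check.names = FALSE))
}

# Random expression tree over a bundle's attributes, for round-trip and
# brute-force-evaluation properties.
random_expr <- function(bundle, depth = 2) {
  attrs <- bundle$attributes
  usable <- attrs[!attrs$kind %in% c("event_time", "event_indicator"), ]
  leaf <- function() {
    row <- usable[sample(nrow(usable), 1), ]
    col <- bundle$table[[row$name]]
    obs <- col[!is.na(col)]
    if (row$kind == "numeric") {
      v <- round(stats::quantile(obs, runif(1)), 2)
      op <- sample(c("is greater than", "is less than", "is"), 1)
      parse_statement(paste(row$name, op, v))
    } else {
      lv <- unique(obs)
      if (length(lv) > 1 && runif(1) < 0.4) {
        k <- sample(length(lv), sample(length(lv), 1))
        parse_statement(paste0(row$name, " is in {", paste(lv[k], collapse = ", "), "}"))
      } else {
        op <- sample(c("is", "is not"), 1)
        parse_statement(paste(row$name, op, sample(lv, 1)))
      }
    }
  }
  build <- function(d) {
    if (d == 0 || runif(1) < 0.3) return(leaf())
    parse_expression(paste0("(", canonical_text(build(d - 1)), ") ",
                            sample(c("and", "or"), 1),
                            " (", canonical_text(build(d - 1)), ")"))
  }
  build(depth)
}

# Brute-force row-wise interpreter: the independent oracle for
# evaluate_filter. Applies the comparison semantics to one row at a time
# with no vectorization shared with the implementation.
brute_eval_row <- function(expr, bundle, i, delim = "|") {
  if (inherits(expr, "filter_connective")) {
    l <- brute_eval_row(expr$left, bundle, i, delim)
    r <- brute_eval_row(expr$right, bundle, i, delim)
    return(if (expr$op == "and") l && r else l || r)
  }
  cell <- bundle$table[[expr$attribute]][i]
  if (is.na(cell)) return(FALSE)
  kind <- bundle$attributes$kind[bundle$attributes$name == expr$attribute]
  numeric_kind <- kind != "categorical"
  switch(expr$operator,
    GT = as.numeric(cell) > as.numeric(expr$value),
    LT = as.numeric(cell) < as.numeric(expr$value),
    RANGE = {
      v <- as.numeric(expr$value)
      as.numeric(cell) >= v[1] && as.numeric(cell) <= v[2]
    },
    IS = if (numeric_kind) as.numeric(cell) == as.numeric(expr$value)
         else trimws(as.character(cell)) == trimws(expr$value),
    IS_NOT = if (numeric_kind) as.numeric(cell) != as.numeric(expr$value)
             else trimws(as.character(cell)) != trimws(expr$value),
    IN = if (numeric_kind) as.numeric(cell) %in% as.numeric(expr$value)
         else any(trimws(strsplit(as.character(cell), delim, fixed = TRUE)[[1]])
                  %in% trimws(expr$value)),
    NOT_IN = if (numeric_kind) !(as.numeric(cell) %in% as.numeric(expr$value))
             else !any(trimws(strsplit(as.character(cell), delim, fixed = TRUE)[[1]])
                       %in% trimws(expr$value)))
}

brute_eval <- function(expr, bundle) {
  vapply(seq_len(bundle$n_samples), function(i) brute_eval_row(expr, bundle, i),
         logical(1))
}
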