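# Global association scan: every eligible index attribute is tested
# against a target variable, a survival endpoint, or a case-control
# structure; raw p-values are corrected for multiplicity and results
# ranked deterministically.

#' Scan all attributes against a target
#'
#' For each index attribute except the target itself (and, for survival
#' targets, the endpoint's time/event columns), runs the comparison chosen
#' by [select_test()] and collects the raw p-values. Multiplicity is
#' corrected across the completed tests (default Benjamini-Hochberg FDR);
#' rows are flagged significant when the adjusted p-value is at most
#' `alpha`. Attributes that cannot be tested — constant, all-missing, or
#' with a level observed fewer than `min_level_n` times — are skipped with
#' an explicit reason, never silently dropped. Rows are sorted by ascending
#' adjusted p, ties broken by raw p then attribute name, so the ranking is
#' a deterministic total order independent of column storage order.
#'
#' @param bundle a `dataset_bundle`.
#' @param target attribute name, or `NULL` when scanning against an
#'   endpoint or cohorts.
#' @param endpoint endpoint group label for survival scans.
#' @param cohorts a `cohort_pair` for case-control scans.
#' @param alpha significance level in (0, 1) applied to adjusted p-values.
#' @param method multiplicity correction: `"bh"` (Benjamini-Hochberg,
#'   default), `"bonferroni"`, or `"none"`.
#' @param min_level_n minimum per-level count for a categorical attribute
#'   to be tested (default 5; prevents degenerate tables dominating the
#'   ranking).
#' @return object of class `scan_report`: `target` (description), `rows`
#'   (data.frame: attribute, test, effect_label, effect, statistic,
#'   p_value, adjusted_p, significant), `results` (named list of full
#'   `test_result`s), `skipped` (data.frame: attribute, reason), `method`,
#'   `alpha`, `n_tested`, `n_skipped`.
#' @export
scan_associations <- function(bundle, target = NULL, endpoint = NULL,
                              cohorts = NULL, alpha = 0.05,
                              method = c("bh", "bonferroni", "none"),
                              min_level_n = 5) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  modes <- c(!is.null(target), !is.null(endpoint), !is.null(cohorts))
  if (sum(modes) != 1) {
    stop("provide exactly one of target, endpoint, or cohorts")
  }
  attrs <- bundle$attributes
  exclude <- character()
  if (!is.null(target)) {
    if (!target %in% attrs$name) stop("target attribute '", target, "' not in bundle index")
    target_kind <- attribute_kind(bundle, target)
    if (target_kind %in% c("event_time", "event_indicator")) {
      stop("survival columns are scanned via endpoint = '<group>', not as target")
    }
    exclude <- target
    target_desc <- paste0("attribute ", target)
  } else if (!is.null(endpoint)) {
    ep <- resolve_endpoint(bundle, endpoint)
    exclude <- c(ep$time, ep$event)
    target_desc <- paste0("survival endpoint ", endpoint)
  } else {
    stopifnot(inherits(cohorts, "cohort_pair"))
    target_desc <- paste0("case-control structure: ",
                          canonical_text(cohorts$case_expr), " vs ",
                          canonical_text(cohorts$control_expr))
  }
  candidates <- setdiff(attrs$name, exclude)
  # survival columns of any endpoint are never scanned as plain attributes
  surv_cols <- attrs$name[attrs$kind %in% c("event_time", "event_indicator")]
  candidates <- setdiff(candidates, surv_cols)

  results <- list()
  skipped <- data.frame(attribute = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(attr, reason) {
    skipped[nrow(skipped) + 1L, ] <<- list(attr, reason)
  }
  for (attr in candidates) {
    kind <- attribute_kind(bundle, attr)
    col <- bundle$table[[attr]]
    res <- tryCatch({
      if (!is.null(cohorts)) {
        used <- cohorts$case_mask | cohorts$control_mask
        check_scannable(col[used], kind, min_level_n)
        compare_variable(attr, cohorts, bundle)
      } else if (!is.null(endpoint)) {
        scan_survival_one(bundle, attr, kind, ep, min_level_n)
      } else {
        scan_target_one(bundle, attr, kind, target, target_kind, min_level_n)
      }
    }, scan_skip = function(e) e, error = function(e) {
      simpleCondition(conditionMessage(e), call = NULL)
    })
    if (inherits(res, "test_result")) {
      if (res$test_name == "uninformative") {
        skip(attr, res$notes)
      } else {
        results[[attr]] <- res
      }
    } else {
      skip(attr, conditionMessage(res))
    }
  }
  raw_p <- vapply(results, function(r) r$p_value, numeric(1))
  adj_p <- stats::p.adjust(raw_p, method = switch(method, bh = "BH",
                                                  bonferroni = "bonferroni",
                                                  none = "none"))
  rows <- data.frame(
    attribute = names(results) %||% character(),
    test = vapply(results, function(r) r$test_name, character(1)),
    effect_label = vapply(results, function(r) r$effect_label, character(1)),
    effect = vapply(results, function(r) r$effect, numeric(1)),
    statistic = vapply(results, function(r) r$statistic, numeric(1)),
    p_value = unname(raw_p),
    adjusted_p = unname(adj_p),
    stringsAsFactors = FALSE
  )
  rows$significant <- rows$adjusted_p <= alpha
  ord <- order(rows$adjusted_p, rows$p_value, rows$attribute)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(
    list(target = target_desc, rows = rows, results = results,
         skipped = skipped, method = method, alpha = alpha,
         n_tested = nrow(rows), n_skipped = nrow(skipped)),
    class = "scan_report"
  )
}

# signal a structured skip
scan_skip <- function(msg) {
  stop(structure(class = c("scan_skip", "condition"),
                 list(message = msg, call = NULL)))
}

check_scannable <- function(col, kind, min_level_n) {
  obs <- col[!is.na(col)]
  if (length(obs) == 0) scan_skip("all values missing")
  if (length(unique(obs)) < 2) scan_skip("constant attribute")
  if (kind == "categorical") {
    counts <- table(obs)
    if (any(counts < min_level_n)) {
      scan_skip(paste0("level(s) with fewer than ", min_level_n,
                       " samples: ",
                       paste(names(counts)[counts < min_level_n], collapse = ", ")))
    }
  }
  invisible(TRUE)
}

scan_target_one <- function(bundle, attr, kind, target, target_kind, min_level_n) {
  x <- bundle$table[[attr]]
  y <- bundle$table[[target]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  check_scannable(x, kind, min_level_n)
  check_scannable(y, target_kind, min_level_n)
  lx <- length(unique(x)); ly <- length(unique(y))
  test <- select_test(kind, target_kind, levels_x = lx, levels_y = ly)
  # orient the pair the way the selected test expects (grouping on y)
  if (test %in% c("mann_whitney_u", "kruskal_wallis") && kind == "categorical") {
    run_pair_test(test, x = y, y = x, kind_x = target_kind)
  } else {
    run_pair_test(test, x = x, y = y, kind_x = kind)
  }
}

scan_survival_one <- function(bundle, attr, kind, ep, min_level_n) {
  x <- bundle$table[[attr]]
  time <- bundle$table[[ep$time]]
  event <- bundle$table[[ep$event]]
  keep <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (length(x) == 0) scan_skip("all values missing")
  if (kind == "numeric") {
    med <- stats::median(x)
    g <- ifelse(x > med, "above_median", "at_or_below_median")
    if (length(unique(g)) < 2) scan_skip("constant after median split")
    res <- logrank_test(time, event, g)
    res$test_name <- "logrank_median_split"
    return(res)
  }
  check_scannable(x, kind, min_level_n)
  lv <- sort(unique(x))
  if (length(lv) == 2) return(logrank_test(time, event, x))
  # multi-level categorical: k-group log-rank via the survival package
  sd <- survival::survdiff(survival::Surv(time, event) ~ x)
  df <- length(lv) - 1
  test_result("logrank_k_group", statistic = unname(sd$chisq),
              p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
              n_per_group = stats::setNames(as.integer(table(x)), lv))
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report> target:", x$target, "\n")
  cat("  ", x$n_tested, "attributes tested,", x$n_skipped, "skipped;",
      "correction:", x$method, "at alpha =", x$alpha, "\n")
  sig <- x$rows[x$rows$significant, , drop = FALSE]
  cat("  ", nrow(sig), "significant association(s)\n")
  if (nrow(x$rows) > 0) {
    print(utils::head(x$rows, 10), digits = 4)
  }
  if (x$n_skipped > 0) {
    cat("  skipped:\n")
    for (i in seq_len(nrow(x$skipped))) {
      cat("    -", x$skipped$attribute[i], ":", x$skipped$reason[i], "\n")
    }
  }
  invisible(x)
}
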