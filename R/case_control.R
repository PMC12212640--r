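# Case-control construction and the comparison repertoire: context
# enrichment (odds ratio), per-variable comparison with automatic test
# selection, and survival comparison (KM + log-rank + Cox).

#' Build case and control cohorts from filter expressions
#'
#' Evaluates both definitions against the bundle. Samples satisfying both
#' definitions are excluded from both cohorts — silent double counting
#' would corrupt the downstream 2x2 tables — and their number is recorded
#' in `overlap`. Samples satisfying neither definition are simply unused.
#' An empty cohort after overlap removal is an error naming the offending
#' definition.
#'
#' @param case_expr,control_expr filter expressions (text or parsed).
#' @param bundle a `dataset_bundle`.
#' @param ... passed to [evaluate_filter()] (e.g. `case_fold`).
#' @return object of class `cohort_pair`: `case_expr`, `control_expr`
#'   (parsed), `case_mask`, `control_mask`, `n_case`, `n_control`,
#'   `overlap` (count of excluded shared samples).
#' @export
build_cohorts <- function(case_expr, control_expr, bundle, ...) {
  case_expr <- as_filter_expr(case_expr)
  control_expr <- as_filter_expr(control_expr)
  case_mask <- evaluate_filter(case_expr, bundle, ...)
  control_mask <- evaluate_filter(control_expr, bundle, ...)
  both <- case_mask & control_mask
  case_mask[both] <- FALSE
  control_mask[both] <- FALSE
  if (sum(both) > 0) {
    warning(sum(both), " sample(s) satisfied both the case and the control ",
            "definition and were excluded from both cohorts")
  }
  if (sum(case_mask) == 0) {
    stop("empty case cohort for definition: ", canonical_text(case_expr))
  }
  if (sum(control_mask) == 0) {
    stop("empty control cohort for definition: ", canonical_text(control_expr))
  }
  structure(
    list(case_expr = case_expr, control_expr = control_expr,
         case_mask = case_mask, control_mask = control_mask,
         n_case = sum(case_mask), n_control = sum(control_mask),
         overlap = sum(both)),
    class = "cohort_pair"
  )
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat("<cohort_pair>\n")
  cat("  case   (n =", x$n_case, "):", canonical_text(x$case_expr), "\n")
  cat("  control(n =", x$n_control, "):", canonical_text(x$control_expr), "\n")
  if (x$overlap > 0) cat("  overlap excluded from both:", x$overlap, "\n")
  invisible(x)
}

#' Context enrichment across case and control cohorts
#'
#' Tests whether samples satisfying a combined filter (the "context") are
#' over-represented among cases versus controls: builds the 2x2 table with
#' rows case/control and columns in-context/out-of-context and runs
#' [odds_ratio_test()]. Per-cohort in-context percentages are reported in
#' `notes` and as the `prevalence` attribute.
#'
#' @param context_expr filter expression defining the context.
#' @param cohorts a `cohort_pair`.
#' @param bundle the `dataset_bundle` the cohorts were built on.
#' @param ... passed to [evaluate_filter()].
#' @return a `test_result` (odds ratio of in-context among cases vs
#'   controls) with an added `table` field (the 2x2 counts) and
#'   `prevalence` field (named percentages).
#' @export
context_enrichment <- function(context_expr, cohorts, bundle, ...) {
  stopifnot(inherits(cohorts, "cohort_pair"))
  ctx <- evaluate_filter(as_filter_expr(context_expr), bundle, ...)
  a <- sum(cohorts$case_mask & ctx)
  b <- sum(cohorts$case_mask & !ctx)
  c_ <- sum(cohorts$control_mask & ctx)
  d <- sum(cohorts$control_mask & !ctx)
  res <- odds_ratio_test(a, b, c_, d)
  prev <- c(case = 100 * a / (a + b), control = 100 * c_ / (c_ + d))
  res$n_per_group <- c(case = a + b, control = c_ + d)
  res$table <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                      dimnames = list(c("case", "control"),
                                      c("in_context", "out_of_context")))
  res$prevalence <- prev
  res$notes <- paste(c(sprintf("in-context: %.2f%% of cases vs %.2f%% of controls",
                               prev["case"], prev["control"]),
                       if (nzchar(res$notes)) res$notes), collapse = "; ")
  res
}

# Observed levels of an attribute among a set of samples (non-missing).
observed_levels <- function(bundle, attr, mask = TRUE) {
  col <- bundle$table[[attr]][mask]
  unique(col[!is.na(col)])
}

#' Compare one variable between case and control cohorts
#'
#' Dispatches on the attribute's statistical kind via [select_test()]
#' against the binary case/control label: binary categorical attributes use
#' the odds-ratio / Fisher path, multi-level categorical the chi-square
#' test, numeric attributes the Mann-Whitney U test. A variable constant
#' across all used samples is uninformative: flagged, p = 1.
#'
#' @param attr attribute name (must be in the bundle index).
#' @param cohorts a `cohort_pair`.
#' @param bundle the `dataset_bundle`.
#' @return a `test_result`.
#' @export
compare_variable <- function(attr, cohorts, bundle) {
  stopifnot(inherits(cohorts, "cohort_pair"))
  kind <- attribute_kind(bundle, attr)
  if (kind %in% c("event_time", "event_indicator")) {
    stop("attribute '", attr, "' is a survival column; use compare_survival()")
  }
  used <- cohorts$case_mask | cohorts$control_mask
  col <- bundle$table[[attr]]
  keep <- used & !is.na(col)
  vals <- col[keep]
  grp <- ifelse(cohorts$case_mask[keep], "case", "control")
  if (length(unique(vals)) < 2 || length(unique(grp)) < 2) {
    return(test_result("uninformative", p_value = 1,
                       n_per_group = c(case = sum(grp == "case"),
                                       control = sum(grp == "control")),
                       notes = paste0("variable '", attr,
                                      "' is constant or unobserved in the cohorts")))
  }
  test <- select_test(kind, "categorical",
                      levels_x = length(unique(vals)), levels_y = 2)
  run_pair_test(test, x = vals, y = grp, kind_x = kind)
}

# Execute one selected test on a prepared (x, y) pair; y is the grouping
# side for the asymmetric tests.
run_pair_test <- function(test, x, y, kind_x) {
  switch(test,
    odds_ratio_fisher = {
      lx <- sort(unique(x)); ly <- sort(unique(y))
      tab <- table(factor(y, levels = ly), factor(x, levels = lx))
      res <- odds_ratio_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
      res$notes <- paste(c(sprintf("outcome '%s' vs '%s' in groups '%s' vs '%s'",
                                   lx[1], lx[2], ly[1], ly[2]),
                           if (nzchar(res$notes)) res$notes), collapse = "; ")
      res
    },
    chi_square = chi_square_test(table(y, x)),
    mann_whitney_u = mann_whitney_test(as.numeric(x), y),
    kruskal_wallis = kruskal_wallis_test(as.numeric(x), y),
    spearman = spearman_test(as.numeric(x), as.numeric(y)),
    stop("unknown test id: ", test)
  )
}

#' Compare survival between case and control cohorts
#'
#' Resolves the endpoint group to its (time, event) column pair, estimates a
#' Kaplan-Meier curve per cohort, and runs both the log-rank test and the
#' single-covariate Cox model (case vs control). Samples missing either
#' endpoint column are dropped with counts in the notes.
#'
#' @param cohorts a `cohort_pair`.
#' @param endpoint_group endpoint label (e.g. `"PFS"`).
#' @param bundle the `dataset_bundle`.
#' @return object of class `survival_comparison`: `logrank` and `cox`
#'   `test_result`s, `curves` (named list of `survival_curve` for case and
#'   control), `endpoint`, `n_dropped`.
#' @export
compare_survival <- function(cohorts, endpoint_group, bundle) {
  stopifnot(inherits(cohorts, "cohort_pair"))
  ep <- resolve_endpoint(bundle, endpoint_group)
  time <- bundle$table[[ep$time]]
  event <- bundle$table[[ep$event]]
  used <- cohorts$case_mask | cohorts$control_mask
  ok <- used & !is.na(time) & !is.na(event)
  n_dropped <- sum(used) - sum(ok)
  grp <- ifelse(cohorts$case_mask, "case", "control")[ok]
  if (sum(event[ok]) == 0) {
    stop("no events observed in either cohort for endpoint '",
         endpoint_group, "'")
  }
  curves <- list(
    case = km_estimate(time[ok][grp == "case"], event[ok][grp == "case"]),
    control = km_estimate(time[ok][grp == "control"], event[ok][grp == "control"])
  )
  lr <- logrank_test(time[ok], event[ok], grp)
  # cox_hr codes the second sorted level ("control") as 1; report case vs
  # control instead by flipping the sign of beta
  cx <- cox_hr(time[ok], event[ok], grp)
  cx <- flip_hazard(cx)
  note <- if (n_dropped > 0) {
    paste(n_dropped, "cohort sample(s) dropped for missing endpoint data")
  }
  if (!is.null(note)) {
    lr$notes <- paste(c(lr$notes[nzchar(lr$notes)], note), collapse = "; ")
    cx$notes <- paste(c(cx$notes[nzchar(cx$notes)], note), collapse = "; ")
  }
  structure(
    list(logrank = lr, cox = cx, curves = curves,
         endpoint = endpoint_group, n_dropped = n_dropped),
    class = "survival_comparison"
  )
}

# Invert a hazard-ratio test_result (group2-vs-group1 -> group1-vs-group2).
flip_hazard <- function(res) {
  if (is.na(res$effect)) return(res)
  new_eff <- 1 / res$effect
  lo <- if (is.na(res$ci_high)) NA_real_ else 1 / res$ci_high
  hi <- if (is.na(res$ci_low)) NA_real_ else 1 / res$ci_low
  res$effect <- new_eff
  res$ci_low <- lo
  res$ci_high <- hi
  res$statistic <- -res$statistic
  res$n_per_group <- rev(res$n_per_group)
  res
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("<survival_comparison> endpoint:", x$endpoint, "\n")
  cat(sprintf("  log-rank: chi-square = %.4g, p = %s\n",
              x$logrank$statistic, format_p(x$logrank$p_value)))
  cat(sprintf("  Cox HR (case vs control) = %.4g [%.4g, %.4g], p = %s\n",
              x$cox$effect, x$cox$ci_low, x$cox$ci_high, format_p(x$cox$p_value)))
  invisible(x)
}
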