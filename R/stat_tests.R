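# Statistical primitives: test selection by variable kind, odds-ratio /
# Fisher, chi-square, and the nonparametric numeric comparisons.

#' Construct a test result
#'
#' Common container for every statistical comparison the engine runs.
#'
#' @param test_name identifier of the test performed.
#' @param effect_label one of `"odds_ratio"`, `"hazard_ratio"`,
#'   `"difference"`, `"correlation"`, `"none"`.
#' @param effect point estimate (`NA` when undefined or not applicable).
#' @param ci_low,ci_high 95% confidence limits.
#' @param statistic test statistic.
#' @param p_value two-sided p-value in `[0, 1]`.
#' @param n_per_group named integer vector of group sizes.
#' @param notes free-text caveats (degeneracy, corrections applied, drops).
#' @return object of class `test_result`.
#' @export
test_result <- function(test_name, effect_label = "none", effect = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        n_per_group = integer(), notes = character()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    list(test_name = test_name, effect_label = effect_label,
         effect = effect, ci_low = ci_low, ci_high = ci_high,
         statistic = statistic, p_value = min(p_value, 1),
         n_per_group = n_per_group, notes = paste(notes, collapse = "; ")),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$test_name, "\n")
  if (x$effect_label != "none" && !is.na(x$effect)) {
    cat(sprintf("  %s = %.4g [%.4g, %.4g]\n", x$effect_label, x$effect,
                x$ci_low, x$ci_high))
  }
  cat(sprintf("  statistic = %.4g, p = %s\n", x$statistic, format_p(x$p_value)))
  if (length(x$n_per_group)) {
    cat("  n:", paste(names(x$n_per_group), x$n_per_group, sep = "=",
                      collapse = ", "), "\n")
  }
  if (nzchar(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

# Data-driven test-selection table: one row per (kind_x, kind_y) situation.
# binary_x/binary_y: NA = any level count, TRUE = exactly 2 levels.
.test_rules <- data.frame(
  kind_x = c("categorical", "categorical", "numeric", "numeric", "numeric",
             "categorical", "numeric"),
  kind_y = c("categorical", "categorical", "categorical", "categorical",
             "numeric", "survival", "survival"),
  binary_x = c(TRUE, NA, NA, NA, NA, NA, NA),
  binary_y = c(TRUE, NA, TRUE, FALSE, NA, NA, NA),
  test = c("odds_ratio_fisher", "chi_square", "mann_whitney_u",
           "kruskal_wallis", "spearman", "logrank", "logrank_median_split"),
  stringsAsFactors = FALSE
)

#' Select the appropriate statistical test for a variable pair
#'
#' Deterministic mapping from the statistical kinds of the two variables to
#' a test identifier, implemented as a single data-driven rule table:
#' categorical x categorical uses the odds-ratio / Fisher path when both are
#' binary and the chi-square test of independence otherwise; numeric against
#' a 2-level grouping uses the Mann-Whitney U test, against more levels
#' Kruskal-Wallis; numeric x numeric uses Spearman correlation; anything
#' against a survival endpoint uses the log-rank test, with numeric
#' variables dichotomized at their median. The mapping is total over kinds;
#' an `event_indicator` or `event_time` used outside a survival context is
#' a selection error.
#'
#' @param kind_x,kind_y attribute kinds (`"numeric"`, `"categorical"`) or
#'   `"survival"` for `kind_y` to denote a survival endpoint.
#' @param levels_x,levels_y number of observed levels (needed for
#'   categorical kinds; ignored otherwise).
#' @return character test identifier.
#' @export
select_test <- function(kind_x, kind_y, levels_x = NA, levels_y = NA) {
  for (k in c(kind_x, kind_y)) {
    if (k %in% c("event_indicator", "event_time")) {
      stop("survival columns must be addressed via their endpoint group, ",
           "not as plain variables")
    }
  }
  stopifnot(kind_x %in% c("numeric", "categorical"),
            kind_y %in% c("numeric", "categorical", "survival"))
  is_bin <- function(k, n) if (k != "categorical") NA else !is.na(n) && n == 2
  bx <- is_bin(kind_x, levels_x)
  by <- if (kind_y == "survival") NA else is_bin(kind_y, levels_y)
  for (i in seq_len(nrow(.test_rules))) {
    r <- .test_rules[i, ]
    if (r$kind_x != kind_x || r$kind_y != kind_y) next
    if (!is.na(r$binary_x) && (is.na(bx) || r$binary_x != bx)) next
    if (!is.na(r$binary_y) && (is.na(by) || r$binary_y != by)) next
    return(r$test)
  }
  # symmetric retry for pairs stated in the other orientation
  if (kind_y != "survival" && kind_x != kind_y) {
    return(select_test(kind_y, kind_x, levels_y, levels_x))
  }
  stop("no test rule for kinds (", kind_x, ", ", kind_y, ")")
}

# Two-sided Fisher exact p for a 2x2 table by summation of hypergeometric
# probabilities of tables as or more extreme (probability at most that of
# the observed table, with a small relative tolerance for ties).
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b # margin of row 1
  n <- c + d
  k <- a + c # margin of column 1
  if (m + n == 0) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Odds-ratio test on a 2x2 contingency table
#'
#' Rows are the two groups, columns the outcome (yes/no). The effect is the
#' cross-product odds ratio `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell for the estimate and
#' its confidence interval. The 95% CI is
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` on the (possibly
#' corrected) cells. The p-value is Fisher's exact two-sided test computed
#' by hypergeometric enumeration of the uncorrected counts. A table with an
#' all-zero margin is degenerate: the effect is undefined (`NA`) and p = 1,
#' flagged in `notes`.
#'
#' @param a,b,c,d non-negative integer counts: `a`,`b` = group 1
#'   outcome-yes/no, `c`,`d` = group 2 outcome-yes/no.
#' @return a `test_result` with `effect_label = "odds_ratio"`.
#' @export
odds_ratio_test <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("empty contingency table")
  n_grp <- c(group1 = a + b, group2 = c + d)
  degenerate <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  if (degenerate) {
    return(test_result("odds_ratio_fisher", "odds_ratio",
                       effect = NA_real_, statistic = NA_real_, p_value = 1,
                       n_per_group = n_grp,
                       notes = "degenerate table: an all-zero margin; odds ratio undefined"))
  }
  corrected <- any(counts == 0)
  cc <- if (corrected) counts + 0.5 else counts
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- fisher_exact_p(a, b, c, d)
  test_result("odds_ratio_fisher", "odds_ratio",
              effect = unname(or), ci_low = ci[1], ci_high = ci[2],
              statistic = unname(log(or) / se), p_value = p,
              n_per_group = n_grp,
              notes = if (corrected) "Haldane-Anscombe 0.5 correction applied to zero cell(s)" else character())
}

#' Chi-square test of independence on an r x c table
#'
#' Pearson chi-square with `(r-1)(c-1)` degrees of freedom. A 2x2 table
#' with any expected count below 5 is routed to [odds_ratio_test()]
#' (Fisher's exact path) instead. A zero-total table is degenerate
#' (effect undefined, p = 1).
#'
#' @param tab integer matrix of counts, at least 2x2.
#' @return a `test_result`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  n_grp <- stats::setNames(as.integer(rowSums(tab)),
                           rownames(tab) %||% paste0("group", seq_len(nrow(tab))))
  if (sum(tab) == 0) {
    return(test_result("chi_square", p_value = 1, n_per_group = n_grp,
                       notes = "degenerate table: zero total"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (nrow(tab) == 2 && ncol(tab) == 2 && any(expected < 5)) {
    res <- odds_ratio_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    res$notes <- paste(c("expected count < 5: routed to Fisher's exact test",
                         if (nzchar(res$notes)) res$notes), collapse = "; ")
    return(res)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(test_result("chi_square", p_value = 1, n_per_group = n_grp,
                       notes = "degenerate table: an all-zero margin"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("chi_square", statistic = unname(ct$statistic),
              p_value = ct$p.value, n_per_group = n_grp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric-vs-grouping and numeric-vs-numeric comparisons (nonparametric
# defaults: clinical variables are routinely non-normal).
mann_whitney_test <- function(x, g) {
  lv <- sort(unique(g))
  stopifnot(length(lv) == 2)
  x1 <- x[g == lv[1]]; x2 <- x[g == lv[2]]
  wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE, correct = TRUE))
  test_result("mann_whitney_u", "difference",
              effect = stats::median(x1) - stats::median(x2),
              statistic = unname(wt$statistic), p_value = wt$p.value,
              n_per_group = stats::setNames(c(length(x1), length(x2)), as.character(lv)),
              notes = "effect is the difference in group medians")
}

kruskal_wallis_test <- function(x, g) {
  kt <- stats::kruskal.test(x, factor(g))
  test_result("kruskal_wallis", statistic = unname(kt$statistic),
              p_value = kt$p.value,
              n_per_group = stats::setNames(as.integer(table(g)),
                                            names(table(g))))
}

spearman_test <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  test_result("spearman", "correlation", effect = unname(ct$estimate),
              statistic = unname(ct$statistic), p_value = ct$p.value,
              n_per_group = c(n = length(x)))
}

format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "g", flag = "#")))
}
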