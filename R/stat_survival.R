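# Survival primitives: Kaplan-Meier product-limit estimation, the two-group
# log-rank test, and a single-binary-covariate Cox model with Breslow tie
# handling. These are authored here (rather than delegated) because the
# engine commits to an exactly reproducible computation path; the survival
# package serves as an independent cross-check in the test suite.

drop_missing_pairs <- function(time, event, group = NULL) {
  keep <- !is.na(time) & !is.na(event)
  if (!is.null(group)) keep <- keep & !is.na(group)
  list(time = time[keep], event = event[keep],
       group = if (is.null(group)) NULL else group[keep],
       n_dropped = sum(!keep))
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`
#' over the distinct event times `t_i`, where `d_i` is the number of events
#' and `n_i` the number at risk at `t_i`. Times at which only censoring
#' occurs reduce the risk set without producing a step. Pairs with a
#' missing time or indicator are dropped and counted.
#'
#' @param time non-negative event/censoring times.
#' @param event 0/1 event indicators (1 = event, 0 = censored).
#' @return object of class `survival_curve`: data.frame-like list with
#'   `times` (increasing distinct event times), `survival` (non-increasing),
#'   `at_risk`, `n_events`, plus `n`, `n_dropped`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  d <- drop_missing_pairs(time, event)
  if (length(d$time) == 0) stop("no usable observations for survival estimation")
  stopifnot(all(d$time >= 0), all(d$event %in% c(0, 1)))
  ord <- order(d$time)
  tm <- d$time[ord]; ev <- d$event[ord]
  n <- length(tm)
  ut <- unique(tm)
  at_risk <- n - c(0, cumsum(tabulate(match(tm, ut))))[seq_along(ut)]
  d_i <- as.integer(table(factor(tm[ev == 1], levels = ut)))
  keep <- d_i > 0
  surv <- cumprod(1 - d_i[keep] / at_risk[keep])
  structure(
    list(times = ut[keep], survival = surv,
         at_risk = as.integer(at_risk[keep]), n_events = as.integer(d_i[keep]),
         n = n, n_dropped = d$n_dropped),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> n =", x$n, "(", sum(x$n_events), "events )\n")
  if (length(x$times)) {
    cat(sprintf("  S(t) steps from %.3f at t=%.3g to %.3f at t=%.3g\n",
                x$survival[1], x$times[1],
                x$survival[length(x$survival)], x$times[length(x$times)]))
  }
  invisible(x)
}

#' Evaluate a survival curve at arbitrary times
#' @param curve a `survival_curve`.
#' @param t times at which to read off `S(t)`.
#' @return numeric vector of survival probabilities.
#' @export
surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$times <= tt)
    if (length(idx) == 0) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

# Per-event-time log-rank tabulation shared by logrank_test and (as the
# score-test identity check) cox_hr: observed minus expected events in
# group 1 with the hypergeometric variance at each distinct event time.
logrank_tabulate <- function(time, event, group1) {
  rs <- risk_sets(time, event, group1)
  n_i <- rs$n; n1_i <- rs$n1; d_i <- rs$d
  E1 <- d_i * n1_i / n_i
  V <- ifelse(n_i > 1,
              d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1),
              0)
  data.frame(time = rs$time, O1 = rs$d1, E1 = E1, V = V)
}

# Shared per-distinct-event-time tabulation: number at risk overall and in
# group 1, events overall and in group 1. Vectorized via sorted counts.
risk_sets <- function(time, event, group1) {
  ut <- sort(unique(time[event == 1]))
  st <- sort(time)
  st1 <- sort(time[group1])
  n_at <- length(st) - findInterval(ut, st, left.open = TRUE)
  n1_at <- length(st1) - findInterval(ut, st1, left.open = TRUE)
  f <- factor(time[event == 1], levels = ut)
  d <- as.integer(table(f))
  d1 <- as.integer(table(f[group1[event == 1]]))
  list(time = ut, n = n_at, n1 = n1_at, d = d, d1 = d1)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom:
#' `statistic = (sum(O1 - E1))^2 / sum(V)` with the hypergeometric variance
#' contribution at each distinct event time; the p-value is the upper tail
#' of the chi-square(1) distribution. Missing triples are dropped with a
#' count in `notes`.
#'
#' @param time non-negative times.
#' @param event 0/1 indicators.
#' @param group binary group labels (any two distinct values).
#' @return a `test_result`.
#' @export
logrank_test <- function(time, event, group) {
  d <- drop_missing_pairs(time, event, group)
  lv <- sort(unique(d$group))
  if (length(lv) != 2) stop("log-rank test requires exactly two non-empty groups")
  g1 <- d$group == lv[1]
  tab <- logrank_tabulate(d$time, d$event, g1)
  sumV <- sum(tab$V)
  n_grp <- stats::setNames(c(sum(g1), sum(!g1)), as.character(lv))
  if (sumV == 0) {
    return(test_result("logrank", p_value = 1, statistic = 0,
                       n_per_group = n_grp,
                       notes = "no usable event times; test degenerate"))
  }
  stat <- sum(tab$O1 - tab$E1)^2 / sumV
  test_result("logrank", statistic = stat,
              p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
              n_per_group = n_grp,
              notes = if (d$n_dropped > 0) paste(d$n_dropped, "observations dropped for missing data") else character())
}

# Breslow log partial likelihood pieces for one binary covariate.
# Returns score U(beta) and information I(beta) over distinct event times.
.cox_score_info <- function(beta, tab) {
  # tab: per distinct event time: d (events), d1 (events in group1),
  #      n1, n0 (at risk in group1/0)
  r <- exp(beta)
  denom <- tab$n0 + tab$n1 * r
  mu <- tab$n1 * r / denom
  U <- sum(tab$d1 - tab$d * mu)
  I <- sum(tab$d * mu * (1 - mu))
  ll <- sum(beta * tab$d1 - tab$d * log(denom))
  list(U = U, I = I, ll = ll)
}

cox_event_table <- function(time, event, group1) {
  rs <- risk_sets(time, event, group1)
  data.frame(time = rs$time, d = rs$d, d1 = rs$d1,
             n1 = rs$n1, n0 = rs$n - rs$n1)
}

#' Cox proportional-hazards estimate for a single binary covariate
#'
#' Maximizes the Breslow-tie partial likelihood by safeguarded
#' Newton-Raphson iteration (step-halving on likelihood decrease;
#' convergence tolerance 1e-8 on the score, at most 100 iterations) and
#' reports the hazard ratio `exp(beta)` with Wald 95% CI and p-value.
#' Complete separation (all events in one group) yields a monotone
#' likelihood: the result is flagged, with an infinite CI bound, rather
#' than an error.
#'
#' @param time non-negative times.
#' @param event 0/1 indicators; at least one event required.
#' @param group binary covariate (any two distinct values; the higher sorted
#'   level is coded 1 so the hazard ratio is level2 vs level1).
#' @return a `test_result` with `effect_label = "hazard_ratio"`.
#' @export
cox_hr <- function(time, event, group) {
  d <- drop_missing_pairs(time, event, group)
  lv <- sort(unique(d$group))
  if (length(lv) != 2) stop("Cox comparison requires exactly two non-empty groups")
  if (sum(d$event) == 0) stop("no events observed; hazard ratio undefined")
  g1 <- d$group == lv[2] # code the second sorted level as 1
  n_grp <- stats::setNames(c(sum(!g1), sum(g1)), as.character(lv))
  tab <- cox_event_table(d$time, d$event, g1)
  notes <- if (d$n_dropped > 0) {
    paste(d$n_dropped, "observations dropped for missing data")
  } else character()
  d1_tot <- sum(tab$d1)
  d0_tot <- sum(tab$d) - d1_tot
  if (d1_tot == 0 || d0_tot == 0) {
    # monotone partial likelihood: beta runs to +/- infinity
    hr <- if (d1_tot == 0) 0 else Inf
    return(test_result("cox_breslow", "hazard_ratio", effect = hr,
                       ci_low = if (d1_tot == 0) 0 else NA_real_,
                       ci_high = if (d1_tot == 0) NA_real_ else Inf,
                       statistic = NA_real_, p_value = NA_real_,
                       n_per_group = n_grp,
                       notes = c(notes, "monotone likelihood: all events in one group; estimate diverges")))
  }
  beta <- 0
  cur <- .cox_score_info(beta, tab)
  converged <- FALSE
  for (iter in seq_len(100)) {
    if (abs(cur$U) < 1e-8) { converged <- TRUE; break }
    step <- cur$U / cur$I
    # safeguard: halve the step until the log partial likelihood improves
    for (h in 0:30) {
      cand <- beta + step / 2^h
      new <- .cox_score_info(cand, tab)
      if (new$ll >= cur$ll - 1e-12) break
    }
    beta <- cand
    cur <- new
  }
  se <- 1 / sqrt(cur$I)
  z <- beta / se
  test_result("cox_breslow", "hazard_ratio", effect = exp(beta),
              ci_low = exp(beta - stats::qnorm(0.975) * se),
              ci_high = exp(beta + stats::qnorm(0.975) * se),
              statistic = z,
              p_value = 2 * stats::pnorm(-abs(z)),
              n_per_group = n_grp,
              notes = c(notes,
                        if (!converged) "Newton iteration did not reach tolerance in 100 steps"))
}
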