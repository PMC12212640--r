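# Rule-based natural-language front-end: classify a free-text request into
# an analysis intent, extract a structured plan against a bundle's
# attribute vocabulary, and (optionally) delegate plan proposal to an
# external language-model adapter whose output is validated before use.
# Core analyses never require the adapter, and no sample-level data is ever
# passed to it — only attribute names and kinds.

.intents <- c("association", "case_control", "lookup", "global_scan",
              "survival_comparison", "ambiguous")

#' Classify the analysis intent of a free-text request
#'
#' Deterministic keyword/pattern classification. Comparative survival
#' phrasing maps to `survival_comparison`; "compare X in A versus B" to
#' `case_control`; "is X linked/associated with Y" to `association`;
#' "tell me everything associated with" / "find all variables" to
#' `global_scan`; distribution/summary queries to `lookup`. Text matching
#' none of the patterns is classified `ambiguous` — never a silent guess.
#'
#' @param text free-text request.
#' @return one of `"association"`, `"case_control"`, `"lookup"`,
#'   `"global_scan"`, `"survival_comparison"`, `"ambiguous"`.
#' @export
classify_intent <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stop("request text must be a non-empty string")
  }
  s <- tolower(text)
  has <- function(p) grepl(p, s, perl = TRUE)
  survival_words <- "(survival|progression[- ]free|overall survival|\\bpfs\\b|\\bos\\b|time to (event|progression|death)|outcome)"
  if (has(survival_words) &&
      has("(compare|differ|different|versus|\\bvs\\b|with and without|better|worse)")) {
    return("survival_comparison")
  }
  if (has("(tell me everything associated|find all (the )?variables|everything (that is )?associated|scan all|all variables associated)")) {
    return("global_scan")
  }
  if (has("\\bcompare\\b") &&
      has("( in | between | versus | vs |early|late|with and without)")) {
    return("case_control")
  }
  if (has("(linked to|linked with|associated with|association between|correlate|correlated with|related to)")) {
    return("association")
  }
  if (has("(distribution|how many|summar(y|ize)|show me|what (is|are) the (values|levels)|look ?up)")) {
    return("lookup")
  }
  "ambiguous"
}

#' Construct an analysis plan
#'
#' @param intent one of the supported intents.
#' @param dataset bundle name or path.
#' @param expressions named list of filter expressions (`subset`, `case`,
#'   `control`, `context`), parsed or text.
#' @param target attribute name(s) or endpoint group the analysis is aimed
#'   at.
#' @param parameters list of analysis parameters (`alpha`, report options).
#' @param provenance which extractor produced the plan.
#' @param gaps character vector of open questions that must be resolved by
#'   the user before the plan can run.
#' @return object of class `analysis_plan` (unconfirmed).
#' @export
analysis_plan <- function(intent, dataset = NA_character_,
                          expressions = list(), target = NULL,
                          parameters = list(alpha = 0.05),
                          provenance = "rule_based", gaps = character()) {
  stopifnot(intent %in% .intents)
  expressions <- lapply(expressions, as_filter_expr)
  structure(
    list(intent = intent, dataset = dataset, expressions = expressions,
         target = target, parameters = parameters, provenance = provenance,
         gaps = gaps, confirmed = FALSE),
    class = "analysis_plan"
  )
}

#' Validate an analysis plan against its intent invariants
#'
#' Checks the intent-specific required fields: a `case_control` or
#' `survival_comparison` plan requires case and control expressions (the
#' latter also an endpoint target); a `global_scan` requires a target; an
#' `association` requires two variables; a `lookup` one. Plans with open
#' gaps are invalid until resolved.
#'
#' @param plan an `analysis_plan`.
#' @param bundle optional `dataset_bundle` to check attribute references
#'   against.
#' @return invisibly `TRUE`; errors describe every violation found.
#' @export
validate_plan <- function(plan, bundle = NULL) {
  stopifnot(inherits(plan, "analysis_plan"))
  problems <- character()
  need_expr <- function(nm) {
    if (is.null(plan$expressions[[nm]])) {
      problems <<- c(problems, paste0("missing '", nm, "' expression"))
    }
  }
  if (length(plan$gaps) > 0) {
    problems <- c(problems, paste("unresolved gap:", plan$gaps))
  }
  switch(plan$intent,
    case_control = { need_expr("case"); need_expr("control") },
    survival_comparison = {
      need_expr("case"); need_expr("control")
      if (is.null(plan$target)) problems <- c(problems, "missing endpoint target")
    },
    global_scan = {
      if (is.null(plan$target)) problems <- c(problems, "missing scan target")
    },
    association = {
      if (length(plan$target) != 2) {
        problems <- c(problems, "association requires exactly two variables")
      }
    },
    lookup = {
      if (length(plan$target) != 1) {
        problems <- c(problems, "lookup requires exactly one attribute")
      }
    },
    ambiguous = {
      problems <- c(problems, "intent is ambiguous; rephrase the request")
    }
  )
  if (!is.null(bundle)) {
    eps <- endpoint_groups(bundle)
    for (tgt in plan$target) {
      if (!tgt %in% c(bundle$attributes$name, eps)) {
        problems <- c(problems, paste0("target '", tgt, "' not in bundle"))
      }
    }
    for (nm in names(plan$expressions)) {
      attrs <- expr_attributes(plan$expressions[[nm]])
      missing <- setdiff(attrs, bundle$attributes$name)
      if (length(missing) > 0) {
        problems <- c(problems, paste0("expression '", nm,
                                       "' references unknown attribute(s): ",
                                       paste(missing, collapse = ", ")))
      }
    }
  }
  if (length(problems) > 0) {
    stop("invalid analysis plan:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(TRUE)
}

expr_attributes <- function(expr) {
  if (inherits(expr, "filter_comparison")) return(expr$attribute)
  c(expr_attributes(expr$left), expr_attributes(expr$right))
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat("<analysis_plan>", x$intent,
      if (x$confirmed) "(confirmed)" else "(unconfirmed)", "\n")
  if (!is.na(x$dataset)) cat("  dataset:", x$dataset, "\n")
  for (nm in names(x$expressions)) {
    cat("  ", nm, ": ", canonical_text(x$expressions[[nm]]), "\n", sep = "")
  }
  if (!is.null(x$target)) cat("  target:", paste(x$target, collapse = ", "), "\n")
  if (length(x$gaps)) {
    cat("  open questions:\n")
    for (g in x$gaps) cat("    ?", g, "\n")
  }
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Map a mentioned gene to its per-sample binary mutation column, if the
# bundle has one (e.g. "KRAS mutations" -> KRAS_mutation_status).
find_mutation_column <- function(gene, bundle) {
  cand <- paste0(tolower(gene), c("_mutation_status", "_mutation", "_mut"))
  hits <- bundle$attributes$name[tolower(bundle$attributes$name) %in% cand]
  if (length(hits) >= 1) hits[1] else NULL
}

# Exact then case-insensitive attribute-name match; NULL when absent.
match_attribute <- function(token, bundle, fuzzy = FALSE) {
  nm <- bundle$attributes$name
  if (token %in% nm) return(token)
  hit <- nm[tolower(nm) == tolower(token)]
  if (length(hit) >= 1) return(hit[1])
  if (fuzzy) {
    dist <- utils::adist(tolower(token), tolower(nm))
    hit <- nm[dist <= 1]
    if (length(hit) == 1) return(hit)
  }
  NULL
}

match_endpoint <- function(s, bundle) {
  eps <- endpoint_groups(bundle)
  s <- tolower(s)
  for (ep in eps) {
    if (grepl(tolower(ep), s, fixed = TRUE)) return(ep)
  }
  if (grepl("progression[- ]free", s) && "PFS" %in% eps) return("PFS")
  if (grepl("overall survival", s) && "OS" %in% eps) return("OS")
  if (length(eps) == 1) return(eps)
  NULL
}

#' Extract an analysis plan from free text
#'
#' Classifies the intent, then maps mentioned entities onto the bundle's
#' attribute vocabulary by exact and case-insensitive name match (an
#' optional fuzzy mode with edit distance 1 is off by default — silently
#' fuzzy-matching clinical column names is a correctness hazard). Mentions
#' of "<GENE> mutation(s)" map to the bundle's `<GENE>_mutation_status`
#' column when one exists. Entities that cannot be grounded become explicit
#' open questions (`gaps`) in the plan rather than guesses, and the plan
#' must be confirmed with [confirm_plan()] before [execute_plan()] will run
#' it.
#'
#' @param text free-text request.
#' @param bundle a `dataset_bundle`.
#' @param fuzzy allow edit-distance-1 attribute matching (default `FALSE`).
#' @return an unconfirmed `analysis_plan`.
#' @export
extract_plan <- function(text, bundle, fuzzy = FALSE) {
  intent <- classify_intent(text)
  genes <- unique(regmatches(text,
    gregexpr("\\b([A-Z][A-Z0-9]{1,9})\\b(?=[ -]?[Mm]utation)", text, perl = TRUE))[[1]])
  mut_cols <- Filter(Negate(is.null),
                     lapply(genes, find_mutation_column, bundle = bundle))
  gaps <- character()
  unmatched <- genes[vapply(genes, function(g) is.null(find_mutation_column(g, bundle)),
                            logical(1))]
  if (length(unmatched) > 0) {
    gaps <- c(gaps, paste0("no mutation-status column found for gene '",
                           unmatched, "'"))
  }
  expressions <- list()
  target <- NULL
  if (intent == "survival_comparison") {
    ep <- match_endpoint(text, bundle)
    if (is.null(ep)) {
      gaps <- c(gaps, "which survival endpoint should be compared?")
    } else {
      target <- ep
    }
    if (length(mut_cols) >= 1) {
      expressions$case <- parse_expression(paste0("(", mut_cols[[1]], " is 1)"))
      expressions$control <- parse_expression(paste0("(", mut_cols[[1]], " is 0)"))
    } else {
      gaps <- c(gaps, "case and control definitions are needed")
    }
  } else if (intent == "case_control") {
    if (length(mut_cols) >= 1) {
      expressions$context <- parse_expression(paste0("(", mut_cols[[1]], " is 1)"))
    }
    gaps <- c(gaps, "case cohort definition is needed",
              "control cohort definition is needed")
  } else if (intent == "global_scan") {
    ep <- match_endpoint(text, bundle)
    if (!is.null(ep) && grepl("survival", tolower(text))) {
      target <- ep
    } else if (length(mut_cols) >= 1) {
      target <- mut_cols[[1]]
    } else {
      # try to ground a directly mentioned attribute name
      hits <- bundle$attributes$name[
        vapply(bundle$attributes$name,
               function(a) grepl(a, text, ignore.case = TRUE, fixed = FALSE),
               logical(1))]
      if (length(hits) >= 1) target <- hits[1]
      else gaps <- c(gaps, "scan target could not be identified")
    }
  } else if (intent == "association") {
    vars <- unlist(mut_cols, use.names = FALSE)
    direct <- bundle$attributes$name[
      vapply(bundle$attributes$name,
             function(a) grepl(paste0("\\b", a, "\\b"), text, ignore.case = TRUE),
             logical(1))]
    vars <- unique(c(vars, direct))
    if (length(vars) >= 2) {
      target <- vars[1:2]
    } else {
      gaps <- c(gaps, "association requires two groundable variables")
      target <- vars
    }
  } else if (intent == "lookup") {
    direct <- bundle$attributes$name[
      vapply(bundle$attributes$name,
             function(a) grepl(paste0("\\b", a, "\\b"), text, ignore.case = TRUE),
             logical(1))]
    if (length(direct) >= 1) target <- direct[1]
    else gaps <- c(gaps, "lookup attribute could not be identified")
  }
  analysis_plan(intent, dataset = NA_character_, expressions = expressions,
                target = target, provenance = "rule_based", gaps = gaps)
}

#' Confirm an analysis plan for execution
#'
#' Plans are never executed implicitly: validation runs first, then the
#' returned copy carries the confirmation flag [execute_plan()] requires.
#'
#' @param plan an `analysis_plan`.
#' @param bundle optional bundle for reference validation.
#' @return the confirmed plan.
#' @export
confirm_plan <- function(plan, bundle = NULL) {
  validate_plan(plan, bundle)
  plan$confirmed <- TRUE
  plan
}

#' Execute a confirmed analysis plan
#'
#' Runs the analysis the plan describes against the bundle. Refuses
#' unconfirmed or invalid plans.
#'
#' @param plan a confirmed `analysis_plan`.
#' @param bundle a `dataset_bundle`.
#' @return the analysis result: a `test_result`, `survival_comparison`,
#'   `scan_report`, or lookup summary depending on intent.
#' @export
execute_plan <- function(plan, bundle) {
  stopifnot(inherits(plan, "analysis_plan"))
  if (!isTRUE(plan$confirmed)) {
    stop("plan is not confirmed; call confirm_plan() first")
  }
  validate_plan(plan, bundle)
  alpha <- plan$parameters$alpha %||% 0.05
  switch(plan$intent,
    survival_comparison = {
      cohorts <- build_cohorts(plan$expressions$case, plan$expressions$control,
                               bundle)
      compare_survival(cohorts, plan$target, bundle)
    },
    case_control = {
      cohorts <- build_cohorts(plan$expressions$case, plan$expressions$control,
                               bundle)
      if (!is.null(plan$expressions$context)) {
        context_enrichment(plan$expressions$context, cohorts, bundle)
      } else if (!is.null(plan$target)) {
        compare_variable(plan$target, cohorts, bundle)
      } else {
        scan_associations(bundle, cohorts = cohorts, alpha = alpha)
      }
    },
    global_scan = {
      if (plan$target %in% endpoint_groups(bundle)) {
        scan_associations(bundle, endpoint = plan$target, alpha = alpha)
      } else {
        scan_associations(bundle, target = plan$target, alpha = alpha)
      }
    },
    association = {
      x <- plan$target[1]; y <- plan$target[2]
      pair_association(bundle, x, y)
    },
    lookup = lookup_attribute(bundle, plan$target)
  )
}

#' Association test between two named attributes
#' @param bundle a `dataset_bundle`.
#' @param x,y attribute names.
#' @return a `test_result`.
#' @export
pair_association <- function(bundle, x, y) {
  kx <- attribute_kind(bundle, x)
  ky <- attribute_kind(bundle, y)
  cx <- bundle$table[[x]]; cy <- bundle$table[[y]]
  keep <- !is.na(cx) & !is.na(cy)
  cx <- cx[keep]; cy <- cy[keep]
  test <- select_test(kx, ky, levels_x = length(unique(cx)),
                      levels_y = length(unique(cy)))
  if (test %in% c("mann_whitney_u", "kruskal_wallis") && kx == "categorical") {
    run_pair_test(test, x = cy, y = cx, kind_x = ky)
  } else {
    run_pair_test(test, x = cx, y = cy, kind_x = kx)
  }
}

#' Distribution lookup for one attribute
#' @param bundle a `dataset_bundle`.
#' @param attr attribute name.
#' @return a list summary: level counts for categorical attributes, the
#'   five-number summary plus mean for numeric ones; missing count always.
#' @export
lookup_attribute <- function(bundle, attr) {
  kind <- attribute_kind(bundle, attr)
  col <- bundle$table[[attr]]
  n_missing <- sum(is.na(col))
  if (kind == "categorical") {
    counts <- table(col)
    list(attribute = attr, kind = kind,
         levels = stats::setNames(as.integer(counts), names(counts)),
         n_missing = n_missing)
  } else {
    obs <- col[!is.na(col)]
    list(attribute = attr, kind = kind,
         summary = c(min = min(obs), q1 = unname(stats::quantile(obs, .25)),
                     median = stats::median(obs),
                     q3 = unname(stats::quantile(obs, .75)), max = max(obs),
                     mean = mean(obs)),
         n_missing = n_missing)
  }
}

# -- LLM adapter contract ----------------------------------------------------

.adapter_env <- new.env(parent = emptyenv())

#' Register an external plan-proposal adapter
#'
#' The adapter is a function `(text, bundle_summary) -> analysis_plan`.
#' It only ever receives the attribute-name/kind summary of the bundle —
#' never sample-level data — so the closed-system property holds regardless
#' of what the adapter does. Its output is validated by the same plan
#' invariants and every expression must parse; a failing proposal is
#' rejected and the rule-based extractor used instead.
#'
#' @param fn adapter function, or `NULL` to deregister.
#' @return invisibly, the previously registered adapter (or `NULL`).
#' @export
register_llm_adapter <- function(fn) {
  stopifnot(is.null(fn) || is.function(fn))
  old <- .adapter_env$adapter
  .adapter_env$adapter <- fn
  invisible(old)
}

#' Attribute-level summary of a bundle for external adapters
#' @param bundle a `dataset_bundle`.
#' @return data.frame of attribute names, kinds and endpoint groups only.
#' @export
bundle_summary <- function(bundle) {
  bundle$attributes[, c("name", "kind", "endpoint_group")]
}

#' Propose an analysis plan (adapter if registered, else rule-based)
#'
#' @param text free-text request.
#' @param bundle a `dataset_bundle`.
#' @return an unconfirmed `analysis_plan`; its `provenance` records whether
#'   the adapter or the rule-based extractor produced it, and
#'   `fallback_reason` (attribute) explains a rejected adapter proposal.
#' @export
propose_plan <- function(text, bundle) {
  adapter <- .adapter_env$adapter
  if (!is.null(adapter)) {
    proposal <- tryCatch({
      p <- adapter(text, bundle_summary(bundle))
      if (!inherits(p, "analysis_plan")) stop("adapter did not return an analysis_plan")
      p$expressions <- lapply(p$expressions, as_filter_expr)
      validate_plan(p, bundle)
      p$provenance <- "llm_adapter"
      p$confirmed <- FALSE
      p
    }, error = function(e) e)
    if (inherits(proposal, "analysis_plan")) return(proposal)
    plan <- extract_plan(text, bundle)
    attr(plan, "fallback_reason") <- conditionMessage(proposal)
    return(plan)
  }
  extract_plan(text, bundle)
}
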