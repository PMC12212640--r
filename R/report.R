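# Run records and report rendering. A run record ties results to the
# exact command, bundle content hash, canonical expression texts, seeds
# and software version, so that re-running the recorded command on the
# hash-identical bundle reproduces every numeric field. The core performs
# no network I/O of any kind: all inputs are local files or in-memory
# objects.

#' Create a run record
#'
#' @param command character description of the command and arguments run.
#' @param bundle the `dataset_bundle` analyzed (hashed; not stored).
#' @param plan named character vector/list of canonical expression texts
#'   and parameters describing the executed logic.
#' @param results the analysis result object(s).
#' @param seed integer seed(s) used, if any.
#' @return object of class `run_record`.
#' @export
run_record <- function(command, bundle = NULL, plan = list(), results,
                       seed = NULL) {
  structure(
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         command = command,
         bundle_hash = if (is.null(bundle)) NA_character_ else bundle_hash(bundle),
         n_samples = if (is.null(bundle)) NA_integer_ else bundle$n_samples,
         plan = plan,
         results = results,
         version = as.character(utils::packageVersion("clincohort")),
         seed = seed),
    class = "run_record"
  )
}

result_to_list <- function(x) {
  if (inherits(x, "test_result")) {
    out <- list(test_name = x$test_name, effect_label = x$effect_label,
                effect = x$effect, ci_low = x$ci_low, ci_high = x$ci_high,
                statistic = x$statistic, p_value = x$p_value,
                n_per_group = as.list(x$n_per_group), notes = x$notes)
    if (!is.null(x$table)) {
      out$table <- list(counts = as.vector(t(x$table)),
                        rows = rownames(x$table), cols = colnames(x$table))
    }
    if (!is.null(x$prevalence)) out$prevalence <- as.list(x$prevalence)
    out
  } else if (inherits(x, "survival_curve")) {
    list(times = x$times, survival = x$survival, at_risk = x$at_risk,
         n_events = x$n_events, n = x$n, n_dropped = x$n_dropped)
  } else if (inherits(x, "survival_comparison")) {
    list(endpoint = x$endpoint, logrank = result_to_list(x$logrank),
         cox = result_to_list(x$cox),
         curves = lapply(x$curves, result_to_list),
         n_dropped = x$n_dropped)
  } else if (inherits(x, "scan_report")) {
    list(target = x$target, method = x$method, alpha = x$alpha,
         n_tested = x$n_tested, n_skipped = x$n_skipped,
         rows = x$rows, skipped = x$skipped)
  } else if (is.data.frame(x)) {
    x
  } else if (is.list(x)) {
    lapply(x, result_to_list)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x) # named vectors must serialize as JSON objects, not arrays
  } else {
    x
  }
}

#' Render a run record
#'
#' Three formats: `json` is schema-stable and complete (the in-memory
#' record re-parses field-for-field); `text` mirrors clinical reporting
#' style (group percentages, effect with CI, p-value with three
#' significant figures and a `<0.001` floor); `tsv` emits survival curves
#' and scan tables for downstream plotting.
#'
#' @param record a `run_record` (or a bare result object, wrapped
#'   automatically).
#' @param format `"json"`, `"text"` or `"tsv"`.
#' @param timestamp include the wall-clock timestamp (default `TRUE`;
#'   disable for byte-identical reproducibility comparisons).
#' @return character: the rendered report (one element per line for text
#'   and tsv).
#' @export
render_report <- function(record, format = c("json", "text", "tsv"),
                          timestamp = TRUE) {
  format <- match.arg(format)
  if (!inherits(record, "run_record")) {
    record <- run_record(command = "(ad hoc)", results = record)
  }
  switch(format,
    json = {
      lst <- list(command = record$command,
                  bundle_hash = record$bundle_hash,
                  n_samples = record$n_samples,
                  plan = record$plan,
                  results = result_to_list(record$results),
                  version = record$version,
                  seed = record$seed)
      if (timestamp) lst <- c(list(timestamp = record$timestamp), lst)
      as.character(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                                    null = "null", na = "null",
                                    dataframe = "rows", pretty = TRUE))
    },
    text = render_text(record, timestamp),
    tsv = render_tsv(record$results)
  )
}

fmt_effect_line <- function(r) {
  if (r$effect_label == "none" || is.na(r$effect)) return(character())
  sprintf("%s = %.3f (95%% CI %.3f-%.3f)", r$effect_label, r$effect,
          r$ci_low, r$ci_high)
}

render_text_result <- function(r, indent = "") {
  lines <- c(paste0("test: ", r$test_name))
  if (!is.null(r$prevalence)) {
    lines <- c(lines, sprintf("in-context prevalence: %.2f%% (case) vs %.2f%% (control)",
                              r$prevalence["case"], r$prevalence["control"]))
  }
  lines <- c(lines, fmt_effect_line(r),
             sprintf("p-value: %s", format_p(r$p_value)))
  if (length(r$n_per_group)) {
    lines <- c(lines, paste0("n: ", paste(names(r$n_per_group), r$n_per_group,
                                          sep = " = ", collapse = ", ")))
  }
  if (nzchar(r$notes)) lines <- c(lines, paste0("notes: ", r$notes))
  paste0(indent, lines)
}

render_text <- function(record, timestamp = TRUE) {
  head <- c("clincohort report",
            if (timestamp) paste0("time: ", record$timestamp),
            paste0("command: ", record$command),
            if (!is.na(record$bundle_hash)) paste0("bundle: ", record$bundle_hash,
                                                   " (n = ", record$n_samples, ")"),
            if (length(record$plan)) paste0("plan ", names(record$plan), ": ",
                                            unlist(record$plan)))
  x <- record$results
  body <- if (inherits(x, "test_result")) {
    render_text_result(x)
  } else if (inherits(x, "survival_comparison")) {
    c(paste0("survival endpoint: ", x$endpoint),
      "-- log-rank --", render_text_result(x$logrank, "  "),
      "-- Cox (case vs control) --", render_text_result(x$cox, "  "))
  } else if (inherits(x, "scan_report")) {
    sig <- x$rows[x$rows$significant, , drop = FALSE]
    c(paste0("scan target: ", x$target),
      sprintf("%d attributes tested, %d skipped; %s correction at alpha = %g",
              x$n_tested, x$n_skipped, x$method, x$alpha),
      sprintf("%d significant association(s)", nrow(sig)),
      if (nrow(sig) > 0) {
        sprintf("  %s (%s): p = %s, adjusted p = %s", sig$attribute, sig$test,
                format_p(sig$p_value), format_p(sig$adjusted_p))
      },
      if (x$n_skipped > 0) {
        paste0("  skipped ", x$skipped$attribute, ": ", x$skipped$reason)
      })
  } else {
    utils::capture.output(utils::str(x))
  }
  c(head, body)
}

render_tsv <- function(x) {
  to_lines <- function(df) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(row) paste(trimws(row), collapse = "\t")))
  }
  if (inherits(x, "scan_report")) {
    to_lines(x$rows)
  } else if (inherits(x, "survival_comparison")) {
    frames <- lapply(names(x$curves), function(nm) {
      cv <- x$curves[[nm]]
      data.frame(cohort = nm, time = cv$times, survival = cv$survival,
                 at_risk = cv$at_risk, n_events = cv$n_events)
    })
    to_lines(do.call(rbind, frames))
  } else if (inherits(x, "survival_curve")) {
    to_lines(data.frame(time = x$times, survival = x$survival,
                        at_risk = x$at_risk, n_events = x$n_events))
  } else {
    stop("tsv rendering is defined for scans and survival curves only")
  }
}
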