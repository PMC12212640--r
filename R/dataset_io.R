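# Missing-value lexicon: accepted on read (case-insensitive), "NA" on write.
.missing_markers <- c("", "na", "nan")

.valid_kinds <- c("numeric", "categorical", "event_indicator", "event_time")

#' Attribute specification table
#'
#' Builds and validates the attribute index of a dataset bundle: one row per
#' analyzable attribute with its statistical kind and, for survival columns,
#' the endpoint group that pairs an event-time column with its event
#' indicator.
#'
#' @param name character vector of unique, non-empty attribute names.
#' @param kind one of `"numeric"`, `"categorical"`, `"event_indicator"`,
#'   `"event_time"` per attribute.
#' @param description free-text description per attribute (recycled).
#' @param endpoint_group optional label (e.g. `"PFS"`) linking each
#'   `event_time` attribute to exactly one `event_indicator` attribute.
#'   `NA` for non-survival attributes.
#' @return a `data.frame` with columns `name`, `kind`, `description`,
#'   `endpoint_group`.
#' @export
attribute_index <- function(name, kind, description = "", endpoint_group = NA) {
  idx <- data.frame(
    name = as.character(name),
    kind = as.character(kind),
    description = rep_len(as.character(description), length(name)),
    endpoint_group = rep_len(as.character(endpoint_group), length(name)),
    stringsAsFactors = FALSE
  )
  validate_attribute_index(idx)
  idx
}

validate_attribute_index <- function(idx) {
  stopifnot(is.data.frame(idx))
  required <- c("name", "kind", "description", "endpoint_group")
  missing_cols <- setdiff(required, names(idx))
  if (length(missing_cols) > 0) {
    stop("attribute index lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!nzchar(idx$name)) || anyNA(idx$name)) {
    stop("attribute names must be non-empty")
  }
  if (anyDuplicated(idx$name)) {
    stop("duplicate attribute name(s): ",
         paste(unique(idx$name[duplicated(idx$name)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(idx$kind), .valid_kinds)
  if (length(bad_kind) > 0) {
    stop("unknown attribute kind(s): ", paste(bad_kind, collapse = ", "),
         " (valid: ", paste(.valid_kinds, collapse = ", "), ")")
  }
  # every event_time pairs with exactly one event_indicator via endpoint_group
  surv <- idx[idx$kind %in% c("event_time", "event_indicator"), , drop = FALSE]
  if (nrow(surv) > 0) {
    if (any(is.na(surv$endpoint_group) | !nzchar(surv$endpoint_group))) {
      stop("survival attributes must carry an endpoint_group label")
    }
    for (grp in unique(surv$endpoint_group)) {
      k <- surv$kind[surv$endpoint_group == grp]
      if (sum(k == "event_time") != 1 || sum(k == "event_indicator") != 1) {
        stop("endpoint group '", grp,
             "' must pair exactly one event_time with one event_indicator")
      }
    }
  }
  invisible(idx)
}

#' Construct a dataset bundle in memory
#'
#' A bundle couples a free-text README, an attribute index
#' (see [attribute_index()]) and a rectangular sample-by-attribute table
#' whose first column holds unique sample identifiers. Columns of the table
#' absent from the index are carried but ignored by analyses.
#'
#' @param readme character scalar, free text.
#' @param attributes attribute index data.frame.
#' @param table data.frame; first column = sample identifier.
#' @return an object of class `dataset_bundle` with elements `readme`,
#'   `attributes`, `table`, `sample_id` (name of the identifier column) and
#'   `n_samples`.
#' @export
dataset_bundle <- function(readme, attributes, table) {
  validate_attribute_index(attributes)
  if (!is.data.frame(table) || ncol(table) < 2) {
    stop("table must be a data.frame with a sample-id column plus attributes")
  }
  sample_id <- names(table)[1]
  ids <- as.character(table[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample identifier(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  absent <- setdiff(attributes$name, names(table))
  if (length(absent) > 0) {
    stop("index attribute(s) absent from table: ",
         paste(absent, collapse = ", "))
  }
  table[[1]] <- ids
  # coerce columns by declared kind; categorical stays character
  for (i in seq_len(nrow(attributes))) {
    nm <- attributes$name[i]
    kd <- attributes$kind[i]
    col <- table[[nm]]
    if (kd %in% c("numeric", "event_time", "event_indicator")) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- !is.na(as.character(col)) & nzchar(trimws(as.character(col))) &
        !(tolower(trimws(as.character(col))) %in% .missing_markers) & is.na(num)
      if (any(bad)) {
        stop("attribute '", nm, "' declared ", kd,
             " but has non-numeric value(s), e.g. '",
             as.character(col)[which(bad)[1]], "'")
      }
      if (kd == "event_indicator" && !all(num[!is.na(num)] %in% c(0, 1))) {
        stop("event_indicator '", nm, "' must contain only 0, 1 or missing")
      }
      if (kd == "event_time" && any(num[!is.na(num)] < 0)) {
        stop("event_time '", nm, "' must be non-negative")
      }
      table[[nm]] <- num
    } else {
      chr <- as.character(col)
      chr[is.na(chr) | tolower(trimws(chr)) %in% .missing_markers] <- NA_character_
      table[[nm]] <- chr
    }
  }
  structure(
    list(readme = paste(as.character(readme), collapse = "\n"),
         attributes = attributes,
         table = table,
         sample_id = sample_id,
         n_samples = nrow(table)),
    class = "dataset_bundle"
  )
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("<dataset_bundle>", x$n_samples, "samples,",
      nrow(x$attributes), "indexed attributes\n")
  tab <- table(x$attributes$kind)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  eps <- endpoint_groups(x)
  if (length(eps)) cat("  survival endpoints:", paste(eps, collapse = ", "), "\n")
  invisible(x)
}

#' List survival endpoint groups of a bundle
#' @param bundle a `dataset_bundle`.
#' @return character vector of endpoint group labels.
#' @export
endpoint_groups <- function(bundle) {
  a <- bundle$attributes
  unique(a$endpoint_group[a$kind == "event_time" & !is.na(a$endpoint_group)])
}

#' Resolve an endpoint group to its (time, event) column pair
#' @param bundle a `dataset_bundle`.
#' @param endpoint_group endpoint label, e.g. `"PFS"`.
#' @return list with `time` and `event` attribute names.
#' @export
resolve_endpoint <- function(bundle, endpoint_group) {
  a <- bundle$attributes
  tm <- a$name[a$kind == "event_time" &
                 !is.na(a$endpoint_group) & a$endpoint_group == endpoint_group]
  ev <- a$name[a$kind == "event_indicator" &
                 !is.na(a$endpoint_group) & a$endpoint_group == endpoint_group]
  if (length(tm) != 1 || length(ev) != 1) {
    stop("endpoint group '", endpoint_group, "' not found in bundle index; ",
         "available: ", paste(endpoint_groups(bundle), collapse = ", "))
  }
  list(time = tm, event = ev)
}

attribute_kind <- function(bundle, name) {
  a <- bundle$attributes
  k <- a$kind[a$name == name]
  if (length(k) != 1) stop("unknown attribute: ", name)
  k
}

#' Infer the statistical kind of a raw column
#'
#' A column is `numeric` when every non-missing cell parses as a number and
#' the number of distinct values exceeds `max_levels`; otherwise it is
#' `categorical`. Binary 0/1 mutation flags therefore come out categorical,
#' which is how they are used as group labels downstream. Survival kinds are
#' never inferred; they must be declared in the index.
#'
#' @param values character (or coercible) vector of raw cells.
#' @param max_levels distinct-value threshold separating categorical from
#'   numeric (default 10).
#' @return `"numeric"` or `"categorical"`.
#' @export
infer_kind <- function(values, max_levels = 10) {
  chr <- as.character(values)
  chr[tolower(trimws(chr)) %in% .missing_markers] <- NA_character_
  obs <- chr[!is.na(chr)]
  if (length(obs) == 0) stop("cannot infer kind of an all-missing column")
  num <- suppressWarnings(as.numeric(obs))
  if (!anyNA(num) && length(unique(num)) > max_levels) "numeric" else "categorical"
}

.bundle_files <- c(readme = "README.txt", index = "index.tsv", table = "data.tsv")

#' Load a dataset bundle from a folder
#'
#' The folder must contain three files: `README.txt` (free text),
#' `index.tsv` (tab-delimited attribute index with columns `name`, `kind`,
#' `description`, `endpoint_group`) and `data.tsv` (tab-delimited data table
#' with a header row; first column = sample identifier). Attributes listed
#' in the index without a declared kind are inferred via [infer_kind()].
#' Empty cells and `NA`/`NaN` (case-insensitive) are read as missing.
#'
#' @param folder_path path to the bundle folder.
#' @param max_levels threshold passed to [infer_kind()] for undeclared kinds.
#' @return a validated `dataset_bundle`.
#' @export
load_bundle <- function(folder_path, max_levels = 10) {
  for (f in .bundle_files) {
    if (!file.exists(file.path(folder_path, f))) {
      stop("bundle at '", folder_path, "' is missing its ", f, " component")
    }
  }
  readme <- paste(readLines(file.path(folder_path, .bundle_files["readme"]),
                            warn = FALSE), collapse = "\n")
  idx <- utils::read.delim(file.path(folder_path, .bundle_files["index"]),
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  tab <- utils::read.delim(file.path(folder_path, .bundle_files["table"]),
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  if (!"endpoint_group" %in% names(idx)) idx$endpoint_group <- ""
  if (!"description" %in% names(idx)) idx$description <- ""
  idx$endpoint_group[!nzchar(idx$endpoint_group)] <- NA_character_
  # infer kinds left blank in the index
  blank <- !nzchar(trimws(idx$kind))
  for (i in which(blank)) {
    if (!idx$name[i] %in% names(tab)) next # caught by dataset_bundle()
    idx$kind[i] <- infer_kind(tab[[idx$name[i]]], max_levels = max_levels)
  }
  dataset_bundle(readme, idx[, c("name", "kind", "description", "endpoint_group")], tab)
}

fmt_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- "NA"
  }
  out
}

#' Write a dataset bundle to a folder
#'
#' Emits `README.txt`, `index.tsv` and `data.tsv` so that [load_bundle()]
#' inverts the write exactly: numeric cells are printed with 17 significant
#' digits (lossless for doubles), missing cells as `NA`, and categorical
#' values verbatim (internal spaces preserved; tabs are rejected because the
#' table is tab-delimited).
#'
#' @param bundle a `dataset_bundle`.
#' @param folder_path destination folder (created if absent).
#' @return invisibly, `folder_path`.
#' @export
write_bundle <- function(bundle, folder_path) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(folder_path, recursive = TRUE, showWarnings = FALSE)
  tryCatch({
    writeLines(bundle$readme, file.path(folder_path, .bundle_files["readme"]))
    idx <- bundle$attributes
    idx$endpoint_group[is.na(idx$endpoint_group)] <- ""
    utils::write.table(idx, file.path(folder_path, .bundle_files["index"]),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    tab <- bundle$table
    out <- as.data.frame(lapply(tab, fmt_cell), check.names = FALSE,
                         stringsAsFactors = FALSE)
    if (any(vapply(out, function(col) any(grepl("\t", col, fixed = TRUE)), logical(1)))) {
      stop("table cells may not contain tab characters")
    }
    utils::write.table(out, file.path(folder_path, .bundle_files["table"]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }, error = function(e) {
    stop("failed writing bundle to '", folder_path, "': ", conditionMessage(e))
  })
  invisible(folder_path)
}

#' Content hash of a bundle
#'
#' MD5 over the canonical on-disk serialization of the three bundle files;
#' used in run records so a report can be tied to the exact data analyzed.
#'
#' @param bundle a `dataset_bundle`.
#' @return character MD5 hex digest.
#' @export
bundle_hash <- function(bundle) {
  tmp <- tempfile("bundlehash")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write_bundle(bundle, tmp)
  files <- file.path(tmp, .bundle_files)
  digests <- tools::md5sum(files)
  cat_file <- tempfile()
  on.exit(unlink(cat_file), add = TRUE)
  writeLines(unname(digests), cat_file)
  unname(tools::md5sum(cat_file))
}
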