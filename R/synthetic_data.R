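# Synthetic clinical-genomic cohort generator. Emulates a consortium-style
# colorectal-cancer table — categorical clinical variables, binary
# per-sample mutation flags, a censored survival endpoint — with plantable
# odds-ratio and hazard-ratio effects so every analysis stage is testable
# offline. No attempt is made to model real marginal distributions or
# mutation co-occurrence; attributes are independent unless an effect is
# planted.

#' Specify a synthetic cohort
#'
#' @param n sample count.
#' @param seed integer seed; generation is fully reproducible given it.
#' @param attributes named list describing unplanted attributes. Each
#'   element is either a named numeric vector of level frequencies (sums
#'   to 1; categorical) or a list `list(dist = "normal", mean=, sd=)` /
#'   `list(dist = "uniform", min=, max=)` (numeric).
#' @param planted_or optional list `list(context=, group_attr=,
#'   group_levels=, or=, baseline=)`: the `context` binary attribute is
#'   drawn with prevalence `baseline` when the sample's `group_attr` value
#'   is outside `group_levels` and with the prevalence solving
#'   `OR = [p1/(1-p1)] / [p0/(1-p0)]` when inside.
#' @param planted_hr optional list `list(group_attr=, hr=, baseline_hazard=,
#'   censoring=, endpoint=)`: exponential event times with rate
#'   `baseline_hazard * hr^(group)` where `group` is 1 when `group_attr`
#'   equals `group_value` (default `"1"`); independent uniform censoring
#'   tuned so the expected overall censoring fraction equals `censoring`.
#' @param delimiter separator for multi-valued categorical cells (default
#'   `"|"`).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1, attributes = list(), planted_or = NULL,
                        planted_hr = NULL, delimiter = "|") {
  stopifnot(n >= 1, length(attributes) == 0 || !is.null(names(attributes)))
  for (nm in names(attributes)) {
    a <- attributes[[nm]]
    if (is.numeric(a) && !is.null(names(a))) {
      if (abs(sum(a) - 1) > 1e-8) {
        stop("level frequencies of '", nm, "' must sum to 1")
      }
    } else if (!(is.list(a) && !is.null(a$dist))) {
      stop("attribute '", nm, "' must be level frequencies or a dist spec")
    }
  }
  if (!is.null(planted_or)) {
    stopifnot(planted_or$or > 0,
              planted_or$baseline > 0, planted_or$baseline < 1)
    p1 <- plant_or_prevalence(planted_or$baseline, planted_or$or)
    if (p1 <= 0 || p1 >= 1) stop("infeasible planted prevalence: ", p1)
  }
  if (!is.null(planted_hr)) {
    stopifnot(planted_hr$hr > 0, planted_hr$baseline_hazard > 0,
              planted_hr$censoring >= 0, planted_hr$censoring < 1)
  }
  structure(list(n = n, seed = seed, attributes = attributes,
                 planted_or = planted_or, planted_hr = planted_hr,
                 delimiter = delimiter),
            class = "cohort_spec")
}

# Prevalence p1 solving OR = [p1/(1-p1)] / [p0/(1-p0)].
plant_or_prevalence <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

# Uniform(0, b) censoring bound giving expected censoring fraction `target`
# for a mixture of exponential event times with rates `rates` and mixture
# weights `w`: P(C < T) = sum_g w_g * (1 - exp(-rate_g b)) / (rate_g b).
censoring_bound <- function(rates, w, target) {
  if (target <= 0) return(Inf)
  frac <- function(b) sum(w * (1 - exp(-rates * b)) / (rates * b)) - target
  stats::uniroot(frac, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Generate a synthetic cohort bundle
#'
#' Draws the cohort described by a [cohort_spec()]: unplanted attributes
#' independently, the planted-enrichment context conditionally on its
#' grouping attribute, and the planted survival endpoint from exponential
#' event times with multiplicative hazard plus independent uniform
#' censoring. The result is a validated [dataset_bundle()] whose index
#' registers the endpoint's time and event columns under the endpoint name.
#'
#' @param spec a `cohort_spec`.
#' @return a `dataset_bundle`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n
  cols <- list(SAMPLE_ID = sprintf("S%05d", seq_len(n)))
  kinds <- character()
  descr <- character()
  epgrp <- character()
  add <- function(nm, values, kind, desc = "", ep = NA_character_) {
    cols[[nm]] <<- values
    kinds[nm] <<- kind
    descr[nm] <<- desc
    epgrp[nm] <<- ep
  }
  for (nm in names(spec$attributes)) {
    a <- spec$attributes[[nm]]
    if (is.numeric(a) && !is.null(names(a))) {
      add(nm, sample(names(a), n, replace = TRUE, prob = a), "categorical")
    } else if (a$dist == "normal") {
      add(nm, stats::rnorm(n, a$mean, a$sd), "numeric")
    } else if (a$dist == "uniform") {
      add(nm, stats::runif(n, a$min, a$max), "numeric")
    } else if (a$dist == "multi_set") {
      # multi-valued categorical: each sample gets a "|"-joined subset
      picks <- lapply(seq_len(n), function(i) {
        k <- sample(seq_along(a$sets), 1, prob = a$set_probs)
        a$sets[[k]]
      })
      add(nm, vapply(picks, paste, character(1), collapse = spec$delimiter),
          "categorical")
    } else {
      stop("unknown distribution '", a$dist, "' for attribute '", nm, "'")
    }
  }
  if (!is.null(spec$planted_or)) {
    po <- spec$planted_or
    if (!po$group_attr %in% names(cols)) {
      stop("planted_or group attribute '", po$group_attr, "' not generated")
    }
    in_group <- cols[[po$group_attr]] %in% po$group_levels
    p1 <- plant_or_prevalence(po$baseline, po$or)
    p <- ifelse(in_group, p1, po$baseline)
    add(po$context, as.character(stats::rbinom(n, 1, p)), "categorical",
        desc = "binary context flag with planted group-conditional prevalence")
  }
  if (!is.null(spec$planted_hr)) {
    ph <- spec$planted_hr
    if (!ph$group_attr %in% names(cols)) {
      stop("planted_hr group attribute '", ph$group_attr, "' not generated")
    }
    gv <- ph$group_value %||% "1"
    g <- as.integer(as.character(cols[[ph$group_attr]]) == gv)
    rate <- ph$baseline_hazard * ph$hr^g
    t_event <- stats::rexp(n, rate)
    w <- c(mean(g == 0), mean(g == 1))
    b <- censoring_bound(ph$baseline_hazard * ph$hr^c(0, 1), w, ph$censoring)
    t_cens <- if (is.finite(b)) stats::runif(n, 0, b) else rep(Inf, n)
    ep <- ph$endpoint
    add(paste0(ep, "_months"), round(pmin(t_event, t_cens), 4), "event_time",
        desc = paste0(ep, " time in months"), ep = ep)
    add(paste0(ep, "_event"), as.numeric(t_event <= t_cens), "event_indicator",
        desc = paste0(ep, " event indicator (1 = event, 0 = censored)"), ep = ep)
  }
  idx <- attribute_index(names(kinds), unname(kinds), unname(descr),
                         unname(epgrp))
  tab <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  dataset_bundle(
    readme = paste0("Synthetic clinical-genomic cohort (n = ", n,
                    ", seed = ", spec$seed, ").\n",
                    "Generated by the clincohort synthetic-cohort module; ",
                    "attributes are independent unless an effect was planted."),
    attributes = idx, table = tab)
}

#' Consortium-style colorectal-cancer preset
#'
#' Returns a [cohort_spec()] whose attribute vocabulary matches the column
#' names used in published colorectal-cancer cohort analyses — AJCC
#' pathological T stage (`TUMOR_STAGE` in T1..T4B), a multi-agent treatment
#' column (`Agent`, components joined by `"|"`, including the FOLFOX
#' regimen of fluorouracil, leucovorin and oxaliplatin), binary
#' `TP53_Mutation_status` / `KRAS_mutation_status` / `BRAF_mutation_status`
#' flags, microsatellite-instability status, age, sex and ethnicity — so
#' that published-style filter expressions parse and run unchanged against
#' the synthetic data.
#'
#' Planted effects (defaults): TP53 mutation prevalence 50% in early T
#' stage rising to the level implied by an odds ratio of 1.92 in late T
#' stage, and a progression-free-survival hazard ratio of 2.0 for
#' KRAS-mutant samples at 30% censoring.
#'
#' @param n sample count (default 5000).
#' @param seed integer seed.
#' @param planted_or planted TP53-by-stage odds ratio (default 1.92).
#' @param or_baseline early-stage TP53 prevalence (default 0.50).
#' @param planted_hr planted KRAS hazard ratio on PFS (default 2.0).
#' @param censoring expected censoring fraction (default 0.30).
#' @param baseline_hazard exponential event rate per month for KRAS
#'   wild-type samples (default 0.02, i.e. median PFS near 35 months).
#' @return a `cohort_spec`.
#' @export
tcga_like_preset <- function(n = 5000, seed = 1, planted_or = 1.92,
                             or_baseline = 0.50, planted_hr = 2.0,
                             censoring = 0.30, baseline_hazard = 0.02) {
  folfox <- c("Fluorouracil", "Leucovorin", "Oxaliplatin")
  cohort_spec(
    n = n, seed = seed,
    attributes = list(
      TUMOR_STAGE = c(T1 = 0.10, T2 = 0.15, T3 = 0.45, T4 = 0.15,
                      T4A = 0.10, T4B = 0.05),
      Agent = list(dist = "multi_set",
                   sets = list(folfox, c("Fluorouracil", "Leucovorin"),
                               "Capecitabine", c("Irinotecan", "Bevacizumab"),
                               "None"),
                   set_probs = c(0.40, 0.15, 0.15, 0.15, 0.15)),
      KRAS_mutation_status = c(`0` = 0.60, `1` = 0.40),
      BRAF_mutation_status = c(`0` = 0.90, `1` = 0.10),
      MSI_status = c(MSS = 0.85, `MSI-H` = 0.15),
      AGE = list(dist = "normal", mean = 65, sd = 11),
      SEX = c(Male = 0.53, Female = 0.47),
      ETHNICITY = c(`Non-Hispanic` = 0.85, Hispanic = 0.15)
    ),
    planted_or = list(context = "TP53_Mutation_status",
                      group_attr = "TUMOR_STAGE",
                      group_levels = c("T3", "T4", "T4A", "T4B"),
                      or = planted_or, baseline = or_baseline),
    planted_hr = list(group_attr = "KRAS_mutation_status", group_value = "1",
                      hr = planted_hr, baseline_hazard = baseline_hazard,
                      censoring = censoring, endpoint = "PFS")
  )
}
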