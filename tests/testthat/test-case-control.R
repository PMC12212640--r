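test_that("disjoint stage definitions build disjoint cohorts with zero overlap", {
  b <- toy_bundle()
  ch <- build_cohorts("TUMOR_STAGE is in {T3, T4}",
                      "TUMOR_STAGE is in {T1, T2}", b)
  expect_equal(ch$overlap, 0)
  expect_false(any(ch$case_mask & ch$control_mask))
  expect_equal(ch$n_case, sum(b$table$TUMOR_STAGE %in% c("T3", "T4")))
  expect_equal(ch$n_control, sum(b$table$TUMOR_STAGE %in% c("T1", "T2")))
})

test_that("samples satisfying both definitions are excluded from both, loudly", {
  idx <- attribute_index("Age", "numeric")
  tab <- data.frame(ID = c("a", "b"), Age = c(25, 40))
  b <- dataset_bundle("x", idx, tab)
  # 40 satisfies both definitions -> excluded; case cohort becomes empty
  expect_warning(
    expect_error(build_cohorts("Age is greater than 30",
                               "Age is greater than 20", b),
                 "empty case cohort"),
    "satisfied both")
})

test_that("cohort sizes equal the brute-force row count for random disjoint splits", {
  for (seed in 1:4) {
    b <- random_bundle(n = 60, seed = seed)
    lv <- unique(na.omit(b$table$CAT1))
    if (length(lv) < 2) next
    case_def <- paste0("CAT1 is ", lv[1])
    ctrl_def <- paste0("CAT1 is not in {", lv[1], "}")
    ch <- build_cohorts(case_def, ctrl_def, b)
    n_brute <- sum(!is.na(b$table$CAT1))
    expect_equal(ch$n_case + ch$n_control, n_brute)
  }
})

test_that("context enrichment builds the 2x2 table and reports prevalences", {
  b <- generate_cohort(tcga_like_preset(n = 5000, seed = 42))
  ch <- build_cohorts("TUMOR_STAGE is in {T3, T4, T4A, T4B}",
                      "TUMOR_STAGE is in {T1, T2}", b)
  res <- context_enrichment("TP53_Mutation_status is 1", ch, b)
  expect_equal(sum(res$table), ch$n_case + ch$n_control)
  expect_equal(unname(res$table["case", "in_context"] /
                        sum(res$table["case", ]) * 100),
               unname(res$prevalence["case"]))
  # planted enrichment (OR 1.92, baseline 50%) is detected
  expect_gt(res$effect, 1)
  expect_lt(res$p_value, 0.05)
  expect_match(res$notes, "% of cases vs")
})

test_that("context true for every sample is degenerate; swapping cohorts inverts OR", {
  b <- toy_bundle()
  ch <- build_cohorts("TUMOR_STAGE is in {T3, T4}",
                      "TUMOR_STAGE is in {T1, T2}", b)
  res_all <- context_enrichment("OS_months is greater than -1", ch, b)
  expect_true(is.na(res_all$effect))
  expect_equal(res_all$p_value, 1)

  res <- context_enrichment("TP53_Mutation_status is 1", ch, b)
  ch_swap <- build_cohorts("TUMOR_STAGE is in {T1, T2}",
                           "TUMOR_STAGE is in {T3, T4}", b)
  res_swap <- context_enrichment("TP53_Mutation_status is 1", ch_swap, b)
  expect_equal(res_swap$effect, 1 / res$effect, tolerance = 1e-12)
  expect_equal(res_swap$p_value, res$p_value, tolerance = 1e-12)
})

test_that("enrichment OR depends only on the in/out dichotomy", {
  b <- generate_cohort(tcga_like_preset(n = 800, seed = 3))
  ch <- build_cohorts("TUMOR_STAGE is in {T3, T4, T4A, T4B}",
                      "TUMOR_STAGE is in {T1, T2}", b)
  r1 <- context_enrichment("MSI_status is MSI-H", ch, b)
  # relabel the out-of-context category: same dichotomy, same table
  b2 <- b
  b2$table$MSI_status[b2$table$MSI_status == "MSS"] <- "microsatellite-stable"
  r2 <- context_enrichment("MSI_status is MSI-H", ch, b2)
  expect_equal(r2$effect, r1$effect)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("compare_variable dispatches by kind and flags constants", {
  b <- generate_cohort(tcga_like_preset(n = 600, seed = 9))
  ch <- build_cohorts("TUMOR_STAGE is in {T3, T4, T4A, T4B}",
                      "TUMOR_STAGE is in {T1, T2}", b)
  expect_equal(compare_variable("KRAS_mutation_status", ch, b)$test_name,
               "odds_ratio_fisher")
  expect_equal(compare_variable("AGE", ch, b)$test_name, "mann_whitney_u")
  # dispatch equals select_test for every plain attribute
  for (attr in setdiff(b$attributes$name[b$attributes$kind %in%
                                          c("numeric", "categorical")],
                       "TUMOR_STAGE")) {
    used <- ch$case_mask | ch$control_mask
    col <- b$table[[attr]][used]
    nl <- length(unique(col[!is.na(col)]))
    expected <- select_test(attribute_kind(b, attr), "categorical",
                            levels_x = nl, levels_y = 2)
    expect_equal(compare_variable(attr, ch, b)$test_name, expected,
                 label = attr)
  }
  b$table$CONST <- "same"
  b$attributes <- rbind(b$attributes,
                        data.frame(name = "CONST", kind = "categorical",
                                   description = "", endpoint_group = NA))
  rc <- compare_variable("CONST", ch, b)
  expect_equal(rc$test_name, "uninformative")
  expect_equal(rc$p_value, 1)
})

test_that("survival comparison couples KM curves, log-rank and Cox", {
  b <- generate_cohort(tcga_like_preset(n = 2000, seed = 12))
  ch <- build_cohorts(
    "(Agent is in {Fluorouracil, Leucovorin, Oxaliplatin}) and (KRAS_mutation_status is 1)",
    "(Agent is in {Fluorouracil, Leucovorin, Oxaliplatin}) and (KRAS_mutation_status is 0)",
    b)
  sc <- compare_survival(ch, "PFS", b)
  # curves equal km_estimate applied to each mask separately
  tcol <- b$table$PFS_months; ecol <- b$table$PFS_event
  cv_case <- km_estimate(tcol[ch$case_mask], ecol[ch$case_mask])
  expect_equal(sc$curves$case$survival, cv_case$survival)
  expect_equal(sc$curves$case$times, cv_case$times)
  # planted hazard: case (KRAS mutant) curve below control at probe times
  probes <- quantile(tcol, c(.2, .4, .6))
  expect_true(all(surv_at(sc$curves$case, probes) <
                    surv_at(sc$curves$control, probes)))
  expect_lt(sc$logrank$p_value, 0.001)
  expect_gt(sc$cox$ci_low, 1)

  # identical cohorts: log-rank p = 1
  idx <- attribute_index(c("G", "T_m", "T_e"),
                         c("categorical", "event_time", "event_indicator"),
                         endpoint_group = c(NA, "T", "T"))
  tab <- data.frame(ID = paste0("s", 1:6),
                    G = rep(c("a", "b"), each = 3),
                    T_m = rep(c(1, 2, 3), 2), T_e = rep(c(1, 0, 1), 2))
  b2 <- dataset_bundle("x", idx, tab)
  ch2 <- build_cohorts("G is a", "G is b", b2)
  sc2 <- compare_survival(ch2, "T", b2)
  expect_equal(sc2$logrank$p_value, 1)
  expect_error(compare_survival(ch2, "GHOST", b2), "endpoint group")
})
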