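test_that("intent classification follows the documented patterns", {
  expect_equal(classify_intent(
    "Do patients with KRAS mutations have different progression-free survival?"),
    "survival_comparison")
  expect_equal(classify_intent(
    "Compare survival outcomes between FOLFOX-treated patients with and without KRAS mutations in colon cancer"),
    "survival_comparison")
  expect_equal(classify_intent(
    "Is BRAF mutation linked to brain metastasis in melanoma?"), "association")
  expect_equal(classify_intent(
    "Tell me everything associated with overall survival in colon cancer"),
    "global_scan")
  expect_equal(classify_intent(
    "Find all variables associated with KRAS mutation status in the TCGA COAD dataset"),
    "global_scan")
  expect_equal(classify_intent(
    "Compare TP53 mutations in early-stage versus late-stage colorectal cancer"),
    "case_control")
  expect_equal(classify_intent("Show me the distribution of AGE"), "lookup")
  expect_equal(classify_intent("Hello"), "ambiguous")
  expect_error(classify_intent(""), "non-empty")
})

test_that("classification is deterministic on repeated calls", {
  texts <- c("Compare TP53 mutations in early versus late stage",
             "Is MSI status associated with BRAF mutation?", "Hello there")
  for (tx in texts) {
    expect_identical(classify_intent(tx), classify_intent(tx))
  }
})

test_that("plan extraction grounds gene mentions and surfaces gaps, never guesses", {
  b <- generate_cohort(tcga_like_preset(n = 200, seed = 2))
  plan <- extract_plan(
    "Compare TP53 mutations in early-stage versus late-stage colorectal cancer", b)
  expect_equal(plan$intent, "case_control")
  expect_equal(canonical_text(plan$expressions$context),
               "(TP53_Mutation_status is 1)")
  # stage sets are user-supplied: case/control stay as named gaps
  expect_true(any(grepl("case cohort", plan$gaps)))
  expect_false(plan$confirmed)

  plan2 <- extract_plan(
    "Find all variables associated with KRAS mutation status in the TCGA COAD dataset", b)
  expect_equal(plan2$intent, "global_scan")
  expect_equal(plan2$target, "KRAS_mutation_status")
  expect_length(plan2$gaps, 0)

  plan3 <- extract_plan(
    "Do patients with KRAS mutations have different progression-free survival?", b)
  expect_equal(plan3$intent, "survival_comparison")
  expect_equal(plan3$target, "PFS")
  expect_equal(canonical_text(plan3$expressions$case),
               "(KRAS_mutation_status is 1)")

  # entity absent from the bundle -> reported gap, not a guess
  plan4 <- extract_plan(
    "Find all variables associated with EGFR mutation status", b)
  expect_true(any(grepl("EGFR", plan4$gaps)))
})

test_that("extraction is deterministic given identical text and bundle", {
  b <- generate_cohort(tcga_like_preset(n = 150, seed = 4))
  tx <- "Do patients with KRAS mutations have different progression-free survival?"
  p1 <- extract_plan(tx, b)
  p2 <- extract_plan(tx, b)
  expect_identical(p1, p2)
})

test_that("execution is impossible on unconfirmed or invalid plans", {
  b <- generate_cohort(tcga_like_preset(n = 400, seed = 6))
  plan <- extract_plan(
    "Do patients with KRAS mutations have different progression-free survival?", b)
  expect_error(execute_plan(plan, b), "not confirmed")
  # a plan with gaps fails validation even if force-confirmed
  gap_plan <- extract_plan("Compare TP53 mutations in early versus late stage", b)
  expect_error(confirm_plan(gap_plan, b), "unresolved gap")
  gap_plan$confirmed <- TRUE
  expect_error(execute_plan(gap_plan, b), "unresolved gap")

  ok <- confirm_plan(plan, b)
  res <- execute_plan(ok, b)
  expect_s3_class(res, "survival_comparison")
  expect_gt(res$cox$effect, 1) # planted hazard for the mutant group
})

test_that("plan validation enforces intent-specific required fields", {
  expect_error(validate_plan(analysis_plan("case_control")), "missing 'case'")
  expect_error(validate_plan(analysis_plan("global_scan")), "missing scan target")
  expect_error(validate_plan(analysis_plan("association", target = "X")),
               "two variables")
  expect_error(validate_plan(analysis_plan("ambiguous")), "ambiguous")
  b <- toy_bundle()
  p <- analysis_plan("global_scan", target = "GHOST")
  expect_error(validate_plan(p, b), "not in bundle")
  p2 <- analysis_plan("case_control",
                      expressions = list(case = "GHOST is 1",
                                         control = "AGE is less than 60"))
  expect_error(validate_plan(p2, b), "unknown attribute")
})

test_that("adapter contract: validation, fallback, and plan equivalence", {
  b <- generate_cohort(tcga_like_preset(n = 400, seed = 8))
  withr::defer(register_llm_adapter(NULL))

  # no adapter registered: rule-based path
  p0 <- propose_plan("Compare TP53 mutations in early versus late stage", b)
  expect_equal(p0$provenance, "rule_based")

  # adapter returning garbage is rejected with fallback
  register_llm_adapter(function(text, summary) stop("model unavailable"))
  p1 <- propose_plan("Compare TP53 mutations in early versus late stage", b)
  expect_equal(p1$provenance, "rule_based")
  expect_match(attr(p1, "fallback_reason"), "model unavailable")

  # adapter returning an unparseable expression is rejected too
  register_llm_adapter(function(text, summary) {
    analysis_plan("global_scan", target = "KRAS_mutation_status",
                  expressions = list(subset = "AGE above 30"))
  })
  expect_error(register_llm_adapter, NA)
  p2 <- propose_plan("Find all variables associated with KRAS mutation status", b)
  expect_equal(p2$provenance, "rule_based")

  # a valid adapter plan executes identically to the same plan entered manually
  register_llm_adapter(function(text, summary) {
    # contract: the adapter sees attribute names/kinds only
    stopifnot(is.data.frame(summary),
              setequal(names(summary), c("name", "kind", "endpoint_group")))
    analysis_plan("survival_comparison", target = "PFS",
                  expressions = list(case = "KRAS_mutation_status is 1",
                                     control = "KRAS_mutation_status is 0"))
  })
  p3 <- propose_plan("anything", b)
  expect_equal(p3$provenance, "llm_adapter")
  res_adapter <- execute_plan(confirm_plan(p3, b), b)
  manual <- confirm_plan(
    analysis_plan("survival_comparison", target = "PFS",
                  expressions = list(case = "KRAS_mutation_status is 1",
                                     control = "KRAS_mutation_status is 0")), b)
  res_manual <- execute_plan(manual, b)
  expect_equal(res_adapter$cox$effect, res_manual$cox$effect)
  expect_equal(res_adapter$logrank$p_value, res_manual$logrank$p_value)
})

test_that("lookup and pairwise association answer directly", {
  b <- toy_bundle()
  lk <- lookup_attribute(b, "TUMOR_STAGE")
  expect_equal(sum(lk$levels), 10)
  lk2 <- lookup_attribute(b, "AGE")
  expect_equal(lk2$n_missing, 1)
  expect_equal(unname(lk2$summary["median"]),
               median(b$table$AGE, na.rm = TRUE))
  pa <- pair_association(b, "TUMOR_STAGE", "TP53_Mutation_status")
  expect_equal(pa$test_name, "chi_square") # 4 stage levels x binary flag
})
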