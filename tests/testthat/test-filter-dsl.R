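test_that("single statements parse into the documented comparisons", {
  s <- parse_statement("Age is greater than 30")
  expect_equal(s$attribute, "Age")
  expect_equal(s$operator, "GT")
  expect_equal(s$value, "30")

  s <- parse_statement("Disease stage is in {Stage I, Stage II, Stage III}")
  expect_equal(s$attribute, "Disease stage")
  expect_equal(s$operator, "IN")
  expect_equal(s$value, c("Stage I", "Stage II", "Stage III"))

  s <- parse_statement("TUMOR_STAGE is in {T3, T4, T4A, T4B}")
  expect_equal(s$value, c("T3", "T4", "T4A", "T4B"))

  s <- parse_statement("KRAS_mutation_status is 1")
  expect_equal(s$operator, "IS")
  expect_equal(s$value, "1")

  s <- parse_statement("AGE from 30 to 50")
  expect_equal(s$operator, "RANGE")
  expect_equal(s$value, c("30", "50"))

  s <- parse_statement("SEX is not Male")
  expect_equal(s$operator, "IS_NOT")

  s <- parse_statement("MSI_status is not in {MSI-H}")
  expect_equal(s$operator, "NOT_IN")
  expect_equal(s$value, "MSI-H")
})

test_that("operator keywords are case-insensitive; values keep internal spaces", {
  s <- parse_statement("Stage IS IN {Stage I,  Stage II}")
  expect_equal(s$value, c("Stage I", "Stage II"))
  s <- parse_statement("Age IS GREATER THAN 30")
  expect_equal(s$operator, "GT")
})

test_that("malformed statements are parse errors naming the offense", {
  expect_error(parse_statement("Age above 30"), "no recognized comparison")
  expect_error(parse_statement("Stage is in {}"), "empty set")
  expect_error(parse_statement("AGE from 50 to 30"), "range start exceeds end")
  expect_error(parse_expression("(Age is 1"), "unbalanced parentheses")
  expect_error(parse_expression("(Age is 1) and"), "dangling")
  expect_error(parse_expression("and (Age is 1)"), "dangling")
})

test_that("chains associate left-to-right with no and-over-or precedence", {
  e <- parse_expression(
    "(Age is greater than 30) and (Gender is male) or (ETHNICITY is Hispanic)")
  expect_s3_class(e, "filter_connective")
  expect_equal(e$op, "or")
  expect_equal(e$left$op, "and")
  expect_equal(e$right$attribute, "ETHNICITY")

  e2 <- parse_expression(
    "(Agent is in {Fluorouracil, Leucovorin, Oxaliplatin}) and (KRAS_mutation_status is 1)")
  expect_equal(e2$op, "and")
  expect_equal(e2$left$operator, "IN")
  expect_equal(e2$right$operator, "IS")

  leaf <- parse_expression("(A is 1)")
  expect_s3_class(leaf, "filter_comparison")

  e3 <- parse_expression("A is 1 and (B is 2 or C is 3)")
  expect_equal(e3$op, "and")
  expect_equal(e3$right$op, "or")
})

test_that("unparenthesized chains equal an explicit left fold (law up to length 8)", {
  withr::local_seed(42)
  for (rep in 1:40) {
    n_leaf <- sample(2:8, 1)
    leaves <- paste0("A", seq_len(n_leaf), " is ", seq_len(n_leaf))
    ops <- sample(c("and", "or"), n_leaf - 1, TRUE)
    chain <- leaves[1]
    for (i in seq_along(ops)) chain <- paste(chain, ops[i], leaves[i + 1])
    parsed <- parse_expression(chain)
    # reference fold-left built from fully parenthesized text
    ref_text <- paste0("(", leaves[1], ")")
    for (i in seq_along(ops)) {
      ref_text <- paste0("(", ref_text, " ", ops[i], " (", leaves[i + 1], "))")
    }
    ref <- parse_expression(ref_text)
    expect_true(clincohort:::expr_equal(parsed, ref))
  }
})

test_that("canonical_text re-parses to an identical tree on random trees", {
  b <- random_bundle(seed = 3)
  withr::local_seed(99)
  for (rep in 1:200) {
    e <- random_expr(b, depth = sample(0:3, 1))
    e2 <- parse_expression(canonical_text(e))
    expect_true(clincohort:::expr_equal(e, e2))
    expect_identical(canonical_text(e2), canonical_text(e))
  }
})

test_that("evaluation applies comparison semantics with missing-excludes rule", {
  b <- toy_bundle()
  # ages: 55 61 NA 70 48 66 59 72 63 50
  m <- evaluate_filter("AGE is greater than 60", b)
  expect_identical(m, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                        TRUE, FALSE))
  # negated operators also fail on missing cells
  m2 <- evaluate_filter("AGE is not 55", b)
  expect_false(m2[3])
  expect_false(evaluate_filter("AGE is not in {55}", b)[3])
  m3 <- evaluate_filter("AGE from 50 to 60", b)
  expect_identical(sum(m3), 3L) # 55, 59, 50; missing cell excluded
  # IS on numeric compares numerically ("070" == 70)
  expect_true(evaluate_filter("AGE is 070", b)[4])
})

test_that("evaluation errors on unknown attributes and kind mismatches", {
  b <- toy_bundle()
  expect_error(evaluate_filter("GHOST is 1", b), "unknown attribute")
  expect_error(evaluate_filter("TUMOR_STAGE is greater than 2", b),
               "numeric attribute")
  expect_error(evaluate_filter("TUMOR_STAGE from 1 to 2", b), "numeric")
  expect_error(evaluate_filter("AGE is greater than ten", b), "non-numeric")
})

test_that("string matching is case-sensitive by default with a fold option", {
  b <- toy_bundle()
  expect_equal(sum(evaluate_filter("TUMOR_STAGE is t1", b)), 0)
  expect_equal(sum(evaluate_filter("TUMOR_STAGE is t1", b, case_fold = TRUE)), 3)
})

test_that("multi-valued cells match set membership through the delimiter", {
  idx <- attribute_index("Agent", "categorical")
  tab <- data.frame(ID = c("a", "b", "c"),
                    Agent = c("Fluorouracil|Leucovorin|Oxaliplatin",
                              "Capecitabine", NA))
  b <- dataset_bundle("x", idx, tab)
  m <- evaluate_filter("Agent is in {Fluorouracil, Leucovorin, Oxaliplatin}", b)
  expect_identical(m, c(TRUE, FALSE, FALSE))
  m2 <- evaluate_filter("Agent is not in {Capecitabine}", b)
  expect_identical(m2, c(TRUE, FALSE, FALSE))
})

test_that("random expressions equal the row-wise brute-force interpreter", {
  for (seed in 1:6) {
    b <- random_bundle(n = 50, seed = seed, miss_rate = 0.15)
    withr::local_seed(seed + 100)
    for (rep in 1:25) {
      e <- random_expr(b, depth = sample(0:3, 1))
      expect_identical(evaluate_filter(e, b), brute_eval(e, b),
                       label = canonical_text(e))
    }
  }
})

test_that("mask monotonicity: AND narrows, OR widens", {
  b <- random_bundle(n = 60, seed = 8)
  withr::local_seed(77)
  for (rep in 1:30) {
    e1 <- random_expr(b, 1); e2 <- random_expr(b, 1)
    conj <- evaluate_filter(parse_expression(
      paste0(canonical_text(e1), " and ", canonical_text(e2))), b)
    disj <- evaluate_filter(parse_expression(
      paste0(canonical_text(e1), " or ", canonical_text(e2))), b)
    m1 <- evaluate_filter(e1, b); m2 <- evaluate_filter(e2, b)
    expect_true(all(conj <= m1) && all(conj <= m2))
    expect_true(all(disj >= m1) && all(disj >= m2))
  }
})
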