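---
title: "Methods: cohort definition and autonomous association analysis with clincohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort definition and autonomous association analysis with clincohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clincohort)
```

## The problem

Integrated clinical–genomic tables — a few thousand tumor samples with
categorical clinical variables (stage, sex, treatment agents), per-sample
binary mutation flags, and censored survival endpoints — are the working
substrate of much precision-oncology research. The recurring analyses on
such tables are few and standard: define two cohorts by clinical criteria,
ask whether a condition is enriched in one versus the other (odds ratio),
compare survival between them (Kaplan–Meier, log-rank, hazard ratio), or
scan every available variable against a target with multiplicity control.
`clincohort` packages exactly that repertoire behind a deterministic,
fully offline engine: a filter grammar for cohort definition, automatic
test selection by variable kind, and reproducible machine-readable
reports. A rule-based natural-language front-end can draft analysis plans,
and a validated adapter contract lets an external language model substitute
for the rules without ever seeing sample-level data.

## The dataset bundle

A dataset is a folder of three plain-text files: `README.txt` (free text),
`index.tsv` (the attributes available for analysis: `name`, `kind`,
`description`, `endpoint_group`), and `data.tsv` (samples as rows,
attributes as columns, first column the sample identifier). Four
statistical kinds exist: `numeric`, `categorical`, and the survival pair
`event_time` / `event_indicator`, linked by an `endpoint_group` label such
as `"PFS"` so survival endpoints are addressed by name rather than by
column pair. Kinds left blank in the index are inferred: a column whose
non-missing cells all parse as numbers is `numeric` only when it has more
than `max_levels = 10` distinct values; otherwise it is `categorical`.
The threshold exists so binary 0/1 mutation flags are treated as group
labels, which is how they are used. Survival kinds are never inferred;
they must be declared. On read, empty cells and `NA`/`NaN`
(case-insensitive) are missing; on write the marker is `NA` and numeric
cells are printed with 17 significant digits, so write-then-load is the
identity (a tested invariant).

## The filter grammar

A statement is attribute, comparison operator, value: `is`, `is not`,
`is greater than`, `is less than`, `from X to Y` (inclusive on both
endpoints), `is in {a, b, c}`, `is not in {...}`. Statements joined by
`and`/`or` are evaluated **strictly left to right**: `A and B or C` means
`(A and B) or C`. This deliberately departs from conventional
AND-over-OR precedence; positional evaluation is what the grammar
specifies, and nested parentheses override it. Parentheses around single
statements are accepted but not required.

Three semantic choices matter for counts and are therefore stated
prominently:

* **Missing cells fail every comparison**, including the negated operators
  `is not` and `is not in`. A sample with unknown stage is in neither the
  early- nor the late-stage cohort. This keeps cohort definitions
  conservative.
* String comparison is **case-sensitive** after whitespace trimming
  (`T4A` ≠ `t4a`); `case_fold = TRUE` opts into folding. Clinical codes
  are conventionally case-normalized upstream; exactness is the safer
  default.
* Multi-valued categorical cells (a treatment column such as
  `Fluorouracil|Leucovorin|Oxaliplatin`) match `is in` when **any** listed
  component is in the set; the delimiter (default `"|"`) is an argument of
  `evaluate_filter()`.

`canonical_text()` renders any parsed tree fully parenthesized such that
re-parsing reproduces the tree exactly; reports always record canonical
text, so the executed logic is unambiguous.

## Statistical engine

Test selection is a single data-driven table over variable kinds:
binary × binary categorical → odds-ratio/Fisher; other categorical pairs →
Pearson chi-square of independence; numeric × 2-level grouping →
Mann–Whitney U; numeric × k-level → Kruskal–Wallis; numeric × numeric →
Spearman; anything × survival endpoint → log-rank, with numeric variables
dichotomized at the median. Nonparametric defaults were chosen over
t-test/Pearson because clinical variables are routinely non-normal and the
engine has no normality-checking subsystem. All tests are two-sided with
fixed 95% intervals; the significance level `alpha` only enters reporting.

The contingency path reports the cross-product odds ratio
$\mathrm{OR} = ad/bc$ with the Haldane–Anscombe correction (+0.5 on every
cell) whenever any cell is zero, a Wald interval
$\exp(\log \mathrm{OR} \pm 1.96\,\sqrt{1/a+1/b+1/c+1/d})$ on the corrected
cells, and a two-sided Fisher exact p-value computed by hypergeometric
enumeration of the uncorrected counts (tables with probability at most
that of the observed one, with a $1+10^{-7}$ relative tie tolerance). A
2×2 table reached through the chi-square path is re-routed to the exact
test when any expected count is below 5. Tables with an all-zero margin
are degenerate: undefined effect, p = 1, flagged in notes rather than
raised.

Survival uses the product-limit estimator
$\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ over distinct event times,
the standard two-group log-rank statistic
$(\sum O_1 - E_1)^2 / \sum V$ with the hypergeometric variance at each
event time, and a single-binary-covariate Cox model maximizing the
**Breslow** tie-approximation partial likelihood by safeguarded
Newton–Raphson (step-halving on likelihood decrease, score tolerance
$10^{-8}$, 100 iterations). Breslow ties were chosen as the simplest
standard convention so results are reproducible bit for bit; the test
suite verifies agreement with `survival::coxph(ties = "breslow")` and the
analytic identity that the score at $\beta = 0$ equals the log-rank
$O - E$. Complete separation (all events in one group) is a monotone
likelihood: the result is flagged with an infinite confidence bound
instead of iterating to overflow. Survival comparisons report both the
log-rank p and the Cox Wald p, since either convention is defensible and
the consumer can choose.

## Case–control analyses

`build_cohorts()` evaluates the case and control definitions and excludes
samples satisfying **both** from **both** cohorts, with a warning carrying
the count — silently double-counting shared samples would corrupt the 2×2
enrichment table. Samples matching neither definition are simply unused;
there is no background cohort. `context_enrichment()` forms the
case/control × in-context/out-of-context table and reports the odds ratio
with per-cohort in-context percentages; only the in/out dichotomy matters
(a tested invariant), and swapping case with control inverts the odds
ratio while preserving the p-value exactly.

## Global scans

`scan_associations()` tests every index attribute except the target (and
any endpoint's time/event columns) and corrects the completed tests with
Benjamini–Hochberg FDR by default (`bonferroni` and `none` are switches).
FDR was chosen because a variable scan is exploratory; the familywise
methods are available where a stricter claim is wanted. Attributes that
cannot be tested — constant, all-missing, or with a level observed fewer
than `min_level_n = 5` times (which would let degenerate Fisher tables
dominate the ranking) — are skipped with explicit reasons, never silently
dropped. Rows sort by adjusted p, ties by raw p, then attribute name, a
deterministic total order independent of column storage order. For
multi-level categorical attributes against a survival endpoint the scan
uses the k-group log-rank test from the `survival` package; the two-group
test is the package's own.

## Natural-language front-end

`classify_intent()` is a fixed cascade of keyword patterns mapping text to
one of five intents (survival comparison, case-control, association,
global scan, lookup) or to an explicit `ambiguous` outcome — never a
silent guess. `extract_plan()` grounds entities against the bundle
vocabulary by exact, then case-insensitive, name match; `"<GENE>
mutations"` maps to a `<GENE>_mutation_status` column when one exists.
Fuzzy matching (edit distance 1) exists behind a flag and is off by
default, because silently fuzzy-matching clinical column names is a
correctness hazard. Anything that cannot be grounded becomes an open
question (`gaps`) on the plan, and a plan cannot execute until it
validates and is explicitly confirmed (`confirm_plan()` →
`execute_plan()`).

An external language model can replace the rule-based extractor through
`register_llm_adapter()`. The adapter receives only the attribute
name/kind summary — never sample-level data — so the closed-system
property is structural, not behavioral. Its proposals pass the same
validation (intent invariants, expression parsing, attribute existence);
a failing proposal is rejected with diagnostics and the rule-based path
used instead. The core never performs network I/O of any kind.

## Synthetic cohorts and what they show

`generate_cohort()` draws independent attributes plus up to two planted
effects. A planted odds ratio is realized by group-conditional Bernoulli
prevalences: given baseline $p_0$ and target OR, the enriched prevalence
is $p_1 = \mathrm{odds}_1/(1+\mathrm{odds}_1)$ with $\mathrm{odds}_1 =
\mathrm{OR}\cdot p_0/(1-p_0)$. A planted hazard ratio is realized by
exponential event times with rate $\lambda \cdot \mathrm{HR}^{g}$ and
independent uniform censoring whose upper bound is solved numerically so
the expected censoring fraction matches the request. The exponential
model satisfies proportional hazards exactly, which makes Cox recovery a
fair test of the estimator rather than of model misspecification.

`tcga_like_preset()` reproduces the attribute vocabulary of published
colorectal-cancer cohort analyses (`TUMOR_STAGE` in T1–T4B, a `|`-joined
`Agent` column including the FOLFOX regimen, binary TP53/KRAS/BRAF
mutation flags, MSI status, age, sex, ethnicity, a `PFS` endpoint), so
published-style filter expressions parse and run unchanged. Its defaults
are the package's study conditions: TP53 enrichment with baseline
prevalence 0.50 and OR 1.92 in late T stage (implying an enriched
prevalence near 65.8%), and a KRAS PFS hazard ratio of 2.0 at 30%
censoring with baseline hazard 0.02/month (median PFS near 35 months for
wild-type, a realistic figure for metastatic colorectal cohorts).

What passing tests on such data do and do not show: the generator draws
attributes independently, so it exercises estimator correctness, error
control, and pipeline plumbing — it does not model real marginal
distributions, clinical-variable linkage, or mutation co-occurrence, and
recovery on it says nothing about confounding in real cohorts. The
shipped `inst/extdata/crc_demo_synthetic` bundle is likewise entirely
simulated, constructed so the stage-wise TP53 prevalences are exactly
65.77% and 50.0% for the worked examples.

## Numerical choices and problem sizes

Tolerances: Cox Newton score tolerance $10^{-8}$; Fisher tie tolerance
$1+10^{-7}$ relative; write/read numeric round-trip via `%.17g`. Ties in
survival times: Breslow. Degenerate inputs (zero margins, constant
variables, no events, complete separation) return flagged results or
named errors rather than crashes; the policy per case is in the function
documentation. The validation suite sizes its simulations to run on one
CPU in minutes: exhaustive Fisher enumeration over all 2×2 tables with
total ≤ 40; planted-OR recovery at n = 5,000 and planted-HR recovery at
n = 2,000; generator convergence at n = 50,000 within 5% relative error;
global-null error control over 200 replicate scans of 50 attributes ×
500 samples; log-rank null uniformity over 1,000 replicates of n = 100.

## Known limitations

No multivariable or stratified Cox, no competing risks, no matching or
propensity scores, no interaction scans. Mutation status must arrive
pre-flattened to per-sample binary columns (no MAF/VCF parsing). Missing
data are excluded, never imputed. The grammar has no unary `not`. The
rule-based front-end handles the documented phrasings, not free
paraphrase — that is exactly the gap the adapter contract exists for.
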