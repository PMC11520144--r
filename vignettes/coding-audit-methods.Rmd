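---
title: "Auditing ICD omissions and DRG severity modifiers from structured EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ICD omissions and DRG severity modifiers from structured EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgaudit)
```

## The problem

Inpatient claims are built from ICD-10 diagnosis codes assigned by medical
coders after discharge. High-acuity secondary diagnoses justify DRG
severity modifiers — a Comorbid Condition (CC) or Major Comorbid Condition
(MCC) tier — which move the admission to a higher-weighted DRG and hence
higher reimbursement. When a clinically present comorbidity never makes it
into the coded chart, the claim may be billed at too low a severity tier.

`drgaudit` implements a rule-in audit of this gap from raw structured EHR
extracts, with four stages:

1. **Computable phenotyping.** Nineteen deterministic disease algorithms
   (twelve CC-level, seven MCC-level) are evaluated per hospitalization
   encounter against labs, cultures, flowsheets, medication events and
   procedure logs. Each admission is flagged as having or not having each
   disease, with the satisfying records retained as evidence.
2. **ICD omission flagging.** An admission with clinical evidence of a
   disease whose billed code list matches none of that disease's
   qualifying ICD patterns is flagged as *missing applicable ICD data*.
   The converse cell — a qualifying code present without algorithmic
   evidence — is tabulated as the algorithm-not-sensitive column.
3. **DRG upgrade evaluation.** The billed DRG's text description is parsed
   into a severity tier and a modifier-stripped family. If the highest
   modifier level across detected diseases exceeds the billed tier, the
   admission receives a single upgrade flag (base→CC, base→MCC or CC→MCC)
   targeting the family entry at the required level.
4. **Valuation and statistics.** The relative-weighting-factor (RWF) delta
   between billed and proposed DRG is valued under a payor-stratified
   dollars-per-RWF schedule, and coding accuracy is compared across
   demographic groups with exact binomial intervals, standardized mean
   differences (SMD) and reference-group tests.

## The rulebook and its thresholds

`build_rulebook()` returns the nineteen algorithms with their qualifying
ICD patterns. All tunable operands live in `default_thresholds()` (units
in parentheses, inequality strictness as stated): arterial pH < 7.35;
at least two positive blood cultures; intraoperative blood loss ≥ 300 mL
with hemoglobin < 12 g/dL within 24 h after the surgery; ejection fraction
≤ 30 %, BNP > 900 pg/mL or a heart-failure problem-list entry within
365 days; MDRD eGFR ≤ 30 mL/min/1.73m²; a positive CAM screen; BMI > 40 or
< 19; a historic positive HIV screen or active zidovudine order; sodium
≤ 134 mmol/L; a positive troponin; transplant history or tacrolimus
administration; urine culture ≥ 100,000 CFU/mL; positive troponin plus a
coronary stent; amylase > 1000 U/L or lipase > 450 U/L; GCS ≤ 8; dialysis
flow documentation; inpatient death; an endotracheal tube or HFNC with no
surgery during the index admission; and TPN documentation.

Boundary semantics follow the rule text literally and each boundary is
unit-tested on both sides. Design choices made where the rules are
genuinely open:

* **"Positive troponin"** has no universal numeric cutoff (assays differ),
  so the default uses the lab's `abnormal_flag == "positive"`; a numeric
  threshold is available via `troponin_threshold`.
* **Lookback windows.** "Within the 12 months prior to admission" is a
  fixed 365-day window ending at admission, inclusive at both ends, and
  the index admission's own results also count (a BNP resulted during the
  stay is evidence of the same chronic condition). HIV screens and
  transplant history use all-time patient history — no window is stated
  for "historic".
* **Post-operative anemia** anchors on the record carrying the blood-loss
  observation (taken as the surgery end) and scans hemoglobins in
  `(anchor, anchor + 24 h]`, same encounter. Day offsets are fractional
  throughout so the 24-hour logic is exact.
* **Hyponatremia** reads the serum sodium analyte; the rule's qualifying
  code (E87.1) and name make the intended analyte unambiguous.
* **The death rule** has no qualifying ICD list: it participates in DRG
  upgrade evaluation (it is MCC-level) but is exempt from omission
  statistics.
* Records with a missing numeric value for a thresholded analyte are
  skipped, never treated as satisfying.

## DRG parsing and upgrade targeting

Severity tiers come from a terminal-suffix grammar over catalogue
descriptions: `WITH MCC` → MCC, `WITH CC` → CC, any `WITHOUT …` arm →
Base, `WITH CC/MCC` → the doublet arm. A description with no recognized
suffix is a Singlet unless tier-suffixed siblings share its stripped
family, in which case it is the family's Base arm. Singlet DRGs are never
considered for modification.

Doublet arms are deliberately asymmetric: billed, a `CC/MCC` arm already
satisfies CC (no CC-level upgrade is proposed against it); as a target, it
satisfies MCC (an MCC-worthy disease can upgrade a doublet Base into it).
This is the most conservative reading that still permits the partial
modification doublets allow. When a family lacks the required tier the
audit falls back to the highest tier the family offers above the billed
one — reassignment across families would require grouper logic that is out
of scope — and when none exists, no flag is raised. Redundancy across
diseases is eliminated by taking the maximum required level, so an
admission carries at most one upgrade flag.

ICD matching is literal for plain codes and root-plus-children for
wildcard patterns (`"I50.*"` matches `I50` and `I50.9`, never `I509` or a
sibling root); children-only matching is available behind a flag.

## Revenue model

Payors consolidate to three classes (Medicare incl. Medicare Advantage;
Medi-Cal incl. Medicaid; everything else private) with shipped 2019
dollars-per-RWF estimates of \$10,000 / \$7,500 / \$20,000. These are
estimates, and all derived dollars are labelled as such. Currency
arithmetic rounds half-up at the line level in exact cents
(`round_half_up()`), because line-level half-up rounding is what makes the
per-cell products, the per-type subtotals (printed to the nearest dollar)
and the grand total mutually consistent; base R's round-half-even does
not. Scaling all rates by a constant scales every dollar figure by the
same constant.

## Statistics

* **Incidence intervals** are exact Clopper–Pearson by default (the
  beta-quantile closed form, identical to `binom.test`), matching a
  "binomial distribution" interval prescription; Wilson is available
  behind `method = "wilson"`.
* **Binary SMD** is `|p1 − p2| / sqrt((p1(1−p1) + p2(1−p2))/2)`.
* **Multi-category SMD** uses the Mahalanobis-type generalization over the
  first K−1 category proportions with the average of the two groups'
  multinomial covariances — the standard formulation in the
  covariate-balance literature. It reduces exactly to the binary form for
  two categories and is invariant to category order. Only the binary form
  has a published reference value to reproduce.
* **Reference-group tests** are Pearson chi-square without continuity
  correction (large-sample setting; Fisher's exact is switchable for
  small tables). Reference categories: Caucasian–Non-Hispanic, private
  payors, the 36–64 age band; p-values are reported raw, without
  multiplicity correction.
* **Audit-table percentages**: the missing-ICD and inadequate-DRG columns
  are percentages of the detected count. The not-sensitive column uses
  the *coded* set (admissions bearing a qualifying code) as denominator by
  default, because detected-count percentages are incoherent for that
  cell when coded admissions far outnumber detected ones; the
  detected-denominator convention is available via
  `not_sensitive_denominator = "detected"`.

## The synthetic cohort generator

No real EHR data ship with the package. `generate_cohort()` emulates the
structure the audit consumes, with a latent truth table
(`truth_table()`) the pipeline must reproduce exactly:

* Disease states are drawn independently per admission from per-disease
  prevalences; defaults (see `default_disease_rates()`) emulate the
  disease-frequency structure of a large academic-center inpatient year —
  common laboratory phenotypes (hyponatremia ~29 %) through rare
  procedure-defined ones (acute MI < 0.1 %), with matching per-disease
  omission and not-sensitive rates, a 10.8 % Singlet share, and an urban
  tertiary-center payor/sex/race/age mix.
* Two consistency reconciliations are forced at draw time and recorded as
  drawn: acute MI implies myocardial injury (they share the troponin
  criterion), and blood-loss anemia suppresses respiratory failure (whose
  rule demands a surgery-free admission).
* For each true disease, rule-satisfying records are injected with values
  drawn *just past* the threshold (e.g. pH uniform on (7.20, 7.349) for
  positives, (7.36, 7.45) for negatives), which stresses boundary
  handling. Negative admissions receive safe-side records only — including
  adversarial near-misses such as a single positive blood culture, a
  stent without a positive troponin, or airway support paired with a
  surgery.
* Qualifying codes are emitted with probability one minus the omission
  rate; billed DRGs sit at or below the required tier under an
  under-coding scheme (one step below with probability `u = 0.3`, two
  steps with `u²/2`, else at level), which exposes all three upgrade
  types.

What passing tests on this data do and do not show: the generator is
noiseless and rule-aligned by construction, so perfect truth recovery
demonstrates the *pipeline's* correctness, not the clinical accuracy of
the algorithms on real charts — real data carry unit mismatches,
free-text leakage, contradictory documentation and treatment-eligibility
subtleties the generator deliberately does not model.

## Numerical and testing choices

Problem sizes were chosen to exercise each property at adequate power
while keeping the default test run fast: the end-to-end oracle runs at
n = 500; brute-force equivalence uses 100 random mini-cohorts (≤ 20
admissions) against an independently written re-scanning evaluator and
100 random mini-catalogues against an exhaustive target search;
statistical recovery uses one n = 5,000 cohort with a Bonferroni-adjusted
simultaneous 99 % exact-binomial band across the 18 ICD-listed diseases
(testing 18 rates at a marginal 99 % level would fail by chance alone in
roughly one run in six); and Clopper–Pearson coverage is estimated over
200 seeded replicates of n = 120, asserting coverage at or above ~95 % as
the exact interval's conservatism implies.

De-identification replaces identifiers with salted SHA-256 hashes and
re-bases every timestamp on the patient's first recorded event, in
fractional days; within-patient intervals, orderings and join structure
are preserved exactly, and validation results are unchanged.

## Known limitations

Downward ("rule-out") auditing is out of scope by design — the algorithms
only rule in. DRG-specific exclusions (e.g. obesity implied by a
bariatric-surgery DRG) are not modelled. Clinical presence does not imply
billing eligibility: a detected disease still needs provider
documentation and management to be codeable, so flagged admissions are
candidates for human review, not automatic claims. The dollars-per-RWF
rates are estimates that ignore contract-level variation and inflation.
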