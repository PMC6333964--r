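---
title: "Extracting time-point structure from series metadata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting time-point structure from series metadata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timegeo)
```

## The problem

Public gene-expression repositories describe each deposited series in free
text: a title, a summary, an overall-design paragraph, and one short title
per sample. Whether a series is a time course — and over how many distinct
time points — is almost never a structured field, yet it is the first
question anyone reusing the data for expression-dynamics analysis has to
answer. timegeo extracts that answer with deterministic rules, annotates
each series with Disease Ontology (DO) terms, and writes a restructured,
queryable record per series.

Rules rather than a learned model are a deliberate choice: the extraction
must be auditable (every count is justified by verbatim evidence spans),
deterministic, and runnable over hundreds of thousands of records with no
training data.

## The extraction model

Four scenarios are evaluated independently for every non-excluded series:

1. **EXPLICIT** — a stated count: "12 time points", "7 developmental
   stages", "three phases". Numerals and number words one–twenty are
   accepted. Larger number words are rare enough in practice that parsing
   them would add complexity without measurable benefit.
2. **LISTING** — an enumeration of time values in the summary or overall
   design. Three shapes are recognized: a strictly ascending run of
   numerals with one unit written before or after it ("days 1, 3, 5";
   "0, 0.25, 1, 3, 6, and 24 h"), several such runs joined in one
   sentence ("6, 12 hours and 1, 3, 5 days"), and runs where every
   numeral carries its own unit ("4 min, 8 min, 9 min"), which must be
   non-decreasing after unit conversion. The count is the number of
   *distinct canonical* values in the union of accepted runs.
3. **APPROXIMATE** — qualitative phrases from a fixed lexicon
   ({early, middle, late, terminal} × {stage, phase, age, time point}).
   These flag temporal structure but never produce a numeric count; there
   is no defensible mapping from "early and late stage" to a number.
4. **SAMPLE_TITLES** — number+unit tokens in sample titles ("day 1",
   "d3", "10h"), validated by the three rules below.

The ascending requirement on shared-unit runs is what separates a time
listing from arbitrary number runs ("3, 5, 8 mice" has no unit; "12, 6,
3 hours" is rejected as descending). It is checked on the raw magnitudes
within each run, not globally across runs: in "6, 12 hours and 1, 3, 5
days" each run ascends on its own, which is how authors actually write
multi-unit listings.

### Unit canonicalization

All temporal magnitudes are converted to hours: second 1/3600, minute
1/60, hour 1, day 24, week 168, month 720, year 8760. Months and years
have no exact duration; 30-day months and 365-day years are fixed so that
identical inputs always produce identical outputs. Stage/passage ordinals
("passage 3") carry no duration: they compare by magnitude and never
merge with temporal values. Two temporal values are the *same time point*
when their canonical hours agree within a relative tolerance of 1e-9 —
tight enough that only genuine unit identities (24 h = 1 day, 0 h = 0
days) collapse, loose enough to absorb binary floating-point
representation of decimals like 0.25.

### Sample-title validation rules

Sample titles are the noisiest source: a matched token such as "45y" may
be a patient age, and "d2" may be a donor code. Candidates with
single-letter units (`s h d w m y`) are therefore only trusted after
three rules; full-word units ("day 3", "10 hr") are trusted as written.

* **Rule i.** If any single-letter candidate magnitude also occurs within
  a two-token window of *sample(s)/patient(s)/subject(s)* in the summary
  or overall design, the entire single-letter set is discarded — the
  number is a cohort size echoed into the titles. The window of two
  tokens covers the common phrasings ("45 patients", "patients (n = 45)")
  without reaching across clause boundaries; both the window and the
  keyword vocabulary are configurable.
* **Rule ii.** For single-letter candidates at a fixed character offset
  within their titles, any *other* title carrying a letter outside the
  time-unit alphabet at that same offset disqualifies the slot: a grid of
  `d1/d3/x9` means the letter position encodes an arbitrary condition
  code, not a unit.
* **Rule iii.** Real sampling grids are regular. If the surviving
  candidate set has three or more distinct canonical values, some three
  of them must form an arithmetic or geometric progression (relative
  tolerance 1e-6); otherwise all candidates are rejected. Sets of one or
  two values pass vacuously, since any two points are trivially both AP
  and GP.

Every rejection is recorded with its rule identifier and the verbatim
span, so a curator can audit why a candidate was discarded.

The progression check is implemented exactly: a subset of size ≥ 3 in
arithmetic (or geometric) progression exists if and only if some
*three-element* subset is one — any longer progression contains its first
three sorted terms — so scanning all three-element subsets decides the
question for every set size without heuristics. The test suite verifies
agreement with exhaustive enumeration over all subsets for sets up to
size eight.

### Resolution: err by excess

When scenarios disagree, the **maximum** count wins. For the downstream
use case — filtering series by a minimum number of time points — a false
extra time point is cheap (the analyst discards the series on inspection)
while a missed one hides usable data permanently. Maximum is the smallest
resolution policy with that property. Ties are broken by scenario
precedence EXPLICIT > LISTING > SAMPLE_TITLES (statements of intent are
more reliable than mined tokens), then field precedence summary >
overall_design. A series with no counted call resolves to a single time
point: a study that never mentions time was measured once. Super-series
(bundles of sub-series, detected from the type field or the standard
summary boilerplate) are excluded from detection entirely and resolve to
count 0; they are still disease-tagged.

A known, accepted failure mode follows directly from the design: short
treatment durations written as listings ("latency lengths of 4 min,
8 min, 9 min...") are indistinguishable from sampling times at the level
of these rules and inflate the count. The engine reproduces this error
deliberately rather than special-casing minute-valued listings, which
would suppress genuine minute-scale time courses.

## Disease tagging

Series are annotated against a Disease Ontology OBO file with a
dictionary matcher over term names and EXACT/RELATED synonyms: greedy
longest-match over word boundaries, case-insensitive, plural-tolerant,
with surface forms shorter than three characters excluded and a small
stop-word list that can never match alone. This is the package's core
simplification relative to full concept-mapping engines (UMLS-based
MetaMap-style systems): no word-sense disambiguation, no negation
detection, no fuzzy matching (configurable off by default, and off). The
trade-off is deliberate — the target vocabulary *is* the DO surface
vocabulary, so dictionary matching against it is the faithful
self-contained reduction, and every emitted tag is justified by a
verbatim span.

Each tag carries hierarchy metrics — leaf status, shortest `is_a`
distance from the root "disease" term, obsolete flag — so that a query
for a non-leaf disease can be answered by descendant closure: a search
for "viral infectious disease" returns series tagged with "influenza" or
"swine influenza". A miniature hand-assembled DO snapshot (26 terms,
real DOIDs, heavily pruned hierarchy) ships with the package for tests
and examples; production use supplies the full `doid.obo`.

## The synthetic corpus

Extraction accuracy cannot be measured without ground truth, and curated
truth for real repository series cannot be redistributed. The generator
therefore fabricates series whose truth is known *by construction*:

* **Strata.** True counts are drawn per stratum — 1, 2–7 (uniform), or
  >7 (uniform on 8–15) — with default weights 159/200, 33/200, 8/200 at
  n = 200, mirroring the composition of a manually curated 200-series
  benchmark in which single-time-point studies dominate.
* **Scenarios.** Multi-time-point series render their (AP or GP,
  integer-magnitude, single-unit) time grid through an explicit
  statement, a listing sentence, a sample-title grid
  (`cond d1 rep1 ...`), or explicit+listing combined.
* **Confounders**, each injected independently at a default rate of
  0.10 per series (a realistic contamination level; the defaults were
  fixed before any accuracy was measured and are not tuned):
  * *patient-age-in-title* — ages appended to sample titles, the classic
    age-mistaken-for-time failure;
  * *latency-duration-in-text* — a minute-valued duration listing in the
    summary, the over-count failure described above;
  * *sample-count-echo* — the cohort size stated in the summary, which
    can trigger rule i against legitimate title candidates.

The corpus emulates the *statistical shape* of repository metadata —
where time information appears, in which phrasings, and what the common
confounders are. It does not model real vocabulary diversity, grammatical
errors, multi-treatment designs, or calendar dates; perfect recovery on
the confounder-free corpus therefore shows the engine covers its declared
grammar, not that it would score the same on real curated series.

Generation is fully determined by the spec's seed (integer draws from
fixed grids), so corpora are byte-identical across platforms.

## Evaluation

Predictions are scored exactly and within ±1 time point — the tolerance
exists because even two human curators frequently disagree by one on
whether the baseline measurement counts as a time point. Error rates are
stratified by true count (1, 2–7, ≥ 8; "more than 7" means ≥ 8).
Excluded super-series are dropped from scoring by the caller, with the
mismatch check refusing silently missing predictions.

## Problem sizes and numerical choices

The shipped tests run the full default corpus (200 series) twice (with
and without confounders), check the listing extractor against an
independent brute-force enumerator on 1000 grammar-generated sentences
plus 100 more for the count/values invariant, verify the progression
check against exhaustive subset enumeration on 500 random sets of size
≤ 8, and enumerate all root paths of the packaged ontology. All
tolerances (1e-9 dedupe, 1e-6 progression) and the rule-i window (2
tokens) are the documented defaults in
`inst/extdata/default-config.yaml` and were chosen as described above,
not fitted.

## Known limitations

* No full temporal-expression normalization: calendar dates, relative
  dates and fractions ("1/2 hour") are not parsed; ranges contribute
  only their endpoints.
* Number words above twenty are not recognized in explicit statements.
* The minutes-vs-hours listing confusion is retained by design (see
  above).
* Grouping samples by patient or treatment — which could separate
  per-subject ages from shared time grids — is out of scope: sample
  titles carry no reliable grouping structure.
* Dictionary disease tagging inherits dictionary blind spots: no
  abbreviation expansion beyond shipped synonyms, no negation ("no
  evidence of influenza" is tagged), no cross-ontology mapping.
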