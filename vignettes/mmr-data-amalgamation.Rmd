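---
title: "Amalgamating germline MMR laboratory records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amalgamating germline MMR laboratory records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchledger)
```

# The problem

Germline testing of the mismatch-repair (MMR) genes *MLH1*, *MSH2*, *MSH6*
and *PMS2* underpins the diagnosis of Lynch syndrome. The records of that
testing accumulate in regional laboratories under incompatible information
systems: some can export structured tables against a prescribed data
model, others can only export free-text clinical report wording in which
gene results, HGVS variant nomenclature and pathogenicity classifications
are embedded, and copy-number variants (CNVs) are typically described in
natural language rather than HGVS. Building a national, linkable,
patient-level resource from these extracts requires four things that this
package implements and tests end to end: keyed pseudonymisation of patient
identifiers, harmonisation of every dialect into one common data model,
collapsing of per-gene records into per-patient test episodes, and
imputation of the testing activity that predates what laboratories can
extract.

Because real extracts contain patient identifiers and are held under
healthcare data governance, everything here runs on synthetic data from a
generator with known ground truth. The generator is first-class, tested
code: every downstream property (extraction recall, linkage recovery,
audit-factor round-trips) is checked against what was planted.

# The pipeline model

## Pseudonymisation

Two reproducible pseudonyms are derived at ingest and all raw identifiers
are then discarded:

* **pseudo-ID1** — HMAC-SHA-256 of the canonicalised (whitespace-stripped)
  NHS number, under a run-scoped secret key;
* **pseudo-ID2** — HMAC-SHA-256 of `"YYYY-MM-DD|POSTCODE"`, the postcode
  upper-cased with internal whitespace removed.

A keyed one-way digest gives reproducibility (the registry side is
pseudonymised under the same key, so equal identifiers meet as equal
tokens) and irreversibility without key escrow. The canonical forms are a
design choice the linkage depends on; they are fixed and documented here
because any change silently breaks comparability across runs. NHS numbers
are validated with the standard mod-11 check digit (weights 10..2 on
digits 1–9; a remainder mapping to 10 means no valid number exists), so
both valid and invalid strings exercise the validator. The scrubber that
removes identifiers is a privacy contract, not a courtesy: after
redaction of identifier-shaped substrings from free text, any surviving
raw identifier anywhere in the output raises a hard error rather than a
warning.

Records keep working with partial identifiers: patients fall into four
mutually exclusive strata (both pseudonyms, ID1 only, ID2 only, none)
which the linkage reports. Records with neither pseudonym are unlinkable;
for episode building they are grouped by laboratory and authorisation
date, so one unlinkable test's per-gene rows still form a single episode
rather than several phantom patients.

## Harmonisation and the common data model

Each dialect is described declaratively (YAML): column mappings, date
format, result-label vocabulary and the free-text fields to scan. Three
dialects ship with the package — `structured` (CSV, ISO dates),
`structured_uk` (CSV, DD/MM/YYYY dates, NAD/VARIANT DETECTED vocabulary,
numeric IARC classes) and `freetext` (JSONL, one clinical report per
line). Rows the mapper cannot interpret (unparseable dates, unknown gene
symbols, unparseable reports) are quarantined with reason codes, never
silently dropped; the mapped plus quarantined counts always reconcile with
the input.

The free-text parser works sentence-wise: gene symbols, HGVS tokens, CNV
phrases, negative-result phrasing and classification clauses are
recognised independently of sentence position (the generator templates its
reports with randomised filler precisely so that extraction cannot succeed
by position). The supported HGVS grammar subset is deliberately scoped:
`c.` substitutions, del, dup, ins, delins, ranges and intronic offsets,
and `p.` three-letter missense, nonsense, frameshift, del/dup and
synonymous forms. No `g.`/`m.`/`n.` prefixes, complex alleles or
mosaicism. Validation is syntax-only (positions ≥ 1, non-zero intron
offsets, range order, reference ≠ alternate): no transcript or
reference-sequence lookup is performed, which keeps the package fully
offline. CNV wording is routed to a separate curated lexicon
(`detect_cnv_language()`) and never extracted as HGVS.

A record is *abnormal* when labelled positive or carrying a P/LP/VUS
classification — an unclassified positive is "abnormal unclassified" —
and *normal* when labelled negative or carrying only benign/likely-benign
variants. The harmonisation contract is auditable: for every gene, the
computational and manual counts of tests and abnormal results must agree
within 95% (`concordance_audit()`).

## Test episodes

Multiple analyses of one patient within 365 days are one clinical event.
Records are sorted by authorisation date and collapsed greedily: the first
record opens an episode anchored at its date, later records join while
within 365 days *of the anchor*, and the first record beyond it opens a
new episode. The anchored window (rather than an unbounded rolling chain)
is chosen because the episode date is defined as the earliest
authorisation date and an episode must not exceed the window's length; a
rolling chain could grow without bound. Within an episode the outcome is
the maximum under the severity order
P > LP > VUS > abnormal unclassified > normal. Patients with more than
one episode contribute each episode to per-year tables but count once in
unique-patient totals.

## Linkage and cancer timing

Linkage to the pseudonymised registry is deterministic: ID1 when both
sides carry it, else ID2, else unlinkable. On an ID1 match with
conflicting ID2, ID1 wins (the NHS number is the stronger identifier); the
conflict is counted and logged. Cancer timing is relative to the report
date of the patient's *first* test episode, and a diagnosis on exactly the
reference date counts as before the test (a documented tie rule). All
primaries are counted, and ICD-10 codes group as C18–C20 colorectal,
C54–C55 uterine, all other malignant codes "other".

## Coverage imputation

Laboratory-level audit data (financial years 1998–2015, April–March,
labelled by starting year) count each laboratory's annual MMR analyses but
are inflated for some laboratories by non-NHS and
microsatellite-instability work. For each laboratory the pipeline computes
a down-adjustment factor as the *pooled* ratio
`sum(observed) / sum(audit)` over the years where patient-level and audit
data overlap, clamped to (0, 1]. The pooled ratio is preferred to a mean
of per-year ratios because small years would otherwise dominate the
estimate. The factor is applied to audit counts for years before the
laboratory's earliest patient-level submission, rounding half-up at the
last step only (half-to-even would make the arithmetic parity-dependent).
The two financial years predating the audit are back-filled flat with the
laboratory's earliest adjusted annual count — the simplest interpolation
consistent with a small positive increment over the audit-era total.
Consensus counts take observed data where they exist, otherwise the
adjusted or interpolated counts; a lab-year present in both sources is a
hard error. Because the audit does not split full-gene from targeted
activity, imputed counts are apportioned by the observed full-gene share.

Carrier arithmetic is then direct: `carriers = round(total × rate)` per
arm, with default rates of 15% (pathogenic/likely-pathogenic yield of
full-gene analysis) and 45% (abnormal rate of targeted analysis), and the
detected fraction of a population's carriers is
`carriers / (population / k) × 100` for a prevalence of 1 in `k`.

# The synthetic-data generator

`generator_config()` fixes the study conditions; its defaults are the
rates the pipeline is designed around and are not tuned per run:

| parameter | default | meaning |
|---|---|---|
| `rate_plp` | 0.15 | P/LP yield of full-gene tests (14:1 P:LP) |
| `rate_vus` | 0.06 | VUS yield of full-gene tests |
| `rate_benign` | 0.04 | benign/likely-benign-only results |
| `rate_targeted_abnormal` | 0.45 | targeted tests finding the familial variant |
| `rate_cnv_among_abnormal` | 0.20 | abnormal results that are CNVs |
| `rate_hgvs_invalid` | 0.04 | planted HGVS strings that are subtly malformed |
| `rate_classification_reported` | 0.29 | abnormal results with a classification |
| `id_missingness` | (0.093, 0.012) | P(no NHS number), P(no DOB+postcode) |
| `pretest_cancer_rate_fullgene` | 0.70 | full-gene patients with a pre-test cancer |
| `registry_cancer_site_mix` | 0.60/0.14/0.26 | colorectal/uterine/other |

Identifier missingness is modelled with two independent per-patient
probabilities, which is the simplest mechanism generating all four strata;
the resulting "none" stratum is smaller than a fully general model could
make it. Three laboratories cover the three dialects with staggered
activity-start and first-submission years, so each has pre-submission
history for the imputation stage to recover; submission availability is
aligned to financial-year boundaries so observed and audited years are
directly comparable. Malformed HGVS plants (position 0, reference equal to
alternate) still match the extraction grammar but fail validation, giving
the validator true negatives at a realistic rate. Benign/likely-benign
results always carry a reported classification — without one they would
surface as abnormal-unclassified and the planted normal/abnormal truth
would be ambiguous.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: misspelled or non-grammatical HGVS (beyond the
two malformed forms), inconsistent identifiers between laboratory and
registry for the same person (identifier availability is patient-level),
free-text wording outside the template families, family structure, and
test-indication mix. Extraction recall of 100% on the synthetic free-text
dialect is a property of the parser *and* of reports whose variants are
planted verbatim; on real reports recall is necessarily lower.

# Recovering the planted P/LP rate

With classifications available for only ~29% of abnormal results, the raw
share of episodes labelled P/LP underestimates the yield by a factor of
three. Because classification availability is independent of the class
itself (true in the generator by construction, and an assumption that must
be stated for real data), the yield is recoverable as

```
plp_rate = abnormal_rate × P(P or LP | abnormal, classified)
```

which `estimate_plp_rate()` implements:

```{r plp, eval = FALSE}
cfg <- generator_config(n_patients = 10000, seed = 101)
res <- run_pipeline(cfg, key = "demo", out_dir = tempfile())
estimate_plp_rate(res$episodes)$plp_rate  # ~0.15 as planted
```

# Numerical and degenerate-input choices

* Counts are rounded half away from zero, once, at the last step.
* Dates parse under the dialect's declared format with a round-trip check,
  so `"2020-02-31"` cannot slip through as a shifted date; failures
  quarantine the row.
* An empty generator (`n_patients = 0`), an empty registry, an empty
  episode table and a factor-less laboratory all produce empty, typed
  outputs rather than errors; the only hard errors are the privacy
  contract, double-counted lab-years and malformed ICD-10 codes.
* All randomness flows from the single configured seed (writers use a
  fixed offset of it), so a fixed seed and key give byte-identical output
  files.

# Problem sizes

The test suite exercises the pipeline at 100–2,000 patients per module
test and one shared 10,000-patient run for parameter-recovery checks
(rates and strata within binomial 99% confidence intervals);
`scripts/acceptance.R` uses the same 10,000-patient design. These sizes
give per-laboratory annual counts comparable to real regional laboratories
while keeping a full run around a minute.

# Known limitations

* HGVS validation is syntactic only; a syntactically valid variant may be
  biologically impossible for the stated gene.
* The dialect roster is three mappers, not thirteen; real amalgamation
  needs one per laboratory information system.
* Coverage imputation inherits the audit's limitations: no full-gene /
  targeted split, no uncertainty intervals on imputed totals.
* Linkage is exact-key only; no probabilistic or fuzzy matching, and no
  family/pedigree linkage.
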