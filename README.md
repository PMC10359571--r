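# lynchledger

Tools for building a national, patient-level resource of germline
mismatch-repair (MMR) gene testing records — the laboratory data behind
Lynch syndrome diagnosis — from heterogeneous laboratory extracts, and for
estimating how much of the historic national testing activity such a
resource captures.

Lynch syndrome is caused by germline pathogenic variants in the four MMR
genes *MLH1*, *MSH2*, *MSH6* and *PMS2*. Testing records accumulate in
regional laboratories in incompatible formats: some laboratories export
structured tables, others embed gene results and HGVS variant nomenclature
(e.g. `c.942+3A>T`, `p.(Thr117Met)`) in free-text clinical report wording,
and copy-number variants are mostly described in natural language
("deletion of exons 1-6") rather than HGVS. `lynchledger` implements the
full amalgamation pipeline over synthetic data with known ground truth:

1. **synthgen** — a synthetic-data generator emulating per-laboratory
   extract files in three dialects, an ICD-10-coded cancer registry and
   inflated laboratory audit counts, with a ground-truth ledger for
   testing.
2. **pseudonym** — keyed pseudonymisation: pseudo-ID1 =
   HMAC-SHA-256(NHS number), pseudo-ID2 = HMAC-SHA-256(DOB | postcode),
   NHS-number mod-11 validation, and a scrubber that hard-fails if any raw
   identifier survives ingestion.
3. **harmonise** — declarative dialect mappers into a common data model
   (one record per gene per test), HGVS extraction from free text,
   syntax-only HGVS validation, CNV phrase detection, classification
   normalisation (`class 5` → P, ...) and a ≥95% concordance audit.
4. **episodes** — deduplication and collapsing of records into per-patient
   test episodes of at most 365 days anchored at the earliest
   authorisation date, with the result-severity hierarchy
   P > LP > VUS > abnormal unclassified > normal.
5. **linkage** — deterministic linkage to the pseudonymised cancer
   registry (ID1 first, ID2 fallback), cancer timing relative to the first
   test report date, ICD-10 site grouping (C18–C20 colorectal, C54–C55
   uterine).
6. **coverage** — imputation of total historic activity: per-laboratory
   audit down-adjustment by the pooled observed/audit ratio over overlap
   years, flat back-fill of the two pre-audit financial years, combined
   consensus totals and carrier-yield arithmetic
   (`carriers = round(total × rate)`).
7. **report** — tidy summary tables (per-year totals, gene combinations,
   result breakdowns, strata, cancer timing) and the end-to-end
   `run_pipeline()`.

## Worked example

```r
library(lynchledger)

cfg <- generator_config(n_patients = 2000, seed = 1)
res <- run_pipeline(cfg, key = "demo-key", out_dir = "demo")

res$manifest$counts
#> $cdm_records
#> [1] 2562
#> $quarantined
#> [1] 0
#> $episodes
#> [1] 1141
#> $patients
#> [1] 1128
#> $linked_cancers
#> [1] 690

res$coverage$factors
#>      LAB1      LAB2      LAB3
#> 1.0000000 0.7975709 0.6649215

estimate_plp_rate(res$episodes)$plp_rate
#> [1] 0.1497549
```

The manifest counts show conservation across stages (2,562 common-data-model
records collapse to 1,141 deduplicated test episodes for 1,128 patients).
The coverage factors recover each laboratory's audit inflation (LAB2 is
inflated 1.25×, and 1/1.25 = 0.8): audit counts for years predating a
laboratory's patient-level submissions are multiplied by its factor to
impute the missing history. `estimate_plp_rate()` recovers the underlying
pathogenic/likely-pathogenic yield (planted at 15%) from the observed
episodes even though pathogenicity classifications are available for only
~29% of abnormal results.

Outputs written to `demo/` include the CDM as CSV and JSONL, the episode
and linked-cancer tables, per-year summary tables and a run manifest
(seed, key fingerprint — never the key — and per-stage row counts).

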