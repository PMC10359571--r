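dialect_name: structured_uk
format: csv
date_format: "%d/%m/%Y"
columns:
  nhs_number: NHSNO
  dob: DOB
  postcode: POSTCODE
  authorised_date: AUTH_DATE
  report_date: REP_DATE
  test_type: TEST_TYPE
  gene: GENE
  result: RESULT
  classification: CLASS
  variant_cdna: CDNA
  variant_protein: PROTEIN
  cnv_text: CNV_DESC
result_labels:
  positive: ["variant detected", "abnormal", "mut", "positive"]
  negative: ["nad", "normal", "negative"]
scope_labels:
  targeted: ["predictive", "targeted"]
  full_gene: ["full screen", "diagnostic", "screen"]
scan_fields: []
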