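dialect_name: structured
format: csv
date_format: "%Y-%m-%d"
columns:
  nhs_number: nhs_number
  dob: date_of_birth
  postcode: postcode
  authorised_date: authorised_date
  report_date: report_date
  test_type: test_type
  gene: gene
  result: result
  classification: classification
  variant_cdna: variant_cdna
  variant_protein: variant_protein
  cnv_text: cnv_desc
result_labels:
  positive: ["abnormal", "variant detected", "positive", "variant found"]
  negative: ["normal", "nad", "negative", "no variant"]
scope_labels:
  targeted: ["predictive", "targeted", "familial"]
  full_gene: ["diagnostic", "full screen", "screen", "full gene"]
scan_fields: []
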