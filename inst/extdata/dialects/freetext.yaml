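dialect_name: freetext
format: jsonl
date_format: "%Y-%m-%d"
columns:
  nhs_number: nhs_number
  dob: date_of_birth
  postcode: postcode
  authorised_date: authorised_date
  report_date: report_date
scan_fields: ["report_text"]
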