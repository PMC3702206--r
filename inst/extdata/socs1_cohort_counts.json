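{
  "_comment": "Cohort-level counts (machine transcription of the published cohort tables): total screened cases, mutant/subtype sizes, and the wild-type signature-label counts needed to rebuild the status-by-signature contingency tables. Mutant-side labels live per case in socs1_mutant_cases.tsv.",
  "n_total": 154,
  "n_mutant": 24,
  "n_major": 12,
  "n_minor": 12,
  "wild_type_signature_counts": {
    "coo": { "GCB": 51, "ABC": 47, "unclassified": 32 },
    "mbl": { "mBL": 9, "non-mBL": 90, "intermediate": 31 },
    "pap": { "BL-PAP": 10, "PAP-1": 25, "PAP-2": 27, "PAP-3": 21, "PAP-4": 9, "Mind-L": 38 },
    "cc": { "BCR": 66, "HR": 38, "OxPhos": 16 }
  }
}
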