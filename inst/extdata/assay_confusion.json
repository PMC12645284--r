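{
  "description": "Agreement between the literature clear-zone assay and the in-house enzymatic assay for the 20 polymers present in both datasets. Rows: literature call; columns: in-house call.",
  "row_labels": ["biodegradable", "non-biodegradable"],
  "col_labels": ["biodegradable", "non-biodegradable"],
  "counts": [[5, 3], [1, 11]]
}
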