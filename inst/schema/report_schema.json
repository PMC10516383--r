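{
  "title": "cllpanel per-sample report",
  "required_sections": {
    "sample_id": [],
    "igh": ["status"],
    "iglv3_21": ["status"],
    "cnas": ["qc_pass"],
    "variants": ["n_calls"],
    "qc": ["mean_target_coverage"],
    "run": ["tool", "version", "bundle_checksum", "config_digest"]
  }
}
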