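{
  "schema_version": "1.0",
  "description": "Structural schema for the standardised PRS evaluation report",
  "required": ["distribution", "traits", "provenance"],
  "provenance_required": ["package_version", "seed", "config_hash", "incidence_mode"]
}
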