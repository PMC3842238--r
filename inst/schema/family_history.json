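{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "family_history report",
  "type": "object",
  "required": ["provenance", "origin", "origin_rank", "family_absent",
               "hgt_candidates", "gains", "losses", "complete_losses"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "timestamp", "config",
                   "input_checksums"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "timestamp": {"type": "string"},
        "config": {"type": "object"},
        "input_checksums": {"type": "object"}
      }
    },
    "origin": {"type": ["string", "null"]},
    "origin_rank": {"type": ["string", "null"]},
    "family_absent": {"type": "boolean"},
    "hgt_candidates": {"type": "array"},
    "gains": {"type": "array"},
    "losses": {"type": "array"},
    "complete_losses": {"type": "array"}
  }
}
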