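{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sexbiasarch consolidated report",
  "type": "object",
  "required": ["seed", "config_hash", "bias_summary", "x_chromosome",
               "enriched_regions", "clusters", "dnds"],
  "properties": {
    "seed": {"type": "integer"},
    "config_hash": {"type": "string"},
    "bias_summary": {"type": ["array", "object"]},
    "x_chromosome": {
      "type": "object",
      "required": ["scaffold", "coverage_ratio", "y_candidates"]
    },
    "enriched_regions": {"type": ["array", "object"]},
    "clusters": {"type": ["array", "object"]},
    "dnds": {"type": ["array", "object"]}
  }
}
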