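{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "comorbidity-network",
  "type": "object",
  "required": ["nodes", "edges", "density", "label", "provenance"],
  "properties": {
    "label": { "type": "string" },
    "density": { "type": "number", "minimum": -1, "maximum": 1 },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["disease", "prevalence", "connectivity"],
        "properties": {
          "disease": { "type": "string" },
          "prevalence": { "type": "number", "minimum": 0, "maximum": 1 },
          "connectivity": { "type": ["number", "null"] }
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["disease_i", "disease_j", "mean_phi", "phi_p025"],
        "properties": {
          "disease_i": { "type": "string" },
          "disease_j": { "type": "string" },
          "mean_phi": { "type": "number", "exclusiveMinimum": 0 },
          "phi_p025": { "type": "number", "exclusiveMinimum": 0 }
        }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["seed", "n_resamples", "resample_size", "percentile", "n_subjects"]
    }
  }
}
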