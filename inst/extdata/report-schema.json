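{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "elncut pipeline report",
  "type": "object",
  "required": ["software", "config", "cohorts", "continuous_models",
               "positive_vs_examined", "breakpoints", "cutpoint",
               "validation", "artifacts"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "config": {"type": "object"},
    "cohorts": {
      "type": "object",
      "required": ["derivation"],
      "properties": {
        "derivation": {"$ref": "#/definitions/cohort_summary"},
        "validation": {"$ref": "#/definitions/cohort_summary"}
      }
    },
    "continuous_models": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["effect", "ci", "p_value", "outcome"],
        "properties": {
          "effect": {"type": "number"},
          "ci": {"type": "array", "items": {"type": "number"}},
          "p_value": {"type": "number"},
          "outcome": {"type": "string"}
        }
      }
    },
    "positive_vs_examined": {"type": "object"},
    "breakpoints": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["smoothed", "raw"],
        "properties": {
          "smoothed": {"type": "number"},
          "raw": {"type": "number"},
          "f": {"type": "number"},
          "p": {"type": "number"}
        }
      }
    },
    "cutpoint": {
      "type": "object",
      "required": ["selected", "threshold_used", "breaks", "spread"],
      "properties": {
        "selected": {"type": "integer"},
        "threshold_used": {"type": "integer"},
        "breaks": {"type": "object"},
        "spread": {"type": "number"},
        "concordant": {"type": "boolean"}
      }
    },
    "validation": {"type": "object"},
    "artifacts": {
      "type": "object",
      "required": ["out_dir", "files"],
      "properties": {
        "out_dir": {"type": "string"},
        "files": {"type": "array", "items": {"type": "string"}}
      }
    }
  },
  "definitions": {
    "cohort_summary": {
      "type": "object",
      "required": ["n", "deaths", "censored_fraction", "median_followup",
                   "eln_median", "eln_iqr"],
      "properties": {
        "n": {"type": "integer"},
        "deaths": {"type": "integer"},
        "censored_fraction": {"type": "number"},
        "median_followup": {"type": "number"},
        "eln_median": {"type": "number"},
        "eln_iqr": {"type": "array", "items": {"type": "number"}},
        "node_negative_fraction": {"type": "number"},
        "node_positive_fraction": {"type": "number"}
      }
    }
  }
}
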