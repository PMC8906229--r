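{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Per-fraction plan-check report",
  "type": "object",
  "required": [
    "files", "identity", "structure_match", "volume_table", "chain_findings",
    "gap_reports", "density_overrides", "complexity", "alerts", "light",
    "config", "timestamp"
  ],
  "properties": {
    "files": {
      "type": "object",
      "required": ["original_plan", "original_rs", "adapted_plan", "adapted_rs"]
    },
    "identity": {
      "type": "object",
      "required": ["original", "adapted"],
      "properties": {
        "original": { "$ref": "#/definitions/identity" },
        "adapted": { "$ref": "#/definitions/identity" }
      }
    },
    "structure_match": {
      "type": "object",
      "required": ["matched", "deleted", "new", "count_difference"]
    },
    "volume_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "volume_original", "volume_adapted", "delta_percent", "delta_cc", "undefined"]
      }
    },
    "chain_findings": { "type": "array" },
    "gap_reports": { "type": "array" },
    "density_overrides": { "type": "array" },
    "complexity": {
      "type": "object",
      "required": ["original", "adapted", "mu_delta_percent"]
    },
    "alerts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["code", "weight", "message"],
        "properties": {
          "code": {
            "enum": [
              "WRONG_PATIENT", "WRONG_PLAN", "MU_DIFF", "STRUCTURE_DELETED",
              "VOLUME_DIFF", "TARGET_INCONSISTENT", "SMALL_SEGMENTS",
              "LOW_MU_SEGMENTS", "STRUCTURE_GAP"
            ]
          },
          "weight": { "type": "number", "minimum": 0 }
        }
      }
    },
    "light": {
      "type": "object",
      "required": ["value", "total_weight"],
      "properties": {
        "value": { "enum": ["green", "orange", "red"] },
        "total_weight": { "type": "number", "minimum": 0 }
      }
    },
    "config": { "type": "object" },
    "timestamp": { "type": "string" }
  },
  "definitions": {
    "identity": {
      "type": "object",
      "required": ["patient_name", "patient_id", "plan_name"]
    }
  }
}
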