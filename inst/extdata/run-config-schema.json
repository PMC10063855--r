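{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ahrfsig pipeline run configuration",
  "type": "object",
  "required": ["seed", "cohorts"],
  "additionalProperties": false,
  "properties": {
    "seed": {"type": "integer", "description": "global RNG seed; per-stage seeds are derived from it"},
    "shared_informative": {"type": "integer", "default": 30},
    "cohorts": {
      "type": "object",
      "required": ["a", "b"],
      "additionalProperties": false,
      "properties": {
        "a": {"$ref": "#/$defs/cohort"},
        "b": {"$ref": "#/$defs/cohort"}
      }
    },
    "preprocess": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "quantile_normalize": {"type": "boolean", "default": true},
        "batch_correct": {"type": "boolean", "default": true}
      }
    },
    "stability": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "n_boot": {"type": "integer", "default": 100},
        "score_threshold": {"type": "number", "default": 0.6},
        "penalty_strength": {"type": "number", "default": 1.0},
        "coef_epsilon": {"type": "number", "default": 1e-8},
        "stratified": {"type": "boolean", "default": true}
      }
    },
    "signature": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "top_k": {"type": "integer", "default": 1500},
        "step": {"type": "integer", "default": 10},
        "sizes": {"type": ["array", "null"], "items": {"type": "integer"}, "default": null},
        "metric": {"type": "string", "enum": ["auroc", "auprc"], "default": "auroc"},
        "ci_resamples": {"type": "integer", "default": 2000}
      }
    },
    "enrich": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "gmt": {"type": ["string", "null"], "default": null}
      }
    },
    "network": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "sif": {"type": ["string", "null"], "default": null},
        "min_degree": {"type": "integer", "default": 10}
      }
    }
  },
  "$defs": {
    "cohort": {
      "type": "object",
      "oneOf": [
        {
          "required": ["n_cases", "n_controls"],
          "properties": {
            "n_cases": {"type": "integer"},
            "n_controls": {"type": "integer"},
            "n_genes": {"type": "integer", "default": 5000},
            "n_informative": {"type": "integer", "default": 50},
            "effect_size": {"type": "number", "default": 0.75},
            "noise_sd": {"type": "number", "default": 1.0},
            "n_batches": {"type": "integer", "default": 2},
            "batch_shift_sd": {"type": "number", "default": 0.5}
          }
        },
        {
          "required": ["expr", "labels"],
          "properties": {
            "expr": {"type": "string"},
            "labels": {"type": "string"},
            "annotation": {"type": "string"}
          }
        }
      ]
    }
  }
}
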