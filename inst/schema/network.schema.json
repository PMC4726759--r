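{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cmekit reaction network configuration",
  "type": "object",
  "required": ["species", "reactions"],
  "properties": {
    "name": { "type": "string" },
    "compartments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": { "type": "string" },
          "volume": { "type": "number", "exclusiveMinimum": 0 }
        }
      }
    },
    "species": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": { "type": "string" },
          "compartment": { "type": "string" },
          "initial": { "type": "integer", "minimum": 0 },
          "copy_class": { "enum": ["auto", "low_copy", "high_copy"] }
        }
      }
    },
    "parameters": {
      "type": "object",
      "additionalProperties": { "type": "number" }
    },
    "inputs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "expression"],
        "properties": {
          "name": { "type": "string" },
          "expression": { "type": "string", "description": "R expression in t and parameters" }
        }
      }
    },
    "reactions": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["rate"],
        "properties": {
          "name": { "type": "string" },
          "reactants": { "type": "object", "additionalProperties": { "type": "integer", "minimum": 1 } },
          "products": { "type": "object", "additionalProperties": { "type": "integer", "minimum": 1 } },
          "rate": { "type": ["string", "number"], "description": "rate constant (mass_action) or propensity expression (general)" },
          "kinetics": { "enum": ["mass_action", "general"] },
          "delay": { "type": "number", "minimum": 0 }
        }
      }
    },
    "observables": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "expression"],
        "properties": {
          "name": { "type": "string" },
          "expression": { "type": "string" }
        }
      }
    }
  }
}
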