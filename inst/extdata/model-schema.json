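{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "hydrogem metabolic model",
  "type": "object",
  "required": ["id", "compartments", "metabolites", "reactions", "objective"],
  "properties": {
    "id": {"type": "string"},
    "compartments": {"type": "array", "items": {"enum": ["c", "h", "e"]}},
    "objective": {"type": "string", "description": "reaction id"},
    "provenance": {"type": "array", "items": {"type": "string"}},
    "vitamin_exchanges": {"type": "array", "items": {"type": "string"}},
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "formula", "charge", "compartment"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "formula": {"type": "string",
                      "description": "CHONPS formula, may be empty"},
          "charge": {"type": "number"},
          "compartment": {"enum": ["c", "h", "e"]}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "bounds", "kind", "stoichiometry"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "bounds": {"type": "array", "minItems": 2, "maxItems": 2,
                     "items": {"type": "number"},
                     "description": "[lower, upper] in mmol/gDW/h"},
          "kind": {"enum": ["internal", "exchange", "biomass",
                            "maintenance", "demand"]},
          "subsystem": {"type": "string"},
          "speculative": {"type": "boolean"},
          "confidence": {"type": "integer", "minimum": 0, "maximum": 4},
          "gene_association": {"type": ["string", "null"]},
          "stoichiometry": {
            "type": "object",
            "additionalProperties": {"type": "number"},
            "description": "metabolite id -> signed coefficient"
          }
        }
      }
    }
  }
}
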