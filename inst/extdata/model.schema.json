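{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "thermokin constraint-based model (canonical JSON dialect)",
  "type": "object",
  "required": ["name", "objective", "compartments", "species", "reactions"],
  "properties": {
    "name": {"type": "string"},
    "temperature": {"type": "number", "description": "K; enters RT terms", "default": 298.15},
    "objective": {"type": "string", "description": "id of the biomass/objective reaction"},
    "compartments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "volume_fraction"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "volume_fraction": {"type": "number", "exclusiveMinimum": 0, "maximum": 1,
            "description": "fraction of intracellular volume; fractions of non-extracellular compartments must sum to 1"},
          "extracellular": {"type": "boolean", "default": false}
        }
      }
    },
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "compartment"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "compartment": {"type": "string"},
          "whole_cell_group": {"type": ["string", "null"],
            "description": "name of the measured whole-cell metabolite this species belongs to"},
          "formula": {"type": ["string", "null"], "description": "chemical formula, e.g. C6H12O6"}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "lb", "ub", "stoichiometry"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "lb": {"type": "number", "description": "mmol/gDCW/h"},
          "ub": {"type": "number", "description": "mmol/gDCW/h"},
          "drG0": {"type": ["number", "null"],
            "description": "transformed standard Gibbs energy of reaction, kJ/mol; null when not annotated"},
          "drG0_err": {"type": "number", "minimum": 0, "description": "kJ/mol"},
          "subsystem": {"type": ["string", "null"]},
          "is_transport": {"type": "boolean", "default": false},
          "is_exchange": {"type": "boolean", "default": false,
            "description": "exchange reactions touch exactly one species"},
          "gene_rule": {"type": ["string", "null"],
            "description": "boolean expression over gene ids using and/or"},
          "stoichiometry": {
            "type": "object",
            "additionalProperties": {"type": "number"},
            "description": "species id -> signed coefficient; negative = consumed"
          }
        }
      }
    }
  }
}
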