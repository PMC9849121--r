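{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "eatr scenario configuration",
  "description": "Task-by-season soil-exposure scenario consumed by eatr::build_grid_from_config(). YAML documents with the same structure are equivalent.",
  "type": "object",
  "required": ["tasks", "seasons", "baselines"],
  "additionalProperties": false,
  "properties": {
    "label": { "type": "string" },
    "tasks": { "type": "array", "items": { "type": "string" } },
    "seasons": { "type": "array", "items": { "type": "string" } },
    "baselines": {
      "type": "object",
      "required": ["ingestion", "dermal"],
      "properties": {
        "ingestion": {
          "type": "object",
          "required": ["concentration", "intake_rate", "exposure_factor", "body_weight"],
          "properties": {
            "concentration": { "type": "number", "minimum": 0, "description": "mg contaminant per mg soil" },
            "intake_rate": { "type": "number", "minimum": 0, "description": "mg soil per day" },
            "exposure_factor": { "type": "number", "minimum": 0, "maximum": 1 },
            "body_weight": { "type": "number", "exclusiveMinimum": 0, "description": "kg" }
          }
        },
        "dermal": {
          "type": "object",
          "required": ["concentration", "conversion_factor", "adherence_factor",
                       "absorption_fraction", "surface_area", "exposure_frequency",
                       "exposure_duration", "event_frequency", "body_weight",
                       "averaging_time"],
          "properties": {
            "concentration": { "type": "number", "minimum": 0, "description": "mg contaminant per kg soil" },
            "conversion_factor": { "type": "number", "minimum": 0, "description": "kg per mg" },
            "adherence_factor": { "type": "number", "minimum": 0, "description": "mg soil per cm2 per event" },
            "absorption_fraction": { "type": "number", "minimum": 0, "maximum": 1 },
            "surface_area": { "type": "number", "minimum": 0, "description": "cm2 exposed skin" },
            "exposure_frequency": { "type": "number", "minimum": 0, "description": "contact days per year" },
            "exposure_duration": { "type": "number", "minimum": 0, "description": "years" },
            "event_frequency": { "type": "number", "minimum": 0, "description": "events per day" },
            "body_weight": { "type": "number", "exclusiveMinimum": 0, "description": "kg" },
            "averaging_time": { "type": "number", "exclusiveMinimum": 0, "description": "days" }
          }
        }
      }
    },
    "schedules": {
      "type": "array",
      "description": "One entry per worked task-season cell; cells absent here are zero-exposure cells. Give either a worked schedule (hours/days/weeks) or direct exposure_factor / exposure_frequency values.",
      "items": {
        "type": "object",
        "required": ["task", "season"],
        "properties": {
          "task": { "type": "string" },
          "season": { "type": "string" },
          "hours_per_day": { "type": "number", "minimum": 0, "maximum": 24 },
          "days_per_week": { "type": "number", "minimum": 0, "maximum": 7 },
          "weeks_per_year": { "type": "number", "minimum": 0, "maximum": 52 },
          "exposure_factor": { "type": "number", "minimum": 0, "maximum": 1 },
          "exposure_frequency": { "type": "number", "minimum": 0, "maximum": 366 }
        }
      }
    },
    "modifiers": { "$ref": "#/$defs/modifier_list" },
    "receptor": {
      "type": "object",
      "required": ["label", "body_weight"],
      "properties": {
        "label": { "type": "string" },
        "body_weight": { "type": "number", "exclusiveMinimum": 0 },
        "age_band": { "type": "string" },
        "sex": { "type": "string" },
        "modifiers": { "$ref": "#/$defs/modifier_list" }
      }
    }
  },
  "$defs": {
    "modifier_list": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["factor", "target", "action", "value"],
        "properties": {
          "factor": {
            "enum": ["natural", "social_built", "crop_type", "growing_practices",
                     "ergonomic_positioning", "season", "day_of_week",
                     "time_of_day", "behavioral", "biological"]
          },
          "target": {
            "description": "Must belong to the factor's permitted parameter set (EAT-R taxonomy); enforced by the package at build time.",
            "enum": ["concentration", "intake_rate", "exposure_factor", "body_weight",
                     "conversion_factor", "adherence_factor", "absorption_fraction",
                     "surface_area", "exposure_frequency", "exposure_duration",
                     "event_frequency", "averaging_time"]
          },
          "action": { "enum": ["multiply", "override"] },
          "value": { "type": "number", "minimum": 0 },
          "tasks": { "type": "array", "items": { "type": "string" } },
          "seasons": { "type": "array", "items": { "type": "string" } }
        }
      }
    }
  }
}
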