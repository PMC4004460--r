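{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Patient visit record (one JSON-Lines object)",
  "description": "One visit's clinical snapshot. A cohort file is UTF-8 JSON Lines (LF endings), one of these objects per line. All event dates must be on or before visit_date.",
  "type": "object",
  "required": ["visit_id", "patient_id", "visit_date", "events"],
  "properties": {
    "visit_id": {"type": "string", "minLength": 1},
    "patient_id": {"type": "string", "minLength": 1},
    "visit_date": {"type": "string", "format": "date"},
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["kind", "system", "code", "date"],
        "properties": {
          "kind": {"enum": ["problem", "lab", "medication", "exam", "discharge_dx"]},
          "system": {"type": "string", "minLength": 1},
          "code": {"type": "string", "minLength": 1},
          "display": {"type": "string"},
          "date": {"type": "string", "format": "date"},
          "value": {"type": "number"}
        }
      }
    }
  }
}
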