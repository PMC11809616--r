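{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "trunksense/posture-session-log/1.0",
  "title": "Posture monitoring session log",
  "description": "OpenMHealth-style envelope for one monitored stage: a header carrying the schema id, acquisition metadata, the engine configuration and the calibration reference, and a body carrying the 1 Hz angle records and the full timestamped feedback/interaction event sequence. Stage-internal times are seconds since stage start; wall-clock fields are ISO-8601.",
  "type": "object",
  "required": ["header", "body"],
  "properties": {
    "header": {
      "type": "object",
      "required": ["schema_id", "subject_id", "stage_label", "config", "calibration"],
      "properties": {
        "schema_id": {
          "type": "object",
          "required": ["namespace", "name", "version"],
          "properties": {
            "namespace": {"const": "trunksense"},
            "name": {"const": "posture-session-log"},
            "version": {"type": "string"}
          }
        },
        "subject_id": {"type": "string"},
        "stage_label": {"enum": ["feedback_on", "feedback_off"]},
        "recorded_at": {"type": "string", "format": "date-time"},
        "config": {
          "type": "object",
          "required": ["frontal_threshold_deg", "lateral_threshold_deg", "tolerance_s"],
          "properties": {
            "frontal_threshold_deg": {"type": "number", "exclusiveMinimum": 0},
            "lateral_threshold_deg": {"type": "number", "exclusiveMinimum": 0},
            "tolerance_s": {"type": "number", "minimum": 0},
            "vibration_enabled": {"type": "boolean"},
            "audio_enabled": {"type": "boolean"},
            "visual_enabled": {"type": "boolean"},
            "language": {"enum": ["en", "es", "pt"]},
            "hysteresis_deg": {"type": "number", "minimum": 0},
            "directive_repeat_s": {"type": "number", "exclusiveMinimum": 0},
            "praise_interval_s": {"type": "number", "exclusiveMinimum": 0},
            "rng_seed": {"type": "integer"}
          }
        },
        "calibration": {
          "type": "object",
          "required": ["r0"],
          "properties": {
            "r0": {
              "type": "array", "items": {"type": "number"},
              "minItems": 3, "maxItems": 3,
              "description": "unit gravity direction of the calibrated best-at-the-time posture, device frame"
            },
            "created_at": {"type": "string", "format": "date-time"}
          }
        }
      }
    },
    "body": {
      "type": "object",
      "required": ["angle_records", "events"],
      "properties": {
        "angle_records": {
          "type": "array",
          "description": "1 Hz records; t non-decreasing",
          "items": {
            "type": "object",
            "required": ["t", "frontal_deg", "lateral_deg", "posture"],
            "properties": {
              "t": {"type": "number", "minimum": 0},
              "frontal_deg": {"type": "number", "exclusiveMinimum": -180, "maximum": 180},
              "lateral_deg": {"type": "number", "exclusiveMinimum": -180, "maximum": 180},
              "posture": {"enum": ["IN", "OUT"]}
            }
          }
        },
        "events": {
          "type": "array",
          "description": "timestamped feedback and interaction events; t non-decreasing",
          "items": {
            "type": "object",
            "required": ["t", "kind"],
            "properties": {
              "t": {"type": "number", "minimum": 0},
              "kind": {
                "enum": ["COLOR_GREEN", "COLOR_RED", "VIBRATION",
                         "AUDIO_DIRECTIVE", "AUDIO_PRAISE",
                         "AUDIO_CONGRATULATION", "CALIBRATED",
                         "SETTINGS_CHANGED", "MONITORING_STARTED",
                         "MONITORING_PAUSED"]
              },
              "payload": {"type": "object"}
            }
          }
        }
      }
    }
  }
}
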