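{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "uwcager pipeline summary",
  "type": "object",
  "required": ["coefficients", "critical_values", "closure_day",
               "class_counts", "validation", "month_histogram", "counts"],
  "properties": {
    "coefficients": {
      "type": "object",
      "required": ["a0", "a1", "b0", "b1"],
      "properties": {
        "a0": {"type": "number"},
        "a1": {"type": "number"},
        "b0": {"type": "number"},
        "b1": {"type": "number"}
      }
    },
    "critical_values": {
      "type": "object",
      "required": ["area_cm2", "perimeter_cm"],
      "properties": {
        "area_cm2": {"type": "number"},
        "perimeter_cm": {"type": "number"}
      }
    },
    "closure_day": {"type": "number"},
    "class_counts": {"type": "object"},
    "validation": {
      "type": "object",
      "required": ["n"],
      "properties": {
        "mean_abs_diff": {"type": ["number", "null"]},
        "sd_abs_diff": {"type": ["number", "null"]},
        "n": {"type": "number"}
      }
    },
    "month_histogram": {"type": "object"},
    "seasonality": {"type": ["object", "null"]},
    "morphometrics": {"type": ["object", "null"]},
    "counts": {"type": "object"}
  }
}
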