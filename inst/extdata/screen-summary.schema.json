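{
  "title": "cpdscreen summary",
  "type": "object",
  "required": ["tool", "thresholds", "stages"],
  "properties": {
    "tool": {"type": "string"},
    "thresholds": {
      "type": "object",
      "required": ["fixation_fraction", "proximity_A", "max_losses",
                   "alpha", "rank"],
      "properties": {
        "fixation_fraction": {"type": "number"},
        "proximity_A": {"type": "number"},
        "max_losses": {"type": "number"},
        "alpha": {"type": "number"},
        "rank": {"type": "string"}
      }
    },
    "stages": {
      "type": "object",
      "required": ["scan", "pair", "ci", "proximity", "dating"],
      "properties": {
        "scan": {"type": "stage"},
        "pair": {"type": "stage"},
        "ci": {"type": "stage"},
        "proximity": {"type": "stage"},
        "dating": {"type": "stage"}
      }
    }
  }
}
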